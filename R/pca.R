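#' Symmetric linear operators for matrix-free computation
#'
#' A `linear_operator` packages a dimension and an action
#' (vector to vector) so that algorithms like [randomized_pca()] can work
#' with a relatedness matrix that is never materialized.
#' `grm_operator()` wraps the matrix-free branch GRM product of a tree
#' sequence; `dense_operator()` wraps an explicit symmetric matrix;
#' `sum_operator()` adds operators of equal dimension, which is how
#' multi-chromosome (per-autosome) operators are combined into a
#' whole-genome one — sample indexing must agree across chromosomes.
#'
#' @param action function taking and returning a numeric vector of length
#'   `n`.
#' @param n dimension.
#' @param description label used when printing.
#' @return an object of class `linear_operator`.
#' @export
linear_operator <- function(action, n, description = "operator") {
  structure(list(action = action, n = as.integer(n),
                 description = description),
            class = "linear_operator")
}

#' @export
print.linear_operator <- function(x, ...) {
  cat(sprintf("linear_operator: %s, dimension %d\n", x$description, x$n))
  invisible(x)
}

#' @rdname linear_operator
#' @param ts a `tree_sequence`.
#' @param centered,ploidy_level passed to [branch_grm_vector()].
#' @export
grm_operator <- function(ts, centered = TRUE,
                         ploidy_level = c("node", "individual")) {
  ploidy_level <- match.arg(ploidy_level)
  n <- if (ploidy_level == "node") length(ts_samples(ts)) else
    length(unique(ts$nodes$individual[ts_samples(ts) + 1L]))
  linear_operator(function(v)
    as.numeric(branch_grm_vector(ts, v, centered = centered,
                                 ploidy_level = ploidy_level)),
    n, sprintf("branch GRM (%s, %s)",
               if (centered) "centered" else "uncentered", ploidy_level))
}

#' @rdname linear_operator
#' @param M symmetric numeric matrix.
#' @export
dense_operator <- function(M) {
  M <- as.matrix(M)
  linear_operator(function(v) as.numeric(M %*% v), nrow(M), "dense matrix")
}

#' @rdname linear_operator
#' @param ops non-empty list of `linear_operator`s of equal dimension.
#' @export
sum_operator <- function(ops) {
  if (length(ops) == 0) stop("empty operator list")
  n <- ops[[1]]$n
  if (any(vapply(ops, `[[`, integer(1), "n") != n))
    stop("operator dimension mismatch")
  linear_operator(function(v) {
    y <- numeric(n)
    for (op in ops) y <- y + op$action(v)
    y
  }, n, sprintf("sum of %d operators", length(ops)))
}

op_apply_mat <- function(op, M) {
  out <- matrix(0, op$n, ncol(M))
  for (j in seq_len(ncol(M))) out[, j] <- op$action(M[, j])
  out
}

#' Randomized PCA of a symmetric PSD linear operator
#'
#' Randomized SVD specialized to the branch GRM: a Gaussian probe matrix
#' with `k + oversample` columns estimates the range of the operator
#' (re-orthonormalized by QR after each of `q` power iterations), then an
#' exact SVD of the small projected matrix yields the leading components.
#' Oversampling tightens the range estimate; `oversample = 0` runs the
#' bare algorithm. Components are sign-normalized so that each column's
#' largest-magnitude entry is positive, making results seed-stable.
#'
#' @param op a `linear_operator` (symmetric; e.g. from [grm_operator()]).
#' @param k number of components to return (`1 <= k <= n - 1`).
#' @param q number of power iterations.
#' @param oversample extra probe columns beyond `k`.
#' @param seed integer RNG seed.
#' @return object of class `ts_pca`: list with `components` (n x k,
#'   orthonormal columns), `singular_values` (descending), and the
#'   parameters used.
#' @export
randomized_pca <- function(op, k, q = 3, oversample = 10, seed) {
  n <- op$n
  if (k >= n) stop("k too large")
  stopifnot(k >= 1, q >= 0, oversample >= 0)
  set.seed(seed)
  m <- min(n, k + oversample)
  omega <- matrix(stats::rnorm(n * m), n, m)
  Q <- qr.Q(qr(op_apply_mat(op, omega)))
  if (q > 0) for (i in seq_len(q)) Q <- qr.Q(qr(op_apply_mat(op, Q)))
  Z <- op_apply_mat(op, Q)              # B Q;  W = Q'B = t(Z) by symmetry
  sv <- svd(t(Z))
  comp <- Q %*% sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(components = comp, singular_values = sv$d[seq_len(k)],
                 k = k, q = q, oversample = oversample, seed = seed),
            class = "ts_pca")
}

#' @export
print.ts_pca <- function(x, ...) {
  cat(sprintf("ts_pca: %d components of a %d-dimensional operator\n",
              x$k, nrow(x$components)))
  cat("singular values:", format(x$singular_values, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.ts_pca <- function(x, dims = c(1, 2), col = 1, ...) {
  if (x$k < 2) stop("need at least two components to plot")
  plot(x$components[, dims[1]], x$components[, dims[2]],
       xlab = sprintf("PC%d", dims[1]), ylab = sprintf("PC%d", dims[2]),
       col = col, ...)
  invisible(x)
}

#' Remap tree-sequence coordinates through a genetic map
#'
#' Applies a piecewise-linear, strictly increasing position map (e.g. base
#' pairs to centimorgans) to every edge endpoint, site position and the
#' sequence length. Tree topologies are unchanged; spans are measured in
#' the new units, so downstream area-based relatedness weighs genomic
#' regions by mapped (genetic) distance. The map must cover
#' `[0, sequence_length]`; the output origin is shifted to 0.
#'
#' @param ts a `tree_sequence`.
#' @param genetic_map data.frame with strictly increasing columns
#'   `position` and `map_cM`.
#' @return a `tree_sequence` in mapped coordinates.
#' @export
remap_coordinates <- function(ts, genetic_map) {
  gm <- as.data.frame(genetic_map)
  if (any(diff(gm$position) <= 0) || any(diff(gm$map_cM) <= 0))
    stop("genetic map must be strictly increasing in both columns")
  if (gm$position[1] > 0 || gm$position[nrow(gm)] < ts$sequence_length)
    stop("map coverage: map must span [0, sequence_length]")
  raw <- function(x) stats::approx(gm$position, gm$map_cM, xout = x,
                                   rule = 1)$y
  origin <- raw(0)
  f <- function(x) raw(x) - origin
  e <- ts$edges
  e$left <- f(e$left); e$right <- f(e$right)
  s <- ts$sites
  if (nrow(s) > 0) s$position <- f(s$position)
  tree_sequence(ts$nodes, e, s, f(ts$sequence_length))
}
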