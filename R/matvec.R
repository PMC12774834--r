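#' Matrix-free branch GRM-vector product
#'
#' Computes `y = B w` where `B` is the branch GRM, without forming `B`.
#' The algorithm sweeps the tree sequence left to right maintaining, per
#' node, a subtree weight `w(n)`, an accumulated haplotype value `v(n)`,
#' and the genome position `x(n)` of the last update. Each edge insertion
#' or removal updates only the nodes from the edge's parent up to the root
#' of the current tree: the pending contribution
#' `z(n) = l(n) * (pos - x(n)) * w(n)` of the branch above each such node
#' is flushed, and the accumulated value of the path is passed down to the
#' edge's child. Removing every edge at the end of the genome flushes all
#' remaining contributions down to the sample leaves. The number of
#' per-node state updates is counted and returned as a diagnostic; it is
#' bounded by a constant times `n + n_trees * log2(n)`.
#'
#' Uncentered, `y = A w` with `A` the shared-area matrix; centered,
#' `y = P A (P w)` with `P = I - 11'/n` applied around the uncentered
#' core. At individual level, each individual's weight is split as `w/2`
#' onto its two genomes and the two node outputs are averaged.
#'
#' @param ts a `tree_sequence` whose samples are leaves in every local
#'   tree.
#' @param w numeric weight vector: one entry per sample node (node level)
#'   or per individual (individual level).
#' @param centered apply double centering (default `TRUE`)?
#' @param ploidy_level `"node"` or `"individual"`.
#' @param debug if `TRUE`, assert after every tree transition that the
#'   root weights sum to `sum(w)` (weight conservation).
#' @return numeric vector `y` with attribute `"diagnostics"`: a list with
#'   `node_updates` and `trees_processed`.
#' @export
branch_grm_vector <- function(ts, w, centered = TRUE,
                              ploidy_level = c("node", "individual"),
                              debug = FALSE) {
  ploidy_level <- match.arg(ploidy_level)
  samples <- ts_samples(ts)
  if (any(ts$edges$parent %in% samples)) stop("samples must be leaves")
  if (ploidy_level == "individual") {
    ind <- ts$nodes$individual[samples + 1L]
    if (any(is.na(ind))) stop("samples must carry individual ids")
    uind <- sort(unique(ind))
    if (length(w) != length(uind)) stop("bad vector")
    grp <- match(ind, uind)
    wn <- w[grp] / 2
    if (centered) wn <- wn - mean(wn)
    res <- algv_core(ts, wn, debug = debug)
    y <- res$y
    if (centered) y <- y - mean(y)
    yi <- as.vector(rowsum(y, grp) / tabulate(grp))
    names(yi) <- uind
    structure(yi, diagnostics = res$diagnostics)
  } else {
    if (length(w) != length(samples)) stop("bad vector")
    wn <- if (centered) w - mean(w) else w
    res <- algv_core(ts, wn, debug = debug)
    y <- res$y
    if (centered) y <- y - mean(y)
    names(y) <- samples
    structure(y, diagnostics = res$diagnostics)
  }
}

# The sweep core. Operates on 1-based node arrays; ids in edge tables are
# 0-based. Every per-node state update (flush + weight adjustment at one
# node) increments the instrumentation counter once.
algv_core <- function(ts, w_samples, debug = FALSE) {
  N <- nrow(ts$nodes)
  e <- ts$edges
  tm <- ts$nodes$time
  samples <- ts_samples(ts)
  w <- numeric(N); w[samples + 1L] <- w_samples
  v <- numeric(N)
  x <- numeric(N)
  parent <- rep(NA_integer_, N)
  updates <- 0L
  el <- e$left; er <- e$right; ep <- e$parent; ec <- e$child
  ins <- ts$insertion; rem <- ts$removal
  ne <- length(el)
  bp <- ts_breakpoints(ts)
  total_w <- sum(w_samples)
  j <- 1L; k <- 1L
  for (pos in bp) {
    while (k <= ne && er[rem[k]] == pos) {
      r <- rem[k]
      ci <- ec[r] + 1L
      p <- ep[r]
      # flush the removed edge's own branch above the child
      v[ci] <- v[ci] + (tm[p + 1L] - tm[ci]) * (pos - x[ci]) * w[ci]
      updates <- updates + 1L
      n <- p
      while (!is.na(n)) {
        ni <- n + 1L
        pn <- parent[ni]
        ell <- if (is.na(pn)) 0 else tm[pn + 1L] - tm[ni]
        v[ni] <- v[ni] + ell * (pos - x[ni]) * w[ni]
        w[ni] <- w[ni] - w[ci]
        v[ci] <- v[ci] + v[ni]
        x[ni] <- pos
        updates <- updates + 1L
        n <- pn
      }
      x[ci] <- pos
      parent[ci] <- NA_integer_
      k <- k + 1L
    }
    while (j <= ne && el[ins[j]] == pos) {
      r <- ins[j]
      ci <- ec[r] + 1L
      p <- ep[r]
      n <- p
      while (!is.na(n)) {
        ni <- n + 1L
        pn <- parent[ni]
        ell <- if (is.na(pn)) 0 else tm[pn + 1L] - tm[ni]
        v[ni] <- v[ni] + ell * (pos - x[ni]) * w[ni]
        w[ni] <- w[ni] + w[ci]
        v[ci] <- v[ci] - v[ni]
        x[ni] <- pos
        updates <- updates + 1L
        n <- pn
      }
      x[ci] <- pos
      parent[ci] <- p
      j <- j + 1L
    }
    if (debug) {
      roots <- is.na(parent)
      stopifnot(abs(sum(w[roots]) - total_w) <= 1e-9 * max(1, abs(total_w)))
    }
  }
  list(y = v[samples + 1L],
       diagnostics = list(node_updates = updates,
                          trees_processed = length(bp) - 1L))
}

#' Quadratic form with the branch GRM
#'
#' `w1' B w2` via one matrix-free product and a dot product; symmetric in
#' its two weight vectors, and non-negative for `w1 = w2` when centered
#' (the centered branch GRM is positive semidefinite).
#'
#' @inheritParams branch_grm_vector
#' @param w1,w2 weight vectors (same length conventions as
#'   [branch_grm_vector()]).
#' @return a single number.
#' @export
branch_quadratic_form <- function(ts, w1, w2, centered = TRUE,
                                  ploidy_level = c("node", "individual")) {
  ploidy_level <- match.arg(ploidy_level)
  if (length(w1) != length(w2)) stop("bad vector")
  sum(w1 * branch_grm_vector(ts, w2, centered = centered,
                             ploidy_level = ploidy_level))
}
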