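#' Relatedness matrix container
#'
#' A dense symmetric matrix of pairwise relatedness values, tagged with how
#' it was computed: `mode` is one of `"branch"`, `"site"`, `"divergence"`,
#' `"shared_area"`, `"egrm"` or `"pedigree"`; `centered` records whether the
#' double-centering projector was applied; `ploidy_level` is `"node"`
#' (haploid genomes) or `"individual"` (diploid averages).
#'
#' @param values symmetric numeric matrix.
#' @param mode character tag (see above).
#' @param centered logical.
#' @param ploidy_level `"node"` or `"individual"`.
#' @return matrix of class `relatedness_matrix` with the tags as attributes.
#' @export
relatedness_matrix <- function(values, mode, centered = FALSE,
                               ploidy_level = "node") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, class = c("relatedness_matrix", "matrix", "array"),
            mode_tag = mode, centered = centered, ploidy_level = ploidy_level)
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("relatedness_matrix (%s, %s, %s level), %d x %d\n",
              attr(x, "mode_tag"),
              if (isTRUE(attr(x, "centered"))) "centered" else "uncentered",
              attr(x, "ploidy_level"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("... %d rows total\n", nrow(x)))
  invisible(x)
}

# double-centering projector action: M -> P M P with P = I - 11'/n
center_matrix <- function(M) {
  M <- sweep(M, 1L, rowMeans(M))
  sweep(M, 2L, colMeans(M))
}

# per-tree node-by-sample descendant indicator matrix (N x n); entry 1 iff
# the sample's lineage passes through (or is) the node in this tree
tree_sample_indicator <- function(tree, samples) {
  st <- tree_rmq(tree)
  N <- length(tree$parent)
  n <- length(samples)
  X <- matrix(0, N, n)
  X[cbind(samples + 1L, seq_len(n))] <- 1
  ord <- order(st$first, decreasing = TRUE)   # children before parents
  for (i in ord) {
    p <- tree$parent[i]
    if (!is.na(p) && any(X[i, ] != 0))
      X[p + 1L, ] <- X[p + 1L, ] + X[i, ]
  }
  X
}

tree_branch_lengths <- function(tree) {
  p <- tree$parent
  ell <- numeric(length(p))
  has <- !is.na(p)
  ell[has] <- tree$time[p[has] + 1L] - tree$time[has]
  ell
}

#' Divergence matrix
#'
#' `D[i, j]` is the genome-summed path length between samples i and j:
#' for each local tree, the distance between the two samples through their
#' MRCA, weighted by the tree's span. Computed by the straightforward
#' tree-by-tree algorithm with constant-time MRCA queries; the number of
#' MRCA queries performed is attached as a diagnostic (it grows as
#' `n_trees * n^2 / 2`).
#'
#' @param ts a `tree_sequence`.
#' @param samples 0-based sample node ids (default: all sample nodes).
#' @return a `relatedness_matrix` with mode `"divergence"` and attribute
#'   `diagnostics` (list with `mrca_queries`, `trees_processed`).
#' @export
divergence_matrix <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  D <- matrix(0, n, n)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  queries <- 0L
  trees <- local_trees(ts)
  for (tree in trees) {
    dd <- tree_depths(tree)
    m <- tree_mrca_bulk(tree_rmq(tree), samples[ij[, 1]], samples[ij[, 2]])
    queries <- queries + nrow(ij)
    shared <- ifelse(is.na(m), 0, dd$depth[m + 1L])
    d <- dd$depth[samples[ij[, 1]] + 1L] + dd$depth[samples[ij[, 2]] + 1L] -
      2 * shared
    D[ij] <- D[ij] + tree$span * d
  }
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  dimnames(D) <- list(samples, samples)
  out <- relatedness_matrix(D, "divergence")
  attr(out, "diagnostics") <- list(mrca_queries = queries,
                                   trees_processed = length(trees))
  out
}

#' Shared-area matrix
#'
#' `A[i, j]` is the total area (branch length times genomic span) of
#' branches ancestral to both samples i and j, summed across local trees;
#' `A[i, i]` is the total area above sample i. This is the uncentered
#' branch relatedness.
#'
#' @inheritParams divergence_matrix
#' @return a `relatedness_matrix` with mode `"shared_area"`.
#' @export
shared_area_matrix <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  A <- matrix(0, n, n)
  for (tree in local_trees(ts)) {
    X <- tree_sample_indicator(tree, samples)
    ell <- tree_branch_lengths(tree)
    A <- A + tree$span * crossprod(X, ell * X)
  }
  dimnames(A) <- list(samples, samples)
  relatedness_matrix(A, "shared_area")
}

#' Dense branch genetic relatedness matrix
#'
#' The branch GRM is the covariance of a hypothetical additive trait whose
#' per-branch effects have variance proportional to branch area. Uncentered
#' it equals the shared-area matrix; centered it equals both `-P D P / 2`
#' (divergence route) and `P A P` (shared-area route), with
#' `P = I - 11'/n`. Both routes are computed and cross-checked to 1e-9
#' before returning.
#'
#' @inheritParams divergence_matrix
#' @param centered apply the double-centering projector?
#' @param ploidy_level `"node"` for haploid genomes; `"individual"`
#'   averages the 2x2 block of each individual's two genomes.
#' @return a `relatedness_matrix` with mode `"branch"`.
#' @export
branch_grm_dense <- function(ts, centered = TRUE, samples = ts_samples(ts),
                             ploidy_level = c("node", "individual")) {
  ploidy_level <- match.arg(ploidy_level)
  A <- unclass(shared_area_matrix(ts, samples))
  if (!centered) {
    B <- A
  } else {
    D <- unclass(divergence_matrix(ts, samples))
    B1 <- -center_matrix(D) / 2
    B2 <- center_matrix(A)
    tol <- 1e-9 * max(1, max(abs(B2)))
    if (max(abs(B1 - B2)) > tol)
      stop("internal inconsistency: -PDP/2 and PAP routes disagree")
    B <- B2
  }
  if (ploidy_level == "individual")
    B <- collapse_to_individuals(B, ts$nodes$individual[samples + 1L])
  relatedness_matrix(B, "branch", centered = centered,
                     ploidy_level = ploidy_level)
}

# average a node-level matrix over each individual's pair of genomes:
# M_ind[a, b] = mean over the 2x2 block (the diploid dosage-proportion
# convention, which introduces a factor of 1/4 relative to node sums)
collapse_to_individuals <- function(M, individual) {
  if (any(is.na(individual)))
    stop("all samples need an individual id for individual-level output")
  ind <- sort(unique(individual))
  grp <- match(individual, ind)
  agg <- rowsum(t(rowsum(M, grp)), grp)        # block sums
  cnt <- tabulate(grp)
  out <- agg / outer(cnt, cnt)
  dimnames(out) <- list(ind, ind)
  out
}

#' Dense eGRM
#'
#' Branch GRM variant in which each branch's contribution is standardized
#' by the variance term `S(1-S)` of its descendant-sample proportion `S`,
#' and the total is scaled by the total tree area. Branches subtending all
#' samples or none (`S` of 0 or 1) carry no genotypic variance and are
#' skipped.
#'
#' @inheritParams divergence_matrix
#' @return a `relatedness_matrix` with mode `"egrm"`.
#' @export
egrm_dense <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  E <- matrix(0, n, n)
  total_area <- 0
  for (tree in local_trees(ts)) {
    X <- tree_sample_indicator(tree, samples)
    ell <- tree_branch_lengths(tree)
    total_area <- total_area + tree$span * sum(ell)
    sbar <- rowSums(X) / n
    ok <- ell > 0 & sbar > 0 & sbar < 1
    if (!any(ok)) next
    Xc <- X[ok, , drop = FALSE] - sbar[ok]
    w <- ell[ok] / (sbar[ok] * (1 - sbar[ok]))
    E <- E + tree$span * crossprod(Xc, w * Xc)
  }
  E <- E / total_area
  dimnames(E) <- list(samples, samples)
  relatedness_matrix(E, "egrm", centered = TRUE)
}

#' Genotype GRM from a 0/1 haplotype (or dosage-proportion) matrix
#'
#' The sample covariance of column-centered genotypes:
#' `C = Gc Gc' / n_L` with `Gc[i, l] = G[i, l] - mean allele frequency at
#' locus l`. No frequency weighting is applied (alpha = 0). Monomorphic
#' columns contribute exactly zero after centering.
#'
#' @param G numeric matrix, individuals by loci, entries in `[0, 1]`.
#' @param centered subtract per-locus mean frequencies (default `TRUE`)?
#' @return a `relatedness_matrix` with mode `"site"`.
#' @export
genotype_grm <- function(G, centered = TRUE) {
  G <- as.matrix(G)
  if (ncol(G) == 0) stop("no loci")
  if (centered) G <- sweep(G, 2L, colMeans(G))
  relatedness_matrix(tcrossprod(G) / ncol(G), "site", centered = centered)
}

#' Genotype GRM via expected allele-match counts
#'
#' Equivalent route to [genotype_grm()] through the match-count identity:
#' with `m(i, j)` the number of loci at which i and j carry equal alleles
#' and `U`, `V` uniform random individuals drawn with replacement,
#' `C[i, j] = E[m(i,j) - m(i,U) - m(j,V) + m(U,V)] / (2 n_L)`, computed
#' exactly by averaging over all choices of `U` and `V`. Agrees with
#' [genotype_grm()] to machine precision.
#'
#' @param G 0/1 matrix, individuals by loci.
#' @return a `relatedness_matrix` with mode `"site"`.
#' @export
match_count_grm <- function(G) {
  G <- as.matrix(G)
  if (ncol(G) == 0) stop("no loci")
  if (!all(G %in% c(0, 1))) stop("match counting requires 0/1 genotypes")
  M <- tcrossprod(G) + tcrossprod(1 - G)       # pairwise match counts
  rm_ <- rowMeans(M)
  C <- (M - outer(rm_, rep(1, nrow(M))) - outer(rep(1, nrow(M)), rm_) +
          mean(M)) / (2 * ncol(G))
  relatedness_matrix(C, "site", centered = TRUE)
}

#' Genome-averaged mean TMRCA of a set of contemporaneous nodes
#'
#' For every unordered pair in `node_set`, the span-weighted average over
#' local trees of the time from the pair back to their most recent common
#' ancestor; the result is the mean over pairs. All nodes must be at the
#' same time (the TMRCA is measured from that time). For sample nodes of a
#' fully coalesced ARG this equals half the mean pairwise branch
#' divergence. For ancestral nodes (e.g. pedigree founders of a
#' gene-dropped, recapitated ARG), intervals on which either node carries
#' no recorded lineage — or on which the pair has no common root — are
#' excluded from the span weighting, since the ARG does not record the
#' genealogy of non-ancestral material there.
#'
#' @param ts a `tree_sequence`.
#' @param node_set at least two 0-based node ids at a common time.
#' @return a single non-negative number (generations).
#' @export
mean_tmrca <- function(ts, node_set) {
  node_set <- as.integer(node_set)
  if (length(node_set) < 2) stop("need at least two nodes")
  t0 <- ts$nodes$time[node_set + 1L]
  if (max(t0) - min(t0) > 0) stop("contemporaneous nodes required")
  t0 <- t0[1]
  ij <- utils::combn(node_set, 2L)
  acc <- numeric(ncol(ij))
  wt <- numeric(ncol(ij))
  for (tree in local_trees(ts)) {
    m <- tree_mrca_bulk(tree_rmq(tree), ij[1, ], ij[2, ])
    present <- !is.na(tree$parent) | tree$num_children > 0 |
      ts$nodes$is_sample
    ok <- !is.na(m) & present[ij[1, ] + 1L] & present[ij[2, ] + 1L]
    acc[ok] <- acc[ok] + tree$span * (tree$time[m[ok] + 1L] - t0)
    wt[ok] <- wt[ok] + tree$span
  }
  if (all(wt == 0))
    stop("no node pair shares any recorded genealogy")
  mean(acc[wt > 0] / wt[wt > 0])
}
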