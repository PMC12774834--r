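#' Simulate additive traits from genotypes
#'
#' Draws per-locus derived-allele effects independently from a zero-mean
#' law with variance `sigma2` (ancestral alleles have effect 0) and sums
#' them per individual: `Z(i) = sum_l effect(l) * G[i, l]`. For diploid
#' dosage-proportion matrices this is the genome-copy average by
#' construction. The law is `"normal"` by default; `"twopoint"` uses
#' +/- sqrt(sigma2) with equal probability, demonstrating that the
#' covariance identities only need the first two moments.
#'
#' @param G genotype matrix, individuals by loci, entries in `[0, 1]`.
#' @param sigma2 per-mutation effect variance.
#' @param effect_law `"normal"` or `"twopoint"`.
#' @param n_reps number of independent effect draws.
#' @param seed integer RNG seed.
#' @return matrix of genetic values, individuals by replicates.
#' @export
simulate_site_trait <- function(G, sigma2 = 1,
                                effect_law = c("normal", "twopoint"),
                                n_reps = 1, seed) {
  effect_law <- match.arg(effect_law)
  set.seed(seed)
  G <- as.matrix(G)
  E <- draw_effects(ncol(G) * n_reps, sigma2, effect_law)
  G %*% matrix(E, ncol(G), n_reps)
}

draw_effects <- function(n, sigma2, law) {
  if (sigma2 == 0) return(numeric(n))
  switch(law,
         normal = stats::rnorm(n, 0, sqrt(sigma2)),
         twopoint = sample(c(-1, 1), n, replace = TRUE) * sqrt(sigma2))
}

#' Simulate additive traits from ARG branches
#'
#' In `"edge"` mode, every branch of every local tree receives an
#' independent zero-mean effect with variance `sigma2` times the branch's
#' area (length times span), and `Z(i)` sums the effects on branches
#' ancestral to sample i — the generative model whose trait covariance is
#' the branch GRM. In `"mutation"` mode the effects are realized through
#' an explicit infinite-sites mutation drop at rate `mu` with per-mutation
#' effect variance `sigma2 / mu`, whose covariance matches the branch GRM
#' in expectation over the mutation process.
#'
#' @param ts a `tree_sequence`.
#' @param sigma2 effect variance scale.
#' @param effect_law `"normal"` or `"twopoint"`.
#' @param mode `"edge"` (branch-area variance) or `"mutation"`.
#' @param mu mutation rate for `"mutation"` mode.
#' @param n_reps number of independent draws.
#' @param seed integer RNG seed.
#' @return matrix of genetic values, samples by replicates.
#' @export
simulate_branch_trait <- function(ts, sigma2 = 1,
                                  effect_law = c("normal", "twopoint"),
                                  mode = c("edge", "mutation"), mu = NULL,
                                  n_reps = 1, seed) {
  effect_law <- match.arg(effect_law)
  mode <- match.arg(mode)
  samples <- ts_samples(ts)
  if (mode == "mutation") {
    stopifnot(!is.null(mu), mu > 0)
    tsm <- drop_mutations(ts, mu, seed = seed)
    G <- genotype_matrix(tsm, samples)
    return(simulate_site_trait(G, sigma2 / mu, effect_law, n_reps,
                               seed = seed + 1L))
  }
  set.seed(seed)
  Z <- matrix(0, length(samples), n_reps)
  for (tree in local_trees(ts)) {
    X <- tree_sample_indicator(tree, samples)
    ell <- tree_branch_lengths(tree)
    hit <- which(ell > 0 & rowSums(X) > 0)
    if (!length(hit)) next
    sdv <- sqrt(sigma2 * ell[hit] * tree$span)
    E <- matrix(draw_effects(length(hit) * n_reps, 1, effect_law),
                length(hit), n_reps) * sdv
    Z <- Z + crossprod(X[hit, , drop = FALSE], E)
  }
  rownames(Z) <- samples
  Z
}

#' Empirical covariance of simulated trait replicates
#'
#' Given a matrix of independent trait draws (individuals by replicates),
#' estimates the covariance matrix of the (optionally sample-mean-centered)
#' genetic values, with elementwise standard errors from batching the
#' replicates.
#'
#' @param Z matrix of trait values, individuals by replicates.
#' @param center subtract the per-replicate mean over individuals first?
#' @param n_batches number of batches for the SE estimate.
#' @return list with `cov` (matrix) and `se` (matrix of standard errors).
#' @export
empirical_trait_covariance <- function(Z, center = TRUE, n_batches = 100) {
  Z <- as.matrix(Z)
  reps <- ncol(Z)
  stopifnot(reps >= n_batches)
  if (center) Z <- sweep(Z, 2L, colMeans(Z))
  batch <- rep(seq_len(n_batches), length.out = reps)
  n <- nrow(Z)
  means <- array(0, c(n, n, n_batches))
  for (b in seq_len(n_batches)) {
    Zb <- Z[, batch == b, drop = FALSE]
    means[, , b] <- tcrossprod(Zb) / ncol(Zb)
  }
  covm <- apply(means, c(1, 2), mean)
  se <- apply(means, c(1, 2), stats::sd) / sqrt(n_batches)
  dimnames(covm) <- dimnames(se) <- list(rownames(Z), rownames(Z))
  list(cov = covm, se = se)
}
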