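# Brute-force oracles, deliberately independent of the package's fast
# implementations: ancestor-set walks instead of MRCA structures, explicit
# lineage-path enumeration instead of the tabular kinship recursion.

# ancestors of node u in a local tree, 0-based, starting with u itself
oracle_ancestors <- function(tree, u) {
  out <- u
  while (!is.na(tree$parent[u + 1L])) {
    u <- tree$parent[u + 1L]
    out <- c(out, u)
  }
  out
}

oracle_mrca <- function(tree, u, v) {
  au <- oracle_ancestors(tree, u)
  av <- oracle_ancestors(tree, v)
  hit <- au[au %in% av]
  if (length(hit)) hit[1] else NA_integer_
}

oracle_branch_above <- function(tree, n) {
  p <- tree$parent[n + 1L]
  if (is.na(p)) 0 else tree$time[p + 1L] - tree$time[n + 1L]
}

# total area of branches ancestral to both i and j, by ancestor-set
# intersection per tree
oracle_shared_area <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  A <- matrix(0, n, n)
  for (tree in local_trees(ts)) {
    anc <- lapply(samples, function(s) oracle_ancestors(tree, s))
    for (i in seq_len(n)) for (j in i:n) {
      common <- intersect(anc[[i]], anc[[j]])
      val <- sum(vapply(common, function(a) oracle_branch_above(tree, a),
                        numeric(1)))
      A[i, j] <- A[j, i] <- A[i, j] + tree$span * val
    }
  }
  A
}

# genome-summed path length between sample pairs: branches above nodes in
# the symmetric difference of the two ancestor sets
oracle_divergence <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  D <- matrix(0, n, n)
  for (tree in local_trees(ts)) {
    anc <- lapply(samples, function(s) oracle_ancestors(tree, s))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      sd_ <- c(setdiff(anc[[i]], anc[[j]]), setdiff(anc[[j]], anc[[i]]))
      val <- sum(vapply(sd_, function(a) oracle_branch_above(tree, a),
                        numeric(1)))
      D[i, j] <- D[j, i] <- D[i, j] + tree$span * val
    }
  }
  D
}

# per-branch accumulation of the standardized-branch GRM
oracle_egrm <- function(ts, samples = ts_samples(ts)) {
  n <- length(samples)
  E <- matrix(0, n, n)
  total_area <- 0
  for (tree in local_trees(ts)) {
    anc <- lapply(samples, function(s) oracle_ancestors(tree, s))
    for (node in seq_along(tree$parent) - 1L) {
      ell <- oracle_branch_above(tree, node)
      if (ell == 0) next
      total_area <- total_area + tree$span * ell
      s_ind <- vapply(anc, function(a) node %in% a, logical(1))
      sbar <- mean(s_ind)
      if (sbar == 0 || sbar == 1) next
      E <- E + tree$span * ell * outer(s_ind - sbar, s_ind - sbar) /
        (sbar * (1 - sbar))
    }
  }
  E / total_area
}

# Wright path-counting kinship: sum over common ancestors and pairs of
# node-disjoint lineage paths of (1/2)^(links + 1) * (1 + f_ancestor)
oracle_kinship <- function(ped) {
  d <- ped$individuals
  n <- nrow(d)
  memo <- vector("list", n)
  get_paths <- function(i) {                 # 0-based id
    if (!is.null(memo[[i + 1L]])) return(memo[[i + 1L]])
    out <- list(i)
    for (par in c(d$father[i + 1L], d$mother[i + 1L]))
      if (!is.na(par)) for (p in get_paths(par)) out <- c(out, list(c(i, p)))
    memo[[i + 1L]] <<- out
    out
  }
  f <- numeric(n)
  th <- matrix(0, n, n)
  pairk <- function(i, j) {
    if (i == j) return((1 + f[i + 1L]) / 2)
    tot <- 0
    for (p1 in get_paths(i)) for (p2 in get_paths(j)) {
      a <- p1[length(p1)]
      if (p2[length(p2)] != a) next
      if (length(intersect(p1, p2)) != 1L) next
      tot <- tot + 0.5^(length(p1) + length(p2) - 1) * (1 + f[a + 1L])
    }
    tot
  }
  for (i in seq_len(n)) {
    fa <- d$father[i]; mo <- d$mother[i]
    f[i] <- if (is.na(fa) || is.na(mo)) 0 else pairk(fa, mo)
    for (j in seq_len(i)) th[i, j] <- th[j, i] <- pairk(i - 1L, j - 1L)
  }
  th
}

# small random simulated ARG for property tests
random_ts <- function(seed, n = NULL, trees_target = 20) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:32, 1)
  sim_coalescent_arg(n, sequence_length = 100, Ne = 50,
                     recombination_rate = trees_target / 100 / (4 * 50 * log(n)),
                     seed = seed + 1000L)
}

expect_symmetric_psd <- function(M, tol = 1e-9) {
  expect_lt(max(abs(M - t(M))), 1e-12 * max(1, max(abs(M))))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(1, sum(diag(M))))
}

# drop relatedness_matrix tags/dimnames for plain numeric comparison
strip <- function(x) {
  x <- unclass(x)
  array(as.numeric(x), dim(x))
}

canonical_pedigree <- function() {
  # founders 0-4; full sibs 5,6 (of 0 x 1); 7 = half sib of 5 via father 0;
  # first cousins 8 (of 5 x 3) and 9 (of 6 x 4); 10 = child of the
  # full-sib mating 5 x 6
  pedigree(data.frame(
    id = 0:10,
    father = c(NA, NA, NA, NA, NA, 0, 0, 0, 5, 6, 5),
    mother = c(NA, NA, NA, NA, NA, 1, 1, 2, 3, 4, 6),
    generation = c(0, 0, 0, 0, 0, 1, 1, 1, 2, 2, 2)),
    probands = c(8, 9, 10))
}

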