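trio_pedigree <- function() {
  pedigree(data.frame(id = 0:2, father = c(NA, NA, 0),
                      mother = c(NA, NA, 1), generation = c(0, 0, 1)),
           probands = 2)
}

sib_pedigree <- function() {
  pedigree(data.frame(id = 0:3, father = c(NA, NA, 0, 0),
                      mother = c(NA, NA, 1, 1), generation = c(0, 0, 1, 1)),
           probands = 2:3)
}

test_that("pedigree simulation respects structure, regions and pairing errors", {
  expect_error(sim_pedigree(5, 2, n_regions = 1, seed = 1), "pairing")
  ped <- sim_pedigree(8, 2, n_regions = 2, migration_prob = 0, seed = 3)
  d <- ped$individuals
  expect_true(all(is.na(d$father) == (d$generation == 0)))
  expect_true(all(d$father[!is.na(d$father)] < d$id[!is.na(d$father)]))
  # without migration every proband's ancestors share its region
  anc_region <- function(i) {
    out <- character(0); stack <- i
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      out <- c(out, d$region[x + 1L])
      for (p in c(d$father[x + 1L], d$mother[x + 1L]))
        if (!is.na(p)) stack <- c(stack, p)
    }
    unique(out)
  }
  for (p in ped$probands) expect_equal(length(anc_region(p)), 1L)
  # a deeper pedigree remains acyclic with parent precedence (10 generations)
  ped10 <- sim_pedigree(8, 10, offspring_mean = 2.5, seed = 5)
  d10 <- ped10$individuals
  expect_true(all(is.na(d10$father) | d10$father < d10$id))
  expect_true(all(is.na(d10$mother) | d10$mother < d10$id))
  expect_equal(max(d10$generation), 10)
})

test_that("gene dropping covers proband genomes with founder ancestry", {
  ts <- gene_drop_arg(trio_pedigree(), 50, seed = 2)
  expect_equal(nrow(ts_validate(ts)), 0)
  samp <- ts_samples(ts)
  expect_equal(length(samp), 2)
  founder_times <- ts$nodes$time[!ts$nodes$is_sample]
  for (tree in local_trees(ts)) {
    for (s in samp) {
      anc <- oracle_ancestors(tree, s)
      top <- anc[length(anc)]
      expect_equal(ts$nodes$time[top + 1L], 1)   # a founder node roots it
    }
  }
  # determinism
  ts2 <- gene_drop_arg(trio_pedigree(), 50, seed = 2)
  expect_identical(ts$edges, ts2$edges)
})

test_that("sib maternal copies coalesce in the mother at half of loci", {
  ped <- sib_pedigree()
  reps <- 2000
  hits <- logical(reps)
  for (s in seq_len(reps)) {
    ts <- gene_drop_arg(ped, 0.01, seed = s)     # ~single locus
    nm <- attr(ts, "node_map")
    m1 <- nm[2 * 2 + 1 + 1L]                     # maternal node of sib 2
    m2 <- nm[2 * 3 + 1 + 1L]                     # maternal node of sib 3
    tree <- local_trees(ts)[[1]]
    mr <- oracle_mrca(tree, m1, m2)
    hits[s] <- !is.na(mr) && ts$nodes$individual[mr + 1L] %in% 1L &&
      ts$nodes$time[mr + 1L] == 1
  }
  se <- sd(hits) / sqrt(reps)
  expect_lt(abs(mean(hits) - 0.5), 4 * se)
})

test_that("crossover counts are Poisson with mean 0.01 per cM", {
  reps <- 1000
  counts <- vapply(seq_len(reps), function(s) {
    ts <- gene_drop_arg(trio_pedigree(), 100, seed = 10000 + s)
    # the proband's two meioses produce all breakpoints of this ARG
    (num_trees(ts) - 1) / 2
  }, numeric(1))
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - 1), 4 * se)
})

test_that("simplification drops unary interiors but keeps founder roots", {
  ped <- sim_pedigree(8, 3, seed = 9)
  ts <- gene_drop_arg(ped, 50, seed = 9)
  expect_equal(nrow(ts_validate(ts)), 0)
  gmax <- max(ped$individuals$generation)
  for (tree in local_trees(ts)) {
    X <- arborelate:::tree_sample_indicator(tree, ts_samples(ts))
    roots <- which(is.na(tree$parent) & rowSums(X) > 0) - 1L
    # every sample-bearing root is a founder-generation node
    expect_true(all(ts$nodes$time[roots + 1L] == gmax))
    # interior (non-root, non-sample) nodes are coalescent: >= 2 children
    interior <- which(!is.na(tree$parent) &
                        !ts$nodes$is_sample[seq_along(tree$parent)] &
                        rowSums(X) > 0) - 1L
    expect_true(all(tree$num_children[interior + 1L] >= 2))
  }
})

test_that("recapitation yields single-rooted trees and older founder TMRCAs", {
  ped <- sim_pedigree(8, 3, seed = 13)
  ts <- gene_drop_arg(ped, 50, seed = 13)
  tsr <- recapitate(ts, Ne = 100, seed = 14)
  expect_equal(nrow(ts_validate(tsr)), 0)
  samp <- ts_samples(tsr)
  for (tree in local_trees(tsr)) {
    X <- arborelate:::tree_sample_indicator(tree, samp)
    expect_equal(sum(is.na(tree$parent) & rowSums(X) > 0), 1)
  }
  # original tables are preserved as a prefix
  expect_identical(tsr$nodes$time[seq_len(nrow(ts$nodes))], ts$nodes$time)
  founder_time <- max(ped$individuals$generation)
  founders <- ts$nodes$id[ts$nodes$time == founder_time]
  if (length(founders) >= 2) {
    tm <- mean_tmrca(tsr, founders)
    expect_gte(tm, 0)
  }
  # an already fully coalesced tree sequence is returned unchanged
  ts1 <- sim_coalescent_arg(4, 100, Ne = 20, recombination_rate = 1e-3,
                            seed = 15)
  tsr1 <- recapitate(ts1, Ne = 20, seed = 16)
  expect_identical(tsr1$edges, ts1$edges)
  expect_identical(tsr1$nodes, ts1$nodes)
})

test_that("gene-dropped ARG TMRCA patterns reproduce pedigree kinship", {
  # Monte Carlo IBD at a single locus: probability that two probands'
  # random genome copies coalesce within the pedigree equals 2 * theta...
  # checked for full sibs against the tabular value via many gene drops
  ped <- sib_pedigree()
  th <- kinship_matrix(ped)
  reps <- 1500
  ibd <- numeric(reps)
  gmax <- 1
  for (s in seq_len(reps)) {
    ts <- gene_drop_arg(ped, 1e-4, seed = 50000 + s)
    tree <- local_trees(ts)[[1]]
    nm <- attr(ts, "node_map")
    a <- nm[2 * 2 + sample(0:1, 1) + 1L]      # random copy from sib 2
    b <- nm[2 * 3 + sample(0:1, 1) + 1L]      # random copy from sib 3
    mr <- oracle_mrca(tree, a, b)
    # all nodes of the (un-recapitated) drop are pedigree genomes, so
    # sharing an ancestor at all means IBD within the pedigree
    ibd[s] <- !is.na(mr) && ts$nodes$time[mr + 1L] <= gmax
  }
  se <- sd(ibd) / sqrt(reps)
  expect_lt(abs(mean(ibd) - th[3, 4]), 3 * se)
})
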