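tol <- function(x, y, t = 1e-12) expect_lt(max(abs(x - y)), t)

test_that("divergence matrix matches hand-computed fixtures and the oracle", {
  D1 <- divergence_matrix(fixture_t1())
  tol(unclass(D1), matrix(c(0, 20, 20, 0), 2, 2))
  D2 <- divergence_matrix(fixture_t2())
  want <- matrix(c(0, 30, 40, 30, 0, 35, 40, 35, 0), 3, 3)
  tol(unclass(D2), want)
  expect_true(all(diag(D2) == 0))
  ts <- random_ts(21)
  tol(strip(divergence_matrix(ts)), oracle_divergence(ts), 1e-9)
})

test_that("shared-area matrix matches fixtures, the oracle, and the R(i)+R(j) identity", {
  A1 <- shared_area_matrix(fixture_t1())
  tol(unclass(A1), diag(c(10, 10)))
  A2 <- strip(shared_area_matrix(fixture_t2()))
  want <- matrix(c(20, 5, 0, 5, 20, 2.5, 0, 2.5, 20), 3, 3)
  tol(A2, want)
  D2 <- strip(divergence_matrix(fixture_t2()))
  # R(i) + R(j) = 2 A(i,j) + D(i,j), with R on the shared-area diagonal
  for (i in 1:3) for (j in 1:3)
    expect_lt(abs(A2[i, i] + A2[j, j] - 2 * A2[i, j] - D2[i, j]), 1e-12)
  ts <- random_ts(22)
  tol(strip(shared_area_matrix(ts)), oracle_shared_area(ts), 1e-9)
})

test_that("branch GRM: uncentered equals shared area; centered equals -PDP/2 = PAP", {
  t1 <- fixture_t1()
  tol(strip(branch_grm_dense(t1, centered = FALSE)), diag(c(10, 10)))
  tol(strip(branch_grm_dense(t1)), matrix(c(5, -5, -5, 5), 2, 2))
  for (seed in 301:310) {
    ts <- random_ts(seed)
    A <- strip(shared_area_matrix(ts))
    expect_equal(strip(branch_grm_dense(ts, centered = FALSE)), A)
    B <- strip(branch_grm_dense(ts))     # internally asserts -PDP/2 == PAP
    n <- nrow(B)
    P <- diag(n) - matrix(1 / n, n, n)
    tol(B, P %*% A %*% P, 1e-9)
    expect_lt(max(abs(rowSums(B))), 1e-9 * max(1, max(abs(B))))
    expect_symmetric_psd(B)
  }
})

test_that("eGRM matches the worked fixture and brute-force branch accumulation", {
  tol(strip(egrm_dense(fixture_t1())), matrix(c(1, -1, -1, 1), 2, 2))
  tol(strip(egrm_dense(fixture_t2())), oracle_egrm(fixture_t2()), 1e-12)
  ts <- random_ts(23)
  tol(strip(egrm_dense(ts)), oracle_egrm(ts), 1e-9)
  # a tree sequence where every branch subtends all samples: two samples
  # whose only branches hang from the root cover both => the single-sample
  # branches have sbar in (0,1); instead make every branch whole-sample by
  # sampling the root's children as one clade below a unary-free chain
  chain <- tree_sequence(
    nodes = data.frame(id = 0:1, time = c(0, 1),
                       is_sample = c(TRUE, FALSE)),
    edges = data.frame(left = 0, right = 10, parent = 1, child = 0),
    sequence_length = 10)
  # the lone branch subtends the full (single-member) sample set
  expect_equal(max(abs(strip(egrm_dense(chain, samples = 0L)))), 0)
})

test_that("genotype GRM and match-count GRM agree with hand values and each other", {
  G <- rbind(c(0, 1), c(1, 1))
  want <- matrix(c(0.125, -0.125, -0.125, 0.125), 2, 2)
  tol(strip(genotype_grm(G)), want)
  tol(strip(match_count_grm(G)), want)
  expect_error(genotype_grm(matrix(numeric(0), 2, 0)), "no loci")
  # monomorphic columns contribute nothing
  G2 <- cbind(G, 1, 0)
  tol(strip(genotype_grm(G2)), strip(genotype_grm(G)) * ncol(G) / ncol(G2))
  # identical rows give identical entries
  G3 <- rbind(G, G[2, ])
  C3 <- strip(genotype_grm(G3))
  expect_equal(C3[2, 2], C3[2, 3])
  # equivalence on random matrices
  for (seed in 1:5) {
    set.seed(seed)
    G4 <- matrix(rbinom(60, 1, 0.4), 6, 10)
    tol(strip(genotype_grm(G4)), strip(match_count_grm(G4)), 1e-12)
  }
  # all-identical rows: zero matrix
  tol(strip(match_count_grm(rbind(c(1, 0), c(1, 0)))), matrix(0, 2, 2))
})

test_that("mean TMRCA matches fixtures and half the mean divergence", {
  expect_equal(mean_tmrca(fixture_t1(), c(0, 1)), 1)
  t2 <- fixture_t2()
  expect_equal(mean_tmrca(t2, 0:2), 1.75)
  D <- strip(divergence_matrix(t2))
  expect_equal(mean_tmrca(t2, 0:2),
               mean(D[upper.tri(D)]) / (2 * t2$sequence_length))
  ts <- tree_sequence(
    nodes = data.frame(id = 0:2, time = c(0, 1, 2),
                       is_sample = c(TRUE, TRUE, FALSE)),
    edges = data.frame(left = 0, right = 1, parent = c(2, 2), child = c(0, 1)),
    sequence_length = 1)
  expect_error(mean_tmrca(ts, c(0, 1)), "contemporaneous")
})

test_that("individual-level branch GRM averages the 2x2 genome blocks", {
  ts <- random_ts(31, n = 8)
  ts$nodes$individual[ts_samples(ts) + 1L] <- rep(0:3, each = 2)
  Bn <- strip(branch_grm_dense(ts))
  Bi <- strip(branch_grm_dense(ts, ploidy_level = "individual"))
  for (a in 1:4) for (b in 1:4) {
    blk <- Bn[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)]
    expect_equal(Bi[a, b], mean(blk))
  }
})
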