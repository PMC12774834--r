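test_that("fixtures load, validate and report their local-tree structure", {
  t1 <- fixture_t1()
  expect_equal(num_trees(t1), 1)
  expect_equal(nrow(ts_validate(t1)), 0)
  t2 <- fixture_t2()
  expect_equal(num_trees(t2), 2)
  expect_equal(ts_breakpoints(t2), c(0, 5, 10))
  expect_equal(nrow(ts_validate(t2)), 0)
  tr <- local_trees(t1)[[1]]
  expect_equal(tr$parent, c(2L, 2L, NA_integer_))
  expect_equal(tr$span, 10)
})

test_that("invalid tables are rejected with the documented labels", {
  nodes <- data.frame(id = 0:2, time = c(0, 0, 0),
                      is_sample = c(TRUE, TRUE, FALSE))
  edges <- data.frame(left = 0, right = 10, parent = c(2, 2), child = c(0, 1))
  expect_error(tree_sequence(nodes, edges, NULL, 10), "time order")
  nodes$time <- c(0, 0, 1)
  bad <- rbind(edges, data.frame(left = 0, right = 10, parent = 2, child = 0))
  expect_error(tree_sequence(nodes, bad, NULL, 10), "edge overlap")
  bad2 <- edges; bad2$right[1] <- 0
  expect_error(tree_sequence(nodes, bad2, NULL, 10), "bad interval")
  # report mode lists the violation instead of stopping
  ts <- fixture_t1()
  ts$edges <- rbind(ts$edges,
                    data.frame(left = 0, right = 10, parent = 0, child = 2))
  ts <- arborelate:::ts_build_indexes(ts)
  rep <- ts_validate(ts)
  expect_true("time order" %in% rep$rule)
})

test_that("TSV round trip reproduces the tables", {
  dir <- tempfile()
  t2 <- fixture_t2()
  t2$sites <- data.frame(position = c(1.5, 7), node = c(0L, 5L),
                         derived_state = "1")
  write_tree_sequence(t2, dir)
  back <- read_tree_sequence_dir(dir)
  expect_equal(back$nodes, t2$nodes)
  expect_equal(back$edges, t2$edges)
  expect_equal(back$sites, t2$sites)
  expect_equal(back$sequence_length, t2$sequence_length)
})

test_that("tree stream spans conserve sequence length and edge order on disk is irrelevant", {
  ts <- random_ts(4)
  spans <- vapply(local_trees(ts), `[[`, numeric(1), "span")
  expect_equal(sum(spans), ts$sequence_length)
  # shuffling edge rows gives an identical tree stream after indexing
  set.seed(1)
  shuf <- tree_sequence(ts$nodes, ts$edges[sample(nrow(ts$edges)), ],
                        NULL, ts$sequence_length)
  p1 <- lapply(local_trees(ts), `[[`, "parent")
  p2 <- lapply(local_trees(shuf), `[[`, "parent")
  expect_identical(p1, p2)
})

test_that("a child can have different parents in different local trees", {
  trees <- local_trees(fixture_t2())
  expect_equal(trees[[1]]$parent[1 + 1L], 3L)
  expect_equal(trees[[2]]$parent[1 + 1L], 5L)
})

test_that("MRCA queries match the ancestor-set oracle on random trees", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(2:64, 1)
    ts <- sim_coalescent_arg(n, 10, Ne = 10, seed = seed)
    tree <- local_trees(ts)[[1]]
    samp <- ts_samples(ts)
    pairs <- utils::combn(samp, 2)
    got <- arborelate:::tree_mrca_bulk(arborelate:::tree_rmq(tree),
                                       pairs[1, ], pairs[2, ])
    want <- mapply(function(u, v) oracle_mrca(tree, u, v),
                   pairs[1, ], pairs[2, ])
    expect_identical(got, as.integer(want))
  }
})

test_that("MRCA handles identity, fixtures and unknown nodes", {
  t1 <- local_trees(fixture_t1())[[1]]
  expect_equal(tree_mrca(t1, 0, 1), 2L)
  expect_equal(tree_mrca(t1, 0, 0), 0L)
  t2trees <- local_trees(fixture_t2())
  expect_equal(tree_mrca(t2trees[[1]], 0, 1), 3L)
  expect_equal(tree_mrca(t2trees[[2]], 0, 1), 4L)
  expect_error(tree_mrca(t1, 0, 99), "no such node")
})

test_that("branch lengths above nodes follow parent times, zero at roots", {
  t1 <- local_trees(fixture_t1())[[1]]
  expect_equal(branch_length_above(t1, 0), 1)
  expect_equal(branch_length_above(t1, 2), 0)
  t2b <- local_trees(fixture_t2())[[2]]
  expect_equal(branch_length_above(t2b, 5), 0.5)
})

test_that("root-path identity d(i,r) + d(j,r) = 2 b(i,j) + d(i,j) holds per tree", {
  for (seed in c(11, 12, 13)) {
    ts <- random_ts(seed)
    samp <- ts_samples(ts)
    for (tree in local_trees(ts)) {
      anc <- lapply(samp, function(s) oracle_ancestors(tree, s))
      bl <- function(set) sum(vapply(set, function(a)
        oracle_branch_above(tree, a), numeric(1)))
      for (i in seq_along(samp)) for (j in seq_along(samp)) {
        if (i >= j) next
        d_ir <- bl(anc[[i]])
        d_jr <- bl(anc[[j]])
        b_ij <- bl(intersect(anc[[i]], anc[[j]]))
        d_ij <- bl(c(setdiff(anc[[i]], anc[[j]]), setdiff(anc[[j]], anc[[i]])))
        expect_lt(abs(d_ir + d_jr - 2 * b_ij - d_ij), 1e-12)
      }
    }
  }
})
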