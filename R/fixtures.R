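#' Built-in worked-example tree sequences
#'
#' `fixture_t1()` is the smallest non-trivial ARG: two sample genomes (nodes
#' 0 and 1 at time 0) joined by a root (node 2 at time 1) on a genome of
#' length 10, a single local tree. `fixture_t2()` has three samples and two
#' local trees with breakpoints \{0, 5, 10\}: on `[0, 5)` samples 0 and 1
#' coalesce first (node 3, time 1), on `[5, 10)` samples 1 and 2 coalesce
#' first (node 5, time 1.5), with a shared root (node 4, time 2). They are
#' used throughout the documentation and tests as hand-checkable instances.
#'
#' @return a validated [tree_sequence()].
#' @export
fixture_t1 <- function() {
  tree_sequence(
    nodes = data.frame(id = 0:2, time = c(0, 0, 1),
                       is_sample = c(TRUE, TRUE, FALSE)),
    edges = data.frame(left = 0, right = 10, parent = c(2, 2), child = c(0, 1)),
    sequence_length = 10)
}

#' @rdname fixture_t1
#' @export
fixture_t2 <- function() {
  tree_sequence(
    nodes = data.frame(id = 0:5, time = c(0, 0, 0, 1, 2, 1.5),
                       is_sample = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    edges = data.frame(
      left   = c(0, 0, 0, 0, 5, 5, 5, 5),
      right  = c(5, 5, 5, 5, 10, 10, 10, 10),
      parent = c(3, 3, 4, 4, 5, 5, 4, 4),
      child  = c(0, 1, 3, 2, 1, 2, 5, 0)),
    sequence_length = 10)
}
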