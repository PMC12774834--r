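#' Construct a succinct tree sequence
#'
#' A succinct tree sequence encodes an ancestral recombination graph (ARG) as
#' three tables. Nodes are haploid genomes with a birth time (generations
#' before present); edges record that a `child` node inherited the genome
#' interval `[left, right)` from a `parent` node; sites place derived
#' mutations on nodes at genomic positions. The sequence of local trees along
#' the genome is recovered by inserting and removing edges left to right.
#'
#' Node ids are 0-based and must be consecutive. Positions are real-valued,
#' 0-based, half-open. Node times are in generations; parents must be
#' strictly older than their children.
#'
#' @param nodes data.frame with columns `id`, `time`, `is_sample` (logical or
#'   0/1) and optionally `individual` (0-based individual id, `NA`/-1 for
#'   none). Rows must be ordered by `id`.
#' @param edges data.frame with columns `left`, `right`, `parent`, `child`.
#' @param sites data.frame with columns `position`, `node`, `derived_state`,
#'   or `NULL` for no sites.
#' @param sequence_length total genome length (same units as edge positions).
#' @param check if `TRUE` (default), invariants are verified and the first
#'   violation raised as an error.
#' @return An object of class `tree_sequence`: a list with the validated
#'   tables, `sequence_length`, and the two sorted edge indexes
#'   (`insertion`, `removal`) used for left-to-right tree building.
#' @seealso [load_tree_sequence()], [local_trees()], [ts_validate()]
#' @export
tree_sequence <- function(nodes, edges, sites = NULL, sequence_length,
                          check = TRUE) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$individual)) nodes$individual <- NA_integer_
  nodes$individual[!is.na(nodes$individual) & nodes$individual < 0] <- NA_integer_
  nodes <- data.frame(id = as.integer(nodes$id), time = as.numeric(nodes$time),
                      is_sample = as.logical(nodes$is_sample),
                      individual = as.integer(nodes$individual))
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(left = numeric(0), right = numeric(0),
                        parent = integer(0), child = integer(0))
  } else {
    edges <- as.data.frame(edges)
    edges <- data.frame(left = as.numeric(edges$left),
                        right = as.numeric(edges$right),
                        parent = as.integer(edges$parent),
                        child = as.integer(edges$child))
  }
  if (is.null(sites) || nrow(as.data.frame(sites)) == 0) {
    sites <- data.frame(position = numeric(0), node = integer(0),
                        derived_state = character(0))
  } else {
    sites <- as.data.frame(sites)
    sites <- data.frame(position = as.numeric(sites$position),
                        node = as.integer(sites$node),
                        derived_state = as.character(sites$derived_state))
    sites <- sites[order(sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  }
  ts <- structure(list(sequence_length = as.numeric(sequence_length),
                       nodes = nodes, edges = edges, sites = sites),
                  class = "tree_sequence")
  ts <- ts_build_indexes(ts)
  if (check) {
    report <- ts_validate(ts)
    if (nrow(report) > 0)
      stop(sprintf("invalid tree sequence: %s (%s)",
                   report$rule[1], report$detail[1]), call. = FALSE)
  }
  ts
}

ts_build_indexes <- function(ts) {
  e <- ts$edges
  pt <- ts$nodes$time[e$parent + 1L]
  ts$insertion <- order(e$left, pt, e$parent, e$child)
  ts$removal <- order(e$right, -pt, e$parent, e$child)
  ts
}

#' Validate a tree sequence and report every invariant violation
#'
#' Runs all structural checks (node id/time sanity, edge interval and time
#' ordering, per-child interval overlap, site ordering and references) and
#' returns a report rather than stopping at the first problem. An empty
#' report means the object is valid.
#'
#' @param ts a `tree_sequence` (or an unchecked one built with
#'   `check = FALSE`).
#' @return data.frame with columns `rule` (short machine-readable label,
#'   e.g. `"time order"`, `"edge overlap"`, `"bad interval"`) and `detail`.
#' @export
ts_validate <- function(ts) {
  bad <- function(rule, detail) data.frame(rule = rule, detail = detail)
  out <- list()
  n <- ts$nodes
  e <- ts$edges
  L <- ts$sequence_length
  if (!is.finite(L) || L <= 0)
    out[[length(out) + 1L]] <- bad("bad sequence length", sprintf("L = %g", L))
  if (nrow(n) == 0 || !identical(n$id, seq_len(nrow(n)) - 1L))
    out[[length(out) + 1L]] <- bad("node ids", "ids must be consecutive from 0")
  if (any(!is.finite(n$time)) || any(n$time < 0))
    out[[length(out) + 1L]] <- bad("node time", "times must be finite and >= 0")
  if (nrow(e) > 0) {
    if (any(e$parent < 0 | e$parent >= nrow(n) | e$child < 0 | e$child >= nrow(n))) {
      out[[length(out) + 1L]] <- bad("no such node", "edge references unknown node")
    } else {
      i <- which(e$left >= e$right | e$left < 0 | e$right > L)
      if (length(i))
        out[[length(out) + 1L]] <- bad("bad interval",
          sprintf("edge rows %s", paste(utils::head(i, 5), collapse = ",")))
      i <- which(n$time[e$parent + 1L] <= n$time[e$child + 1L])
      if (length(i))
        out[[length(out) + 1L]] <- bad("time order",
          sprintf("parent not older than child at edge rows %s",
                  paste(utils::head(i, 5), collapse = ",")))
      # per-child interval overlap (any two edges of one child must be disjoint)
      o <- order(e$child, e$left)
      ch <- e$child[o]; lf <- e$left[o]; rt <- e$right[o]
      k <- which(ch[-1] == ch[-length(ch)] & lf[-1] < rt[-length(rt)])
      if (length(k))
        out[[length(out) + 1L]] <- bad("edge overlap",
          sprintf("child %s has overlapping parent intervals",
                  paste(unique(utils::head(ch[k + 1L], 5)), collapse = ",")))
    }
  }
  s <- ts$sites
  if (nrow(s) > 0) {
    if (any(s$node < 0 | s$node >= nrow(n)))
      out[[length(out) + 1L]] <- bad("no such node", "site references unknown node")
    if (any(s$position < 0 | s$position >= L))
      out[[length(out) + 1L]] <- bad("site position", "position outside [0, L)")
    if (any(diff(s$position) <= 0))
      out[[length(out) + 1L]] <- bad("site order", "positions not strictly increasing")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(0), detail = character(0))
}

#' Read a tree sequence from TSV tables
#'
#' The dialect is tab-separated with a header row: `nodes.tsv` has columns
#' `id`, `time`, `is_sample` (0/1), `individual` (integer or -1);
#' `edges.tsv` has `left`, `right`, `parent`, `child`; the optional
#' `sites.tsv` has `position`, `node`, `derived_state`.
#'
#' @param node_path,edge_path,site_path file paths (`site_path` may be `NULL`).
#' @param sequence_length total genome length.
#' @return a validated [tree_sequence()].
#' @export
load_tree_sequence <- function(node_path, edge_path, site_path = NULL,
                               sequence_length) {
  rd <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  nodes <- rd(node_path)
  edges <- rd(edge_path)
  sites <- if (!is.null(site_path)) rd(site_path) else NULL
  tree_sequence(nodes, edges, sites, sequence_length)
}

#' Write a tree sequence as TSV tables
#'
#' Inverse of [load_tree_sequence()]: writes `nodes.tsv`, `edges.tsv` and
#' (when sites are present) `sites.tsv` into `dir`, plus a one-line
#' `sequence_length.tsv`.
#'
#' @param ts a `tree_sequence`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_tree_sequence <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(d, p) utils::write.table(d, file.path(dir, p), sep = "\t",
    quote = FALSE, row.names = FALSE)
  nodes <- ts$nodes
  nodes$is_sample <- as.integer(nodes$is_sample)
  nodes$individual[is.na(nodes$individual)] <- -1L
  wr(nodes, "nodes.tsv")
  wr(ts$edges, "edges.tsv")
  if (nrow(ts$sites) > 0) wr(ts$sites, "sites.tsv")
  wr(data.frame(sequence_length = ts$sequence_length), "sequence_length.tsv")
  invisible(dir)
}

#' Read a tree sequence written by [write_tree_sequence()]
#' @param dir directory containing the TSV tables.
#' @return a validated [tree_sequence()].
#' @export
read_tree_sequence_dir <- function(dir) {
  L <- utils::read.table(file.path(dir, "sequence_length.tsv"), header = TRUE,
                         sep = "\t")$sequence_length[1]
  sp <- file.path(dir, "sites.tsv")
  load_tree_sequence(file.path(dir, "nodes.tsv"), file.path(dir, "edges.tsv"),
                     if (file.exists(sp)) sp else NULL, L)
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat(sprintf(
    "tree_sequence: %d nodes (%d samples), %d edges, %d sites, L = %g, %d trees\n",
    nrow(x$nodes), sum(x$nodes$is_sample), nrow(x$edges), nrow(x$sites),
    x$sequence_length, num_trees(x)))
  invisible(x)
}

#' Sample node ids of a tree sequence
#' @param ts a `tree_sequence`.
#' @return integer vector of 0-based node ids flagged as samples.
#' @export
ts_samples <- function(ts) ts$nodes$id[ts$nodes$is_sample]

#' Number of local trees
#' @param ts a `tree_sequence`.
#' @return integer count of distinct genomic intervals (local trees).
#' @export
num_trees <- function(ts) length(ts_breakpoints(ts)) - 1L

#' Breakpoints of the local-tree partition
#' @param ts a `tree_sequence`.
#' @return sorted vector of breakpoints, starting at 0 and ending at
#'   `sequence_length`; the k-th local tree covers `[b_k, b_{k+1})`.
#' @export
ts_breakpoints <- function(ts) {
  sort(unique(c(0, ts$edges$left, ts$edges$right, ts$sequence_length)))
}
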