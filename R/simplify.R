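#' Simplify a tree sequence to the ancestry of a set of samples
#'
#' Restricts the tables to the genetic material ancestral to `samples`:
#' non-ancestral nodes and edges are dropped and nodes that are unary on
#' every retained interval are removed from paths (their branch is merged
#' into the one below). With `keep_input_roots = TRUE`, input roots (nodes
#' that are no edge's child, e.g. founder genomes of a gene-dropped ARG)
#' are retained at the top of every retained lineage even where unary, so
#' later recapitation can continue from them.
#'
#' The retained samples are renumbered `0 ... n-1` in the order given;
#' other retained nodes are numbered upwards in time order. Sites are
#' dropped (simplification here is used before mutation dropping).
#'
#' @param ts a `tree_sequence`.
#' @param samples 0-based node ids to keep as samples.
#' @param keep_input_roots keep input roots on retained lineages?
#' @return a `tree_sequence`; attribute `"node_map"` maps input node id + 1
#'   to output id (`NA` if dropped).
#' @export
simplify_ts <- function(ts, samples, keep_input_roots = FALSE) {
  N <- nrow(ts$nodes)
  L <- ts$sequence_length
  A <- vector("list", N)               # per input node: (left, right, onode)
  out_time <- numeric(0); out_samp <- logical(0); out_ind <- integer(0)
  node_map <- rep(NA_integer_, N)
  alloc <- function(input_id, sample) {
    out_time[length(out_time) + 1L] <<- ts$nodes$time[input_id + 1L]
    out_samp[length(out_samp) + 1L] <<- sample
    out_ind[length(out_ind) + 1L] <<- ts$nodes$individual[input_id + 1L]
    node_map[input_id + 1L] <<- length(out_time) - 1L
    length(out_time) - 1L
  }
  for (s in samples) {
    o <- alloc(s, TRUE)
    A[[s + 1L]] <- matrix(c(0, L, o), 1, 3)
  }
  e <- ts$edges
  echunks <- list()
  emit <- function(l, r, p, c) {
    echunks[[length(echunks) + 1L]] <<- c(l, r, p, c)
  }
  parents <- unique(e$parent)
  parents <- parents[order(ts$nodes$time[parents + 1L], parents)]
  for (p in parents) {
    rows <- which(e$parent == p)
    segs <- list()
    for (ri in rows) {
      ac <- A[[e$child[ri] + 1L]]
      if (is.null(ac)) next
      l <- pmax(ac[, 1], e$left[ri]); r <- pmin(ac[, 2], e$right[ri])
      keep <- l < r
      if (any(keep))
        segs[[length(segs) + 1L]] <- cbind(l[keep], r[keep], ac[keep, 3])
    }
    if (!length(segs)) next
    segs <- do.call(rbind, segs)
    is_sample_p <- ts$nodes$is_sample[p + 1L]
    bnd <- sort(unique(c(segs[, 1], segs[, 2])))
    np <- if (is_sample_p) node_map[p + 1L] else NA_integer_
    amap <- list()
    for (i in seq_len(length(bnd) - 1L)) {
      l <- bnd[i]; r <- bnd[i + 1L]
      cov <- which(segs[, 1] <= l & segs[, 2] >= r)
      if (!length(cov)) next
      if (length(cov) >= 2 || is_sample_p) {
        if (is.na(np)) np <- alloc(p, FALSE)
        for (ci in cov) emit(l, r, np, segs[ci, 3])
        amap[[length(amap) + 1L]] <- c(l, r, np)
      } else {
        amap[[length(amap) + 1L]] <- c(l, r, segs[cov, 3])
      }
    }
    if (length(amap)) A[[p + 1L]] <- do.call(rbind, amap)
  }
  if (keep_input_roots) {
    is_child <- rep(FALSE, N)
    is_child[e$child + 1L] <- TRUE
    for (p in which(!is_child) - 1L) {
      ap <- A[[p + 1L]]
      if (is.null(ap)) next
      np <- node_map[p + 1L]
      loose <- if (is.na(np)) seq_len(nrow(ap)) else which(ap[, 3] != np)
      if (!length(loose)) next
      if (is.na(np)) np <- alloc(p, FALSE)
      for (i in loose) emit(ap[i, 1], ap[i, 2], np, ap[i, 3])
    }
  }
  edges <- if (length(echunks)) {
    m <- do.call(rbind, echunks)
    squash_edges(data.frame(left = m[, 1], right = m[, 2],
                            parent = as.integer(m[, 3]),
                            child = as.integer(m[, 4])))
  } else data.frame(left = numeric(0), right = numeric(0),
                    parent = integer(0), child = integer(0))
  nodes <- data.frame(id = seq_along(out_time) - 1L, time = out_time,
                      is_sample = out_samp, individual = out_ind)
  out <- tree_sequence(nodes, edges, NULL, L)
  attr(out, "node_map") <- node_map
  out
}
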