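#' Local trees of a tree sequence
#'
#' Recovers the sequence of local trees left-to-right by sweeping the sorted
#' edge indexes: at each breakpoint, edges whose interval ends there are
#' removed (removal index order) and edges whose interval starts there are
#' inserted (insertion index order). The concatenated spans of the returned
#' trees cover `[0, sequence_length)` exactly.
#'
#' @param ts a `tree_sequence`.
#' @return list of `local_tree` objects, each a list with `interval`
#'   (half-open `[b_{k-1}, b_k)`), `span`, `parent` (0-based parent id per
#'   node, `NA` for roots), `num_children`, and the node `time` vector.
#' @export
local_trees <- function(ts) {
  N <- nrow(ts$nodes)
  e <- ts$edges
  bp <- ts_breakpoints(ts)
  parent <- rep(NA_integer_, N)
  nchild <- integer(N)
  ins <- ts$insertion; rem <- ts$removal
  j <- 1L; k <- 1L; ne <- nrow(e)
  out <- vector("list", length(bp) - 1L)
  for (t in seq_len(length(bp) - 1L)) {
    pos <- bp[t]
    while (k <= ne && e$right[rem[k]] == pos) {
      r <- rem[k]
      parent[e$child[r] + 1L] <- NA_integer_
      nchild[e$parent[r] + 1L] <- nchild[e$parent[r] + 1L] - 1L
      k <- k + 1L
    }
    while (j <= ne && e$left[ins[j]] == pos) {
      r <- ins[j]
      parent[e$child[r] + 1L] <- e$parent[r]
      nchild[e$parent[r] + 1L] <- nchild[e$parent[r] + 1L] + 1L
      j <- j + 1L
    }
    out[[t]] <- structure(list(interval = c(bp[t], bp[t + 1L]),
                               span = bp[t + 1L] - bp[t],
                               parent = parent, num_children = nchild,
                               time = ts$nodes$time,
                               cache = new.env(parent = emptyenv())),
                          class = "local_tree")
  }
  out
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("local_tree on [%g, %g): %d nodes, %d roots\n", x$interval[1],
              x$interval[2], length(x$parent),
              sum(is.na(x$parent) & (x$num_children > 0 | tree_is_leaf(x)))))
  invisible(x)
}

tree_is_leaf <- function(tree) tree$num_children == 0L

#' Branch length above a node in a local tree
#'
#' The time from a node to its parent in this tree, or 0 when the node is a
#' (local) root.
#'
#' @param tree a `local_tree`.
#' @param n 0-based node id.
#' @return non-negative real.
#' @export
branch_length_above <- function(tree, n) {
  if (any(n < 0 | n >= length(tree$parent))) stop("no such node")
  p <- tree$parent[n + 1L]
  ifelse(is.na(p), 0, tree$time[p + 1L] - tree$time[n + 1L])
}

#' Most recent common ancestor of two nodes in a local tree
#'
#' Queries use an Euler-tour + sparse-table range-minimum structure built
#' once per tree (O(N log N) preprocessing, O(1) per query) and cached on
#' the tree object. `tree_mrca(tree, u, u)` is `u`; nodes in different root
#' subtrees have no MRCA and give `NA`.
#'
#' @param tree a `local_tree`.
#' @param u,v 0-based node ids.
#' @return 0-based node id of the MRCA, or `NA` if none.
#' @export
tree_mrca <- function(tree, u, v) {
  N <- length(tree$parent)
  if (any(c(u, v) < 0 | c(u, v) >= N)) stop("no such node")
  st <- tree_rmq(tree)
  drop(tree_mrca_bulk(st, u, v))
}

# Euler tour + sparse table, cached in tree$cache. Multiple roots are
# handled by concatenating per-root tours and recording a root label per
# node; cross-root queries return NA.
tree_rmq <- function(tree) {
  if (!is.null(tree$cache$rmq)) return(tree$cache$rmq)
  N <- length(tree$parent)
  kids <- vector("list", N)
  ch <- which(!is.na(tree$parent))           # 1-based child rows
  for (i in ch) {
    p <- tree$parent[i] + 1L
    kids[[p]] <- c(kids[[p]], i - 1L)
  }
  roots <- which(is.na(tree$parent)) - 1L
  tour <- integer(2L * N); dep <- integer(2L * N); m <- 0L
  first <- rep(NA_integer_, N)
  rootof <- rep(NA_integer_, N)
  for (r in roots) {
    # iterative DFS emitting the node at every visit (Euler tour)
    stack_node <- integer(N); stack_ci <- integer(N); stack_d <- integer(N)
    top <- 1L
    stack_node[1L] <- r; stack_ci[1L] <- 1L; stack_d[1L] <- 0L
    m <- m + 1L; tour[m] <- r; dep[m] <- 0L; first[r + 1L] <- m
    rootof[r + 1L] <- r
    while (top > 0L) {
      nd <- stack_node[top]; ci <- stack_ci[top]; d <- stack_d[top]
      kk <- kids[[nd + 1L]]
      if (ci <= length(kk)) {
        stack_ci[top] <- ci + 1L
        c0 <- kk[ci]
        top <- top + 1L
        stack_node[top] <- c0; stack_ci[top] <- 1L; stack_d[top] <- d + 1L
        m <- m + 1L; tour[m] <- c0; dep[m] <- d + 1L
        first[c0 + 1L] <- m
        rootof[c0 + 1L] <- r
      } else {
        top <- top - 1L
        if (top > 0L) {
          m <- m + 1L
          tour[m] <- stack_node[top]; dep[m] <- stack_d[top]
        }
      }
    }
  }
  tour <- tour[seq_len(m)]; dep <- dep[seq_len(m)]
  K <- max(0L, floor(log2(m)))
  sp <- matrix(0L, nrow = m, ncol = K + 1L)     # sp[i, j]: argmin over 2^(j-1)
  sp[, 1L] <- seq_len(m)
  if (K >= 1L) for (j in seq_len(K)) {
    half <- 2L^(j - 1L)
    i <- seq_len(m - 2L * half + 1L)
    a <- sp[i, j]; b <- sp[i + half, j]
    sp[i, j + 1L] <- ifelse(dep[a] <= dep[b], a, b)
  }
  st <- list(tour = tour, dep = dep, first = first, sp = sp,
             rootof = rootof)
  tree$cache$rmq <- st
  st
}

# Vectorized O(1) MRCA queries; u, v are equal-length 0-based id vectors.
tree_mrca_bulk <- function(st, u, v) {
  fu <- st$first[u + 1L]; fv <- st$first[v + 1L]
  l <- pmin(fu, fv); r <- pmax(fu, fv)
  k <- floor(log2(r - l + 1))
  a <- st$sp[cbind(l, k + 1L)]
  b <- st$sp[cbind(r - 2L^k + 1L, k + 1L)]
  res <- st$tour[ifelse(st$dep[a] <= st$dep[b], a, b)]
  res[st$rootof[u + 1L] != st$rootof[v + 1L]] <- NA_integer_
  res
}

# Node depths as path length (sum of branch lengths) to the root of its
# subtree, plus the root id of each node.
tree_depths <- function(tree) {
  st <- tree_rmq(tree)
  N <- length(tree$parent)
  depth <- numeric(N)
  # process nodes in tour-first order: parents always appear before children
  ord <- order(st$first)
  for (i in ord) {
    p <- tree$parent[i]
    if (!is.na(p))
      depth[i] <- depth[p + 1L] + tree$time[p + 1L] - tree$time[i]
  }
  list(depth = depth, rootof = st$rootof)
}
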