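#' Simulate an ARG under the coalescent with recombination
#'
#' Hudson-style backward-in-time simulation for a single panmictic
#' population of constant haploid effective size `Ne`: each pair of
#' ancestral lineages coalesces at rate `1/(2 Ne)` per generation (so the
#' expected pairwise TMRCA is `2 Ne`), and recombination splits a lineage
#' at rate `recombination_rate` per unit of tracked ancestral material per
#' generation. Segments on which all samples have found their MRCA are
#' dropped from the ancestral material, so every local tree of the result
#' has exactly one root. Deterministic given `seed`.
#'
#' @param n_samples number of haploid sample genomes (>= 2), at time 0.
#' @param sequence_length genome length.
#' @param Ne haploid effective population size (generations time scale).
#' @param recombination_rate per unit length per generation.
#' @param mutation_rate if positive, infinite-sites mutations are dropped
#'   on the result via [drop_mutations()].
#' @param seed integer RNG seed (required).
#' @return a validated [tree_sequence()].
#' @export
sim_coalescent_arg <- function(n_samples, sequence_length, Ne,
                               recombination_rate = 0, mutation_rate = 0,
                               seed) {
  if (n_samples < 2) stop("too few samples")
  set.seed(seed)
  n <- as.integer(n_samples)
  L <- sequence_length
  lineages <- lapply(seq_len(n) - 1L, function(i)
    matrix(c(0, L, i, 1), 1, 4,
           dimnames = list(NULL, c("left", "right", "node", "ndesc"))))
  res <- run_coalescent(lineages, start_time = 0, Ne = Ne,
                        recombination_rate = recombination_rate,
                        n_total = n, next_node = n, L = L)
  nodes <- data.frame(id = seq_len(n + length(res$new_times)) - 1L,
                      time = c(rep(0, n), res$new_times),
                      is_sample = c(rep(TRUE, n),
                                    rep(FALSE, length(res$new_times))))
  ts <- tree_sequence(nodes, res$edges, NULL, L)
  if (mutation_rate > 0)
    ts <- drop_mutations(ts, mutation_rate, seed = seed + 1L)
  ts
}

# Shared event loop for coalescent simulation and recapitation. `lineages`
# is a list of segment matrices (left, right, node, ndesc) sorted by left;
# `activation` gives the time at which each enters the ancestral process.
# Returns new node times (in creation order) and the edge table.
run_coalescent <- function(lineages, start_time, Ne, recombination_rate,
                           n_total, next_node, L,
                           activation = rep(start_time, length(lineages))) {
  t <- start_time
  new_times <- numeric(0)
  echunks <- list()
  active <- which(activation <= t)
  pending <- setdiff(order(activation), active)
  span_of <- function(s) s[nrow(s), 2] - s[1, 1]
  tracked_all <- vapply(lineages, span_of, numeric(1))  # by lineage id
  repeat {
    k <- length(active)
    if (k < 2 && length(pending) == 0) break
    tracked <- tracked_all[active]
    rate_c <- k * (k - 1) / 2 / (2 * Ne)
    rate_r <- recombination_rate * sum(tracked)
    rate <- rate_c + rate_r
    if (rate <= 0) {
      if (length(pending) == 0) break
      t <- activation[pending[1]]
    } else {
      dt <- stats::rexp(1, rate)
      if (length(pending) > 0 && t + dt > activation[pending[1]]) {
        t <- activation[pending[1]]
      } else {
        t <- t + dt
        if (stats::runif(1) < rate_r / rate) {
          # recombination: split one lineage at a uniform tracked position
          li <- active[sample.int(k, 1L, prob = tracked)]
          s <- lineages[[li]]
          bp <- stats::runif(1, s[1, 1], s[nrow(s), 2])
          lo <- s[s[, 2] <= bp, , drop = FALSE]
          hi <- s[s[, 1] >= bp, , drop = FALSE]
          mid <- s[s[, 1] < bp & s[, 2] > bp, , drop = FALSE]
          if (nrow(mid) == 1) {
            lo <- rbind(lo, c(mid[1, 1], bp, mid[1, 3], mid[1, 4]))
            hi <- rbind(c(bp, mid[1, 2], mid[1, 3], mid[1, 4]), hi)
          }
          if (nrow(lo) > 0 && nrow(hi) > 0) {
            lineages[[li]] <- lo
            tracked_all[li] <- lo[nrow(lo), 2] - lo[1, 1]
            lineages[[length(lineages) + 1L]] <- hi
            tracked_all[length(lineages)] <- hi[nrow(hi), 2] - hi[1, 1]
            active <- c(active, length(lineages))
          }
        } else {
          # coalescence of a uniform pair of active lineages
          pair <- active[sample.int(k, 2L)]
          m <- merge_lineages(lineages[[pair[1]]], lineages[[pair[2]]],
                              next_node, n_total)
          if (m$used_node) {
            new_times <- c(new_times, t)
            echunks[[length(echunks) + 1L]] <- m$edges
            next_node <- next_node + 1L
          }
          lineages[[pair[1]]] <- m$segs
          tracked_all[pair[1]] <- if (nrow(m$segs) > 0)
            m$segs[nrow(m$segs), 2] - m$segs[1, 1] else 0
          active <- setdiff(active, pair[2])
          if (nrow(m$segs) == 0) active <- setdiff(active, pair[1])
        }
      }
    }
    newly <- pending[activation[pending] <= t]
    if (length(newly)) {
      active <- c(active, newly)
      pending <- setdiff(pending, newly)
    }
  }
  edges <- if (length(echunks)) do.call(rbind, echunks) else
    data.frame(left = numeric(0), right = numeric(0), parent = integer(0),
               child = integer(0))
  list(new_times = new_times, edges = squash_edges(edges))
}

# Merge two segment lists under a coalescence: overlapping pieces receive
# edges to a freshly created parent node `u`; single-covered pieces pass
# through unchanged; pieces on which all `n_total` samples have coalesced
# are dropped from the output ancestral material.
merge_lineages <- function(sa, sb, u, n_total) {
  bnd <- sort(unique(c(sa[, 1], sa[, 2], sb[, 1], sb[, 2])))
  segs <- list(); edges <- list(); used <- FALSE
  for (i in seq_len(length(bnd) - 1L)) {
    l <- bnd[i]; r <- bnd[i + 1L]
    ia <- which(sa[, 1] <= l & sa[, 2] >= r)
    ib <- which(sb[, 1] <= l & sb[, 2] >= r)
    if (length(ia) && length(ib)) {
      used <- TRUE
      edges[[length(edges) + 1L]] <-
        data.frame(left = c(l, l), right = c(r, r), parent = c(u, u),
                   child = c(sa[ia, 3], sb[ib, 3]))
      nd <- sa[ia, 4] + sb[ib, 4]
      if (nd < n_total)
        segs[[length(segs) + 1L]] <- c(l, r, u, nd)
    } else if (length(ia)) {
      segs[[length(segs) + 1L]] <- c(l, r, sa[ia, 3], sa[ia, 4])
    } else if (length(ib)) {
      segs[[length(segs) + 1L]] <- c(l, r, sb[ib, 3], sb[ib, 4])
    }
  }
  segs <- if (length(segs)) do.call(rbind, segs) else
    matrix(numeric(0), 0, 4)
  colnames(segs) <- c("left", "right", "node", "ndesc")
  # re-join touching pieces with identical node and descendant count
  if (nrow(segs) > 1) {
    keep <- rep(TRUE, nrow(segs))
    for (i in 2:nrow(segs)) {
      j <- max(which(keep[1:(i - 1)]))
      if (segs[j, 2] == segs[i, 1] && segs[j, 3] == segs[i, 3] &&
          segs[j, 4] == segs[i, 4]) {
        segs[j, 2] <- segs[i, 2]
        keep[i] <- FALSE
      }
    }
    segs <- segs[keep, , drop = FALSE]
  }
  list(segs = segs,
       edges = if (length(edges)) do.call(rbind, edges) else NULL,
       used_node = used)
}

# merge runs of edges with equal (parent, child) and abutting intervals
squash_edges <- function(edges) {
  if (nrow(edges) < 2) return(edges)
  o <- order(edges$parent, edges$child, edges$left)
  edges <- edges[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(edges))
  j <- 1L
  for (i in 2:nrow(edges)) {
    if (edges$parent[i] == edges$parent[j] &&
        edges$child[i] == edges$child[j] &&
        edges$left[i] == edges$right[j]) {
      edges$right[j] <- edges$right[i]
      keep[i] <- FALSE
    } else j <- i
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recapitate a tree sequence
#'
#' Continues the coalescent (single panmictic population of size `Ne`)
#' backwards from the root lineages of each local tree until every local
#' tree has a single root. Existing nodes and edges are untouched;
#' intervals that are already fully coalesced are left alone. Root
#' lineages enter the process at their node's time. By default the
#' continuation is recombination-free; pass the genome's recombination
#' rate (e.g. 0.01 per cM per generation for gene-dropped chromosomes) to
#' let ancestral lineages recombine above the roots as well, as standard
#' recapitation tools do.
#'
#' @param ts a `tree_sequence`, possibly with multiple roots per tree.
#' @param Ne haploid effective population size.
#' @param seed integer RNG seed.
#' @param recombination_rate per unit length per generation, applied to
#'   the continued ancestral lineages.
#' @return a `tree_sequence` in which every local tree has one root.
#' @export
recapitate <- function(ts, Ne, seed, recombination_rate = 0) {
  set.seed(seed)
  samples <- ts_samples(ts)
  n <- length(samples)
  # collect, per root node, the intervals it roots plus sample counts below
  segmap <- list()
  for (tree in local_trees(ts)) {
    X <- tree_sample_indicator(tree, samples)
    nb <- rowSums(X)
    roots <- which(is.na(tree$parent) & nb > 0) - 1L
    for (r in roots) {
      if (nb[r + 1L] >= n) next                  # interval already coalesced
      key <- as.character(r)
      segmap[[key]] <- rbind(segmap[[key]],
                             c(tree$interval[1], tree$interval[2], r,
                               nb[r + 1L]))
    }
  }
  if (length(segmap) == 0) return(ts)
  lineages <- lapply(segmap, function(s) {
    s <- s[order(s[, 1]), , drop = FALSE]
    colnames(s) <- c("left", "right", "node", "ndesc")
    s
  })
  activation <- vapply(lineages, function(s) ts$nodes$time[s[1, 3] + 1L],
                       numeric(1))
  res <- run_coalescent(lineages, start_time = min(activation), Ne = Ne,
                        recombination_rate = recombination_rate, n_total = n,
                        next_node = nrow(ts$nodes), L = ts$sequence_length,
                        activation = activation)
  nodes <- rbind(ts$nodes,
                 data.frame(id = nrow(ts$nodes) +
                              seq_along(res$new_times) - 1L,
                            time = res$new_times, is_sample = FALSE,
                            individual = NA_integer_))
  tree_sequence(nodes, rbind(ts$edges, res$edges), ts$sites,
                ts$sequence_length)
}

#' Drop infinite-sites mutations on a tree sequence
#'
#' On every edge, the mutation count is Poisson with mean `mu` times the
#' edge's area (branch length times span); positions are uniform on the
#' edge's genomic interval and all distinct. Each mutation defines a site
#' whose derived allele is carried by exactly the samples below the edge's
#' child at that position.
#'
#' @param ts a `tree_sequence`.
#' @param mu mutation rate per unit length per generation (>= 0).
#' @param seed integer RNG seed.
#' @return the tree sequence with a replaced site table.
#' @export
drop_mutations <- function(ts, mu, seed) {
  stopifnot(mu >= 0)
  set.seed(seed)
  e <- ts$edges
  if (mu == 0 || nrow(e) == 0) {
    ts$sites <- data.frame(position = numeric(0), node = integer(0),
                           derived_state = character(0))
    return(ts)
  }
  area <- (ts$nodes$time[e$parent + 1L] - ts$nodes$time[e$child + 1L]) *
    (e$right - e$left)
  cnt <- stats::rpois(nrow(e), mu * area)
  idx <- rep(seq_len(nrow(e)), cnt)
  pos <- stats::runif(length(idx), e$left[idx], e$right[idx])
  while (anyDuplicated(pos)) {
    d <- which(duplicated(pos))
    pos[d] <- stats::runif(length(d), e$left[idx[d]], e$right[idx[d]])
  }
  sites <- data.frame(position = pos, node = e$child[idx],
                      derived_state = rep("1", length(idx)))
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  ts$sites <- sites
  ts
}

#' Extract the 0/1 genotype matrix implied by a tree sequence's sites
#'
#' Entry `[i, s]` is 1 iff sample i inherits from site s's mutation node in
#' the local tree containing the site's position.
#'
#' @param ts a `tree_sequence` with sites.
#' @param samples 0-based sample node ids (default all samples).
#' @return numeric 0/1 matrix, samples by sites (site order = position
#'   order).
#' @export
genotype_matrix <- function(ts, samples = ts_samples(ts)) {
  s <- ts$sites
  G <- matrix(0, length(samples), nrow(s),
              dimnames = list(samples, NULL))
  if (nrow(s) == 0) return(G)
  for (tree in local_trees(ts)) {
    in_tree <- which(s$position >= tree$interval[1] &
                       s$position < tree$interval[2])
    if (!length(in_tree)) next
    X <- tree_sample_indicator(tree, samples)
    G[, in_tree] <- t(X[s$node[in_tree] + 1L, , drop = FALSE])
  }
  G
}
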