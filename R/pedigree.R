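#' Pedigree container
#'
#' Individuals are identified by consecutive 0-based ids; parents must have
#' smaller ids than their children (which also rules out cycles). Founders
#' have both parents missing (`NA`); an individual with a single known
#' parent is treated downstream as having one anonymous founder parent.
#'
#' @param individuals data.frame with columns `id`, `father`, `mother`
#'   (0-based ids or `NA`), `generation` (integer, founders 0), and
#'   optionally `region` (character, `NA` for none).
#' @param probands 0-based ids of the focal (typically most recent)
#'   individuals.
#' @return an object of class `pedigree`.
#' @export
pedigree <- function(individuals, probands) {
  d <- as.data.frame(individuals)
  if (is.null(d$region)) d$region <- NA_character_
  d <- data.frame(id = as.integer(d$id), father = as.integer(d$father),
                  mother = as.integer(d$mother),
                  generation = as.integer(d$generation),
                  region = as.character(d$region))
  if (!identical(d$id, seq_len(nrow(d)) - 1L))
    stop("individual ids must be consecutive from 0")
  ok <- (is.na(d$father) | d$father < d$id) & (is.na(d$mother) | d$mother < d$id)
  if (!all(ok)) stop("pedigree cycle: parents must precede children")
  probands <- as.integer(probands)
  if (any(!probands %in% d$id)) stop("unknown proband id")
  structure(list(individuals = d, probands = probands), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, %d founders, %d probands, %d generations\n",
              nrow(x$individuals),
              sum(is.na(x$individuals$father) & is.na(x$individuals$mother)),
              length(x$probands), max(x$individuals$generation) + 1L))
  invisible(x)
}

#' Read/write a pedigree as TSV
#'
#' Columns `id`, `father`, `mother`, `generation`, `region`, with `.` for
#' missing values; a final logical column `proband` marks probands.
#'
#' @param path file path.
#' @return [read_pedigree()] returns a `pedigree`.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                         stringsAsFactors = FALSE)
  pedigree(d[c("id", "father", "mother", "generation", "region")],
           d$id[as.logical(d$proband)])
}

#' @rdname read_pedigree
#' @param ped a `pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  d <- ped$individuals
  d$proband <- as.integer(d$id %in% ped$probands)
  d$father[is.na(d$father)] <- "."
  d$mother[is.na(d$mother)] <- "."
  d$region[is.na(d$region)] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a random multi-generation pedigree
#'
#' Founders are split evenly across `n_regions`; each generation,
#' individuals are paired monogamously within their region and each pair
#' draws a Poisson number of offspring. A child inherits its parents'
#' region but moves to a uniformly chosen other region with probability
#' `migration_prob` before mating. The last generation is marked as the
#' probands. Generations with fewer than two individuals in a region are
#' redrawn (up to an internal retry limit) to keep every region populated.
#'
#' @param n_founders total founders (must split into even counts per
#'   region, otherwise error `"pairing"`).
#' @param n_generations number of generations bred below the founders.
#' @param offspring_mean mean of the per-pair Poisson offspring count.
#' @param n_regions number of mating regions.
#' @param migration_prob per-child probability of switching region.
#' @param seed integer RNG seed.
#' @return a `pedigree`.
#' @export
sim_pedigree <- function(n_founders, n_generations, offspring_mean = 3,
                         n_regions = 1, migration_prob = 0, seed) {
  if (n_founders < 2) stop("too few founders")
  if (n_founders %% n_regions != 0 || (n_founders / n_regions) %% 2 != 0)
    stop("pairing: founders must split into even per-region counts")
  set.seed(seed)
  regions <- paste0("R", seq_len(n_regions))
  id <- seq_len(n_founders) - 1L
  df <- data.frame(id = id, father = NA_integer_, mother = NA_integer_,
                   generation = 0L,
                   region = rep(regions, each = n_founders / n_regions))
  cur <- df
  for (g in seq_len(n_generations)) {
    for (try in 1:100) {
      kids <- list()
      for (rg in regions) {
        members <- cur$id[cur$region == rg]
        if (length(members) < 2) next
        members <- sample(members)
        npair <- floor(length(members) / 2)
        for (p in seq_len(npair)) {
          noff <- stats::rpois(1, offspring_mean)
          if (noff == 0) next
          kids[[length(kids) + 1L]] <- data.frame(
            father = members[2 * p - 1L], mother = members[2 * p],
            region = rg)[rep(1, noff), ]
        }
      }
      kids <- if (length(kids)) do.call(rbind, kids) else NULL
      if (!is.null(kids)) {
        mig <- stats::runif(nrow(kids)) < migration_prob & n_regions > 1
        if (any(mig))
          kids$region[mig] <- vapply(kids$region[mig], function(r)
            sample(setdiff(regions, r), 1), character(1))
        if (all(table(factor(kids$region, levels = regions)) >= 2)) break
      }
      kids <- NULL
    }
    if (is.null(kids)) stop("pedigree simulation failed to populate regions")
    kids$id <- max(df$id) + seq_len(nrow(kids))
    kids$generation <- g
    kids <- kids[c("id", "father", "mother", "generation", "region")]
    df <- rbind(df, kids)
    cur <- kids
  }
  pedigree(df, cur$id)
}

#' Gene-drop chromosomes through a fixed pedigree
#'
#' Simulates chromosomal inheritance: each individual has two genome nodes;
#' each child node inherits from its parent's two nodes with recombination
#' breakpoints from a Poisson process at 0.01 crossovers per cM and a
#' fair-coin starting haplotype. The genome coordinate is genetic distance
#' (cM) so the crossover process is homogeneous. Node time is generation
#' depth (probands 0, founders deepest). The result is simplified to the
#' lineages ancestral to the proband nodes, removing unary nodes but
#' retaining founder lineage nodes as roots; individuals with one missing
#' parent inherit that genome copy as an untransmitted founder-style
#' lineage of their own.
#'
#' Per-meiosis RNG streams are derived from `seed`, so transmissions are
#' reproducible independently of evaluation order.
#'
#' @param ped a `pedigree`.
#' @param chrom_length_cM chromosome length in centimorgans.
#' @param seed integer RNG seed.
#' @return a `tree_sequence` in cM coordinates whose samples are the
#'   proband genomes (two per proband, `individual` set to the proband id).
#' @export
gene_drop_arg <- function(ped, chrom_length_cM, seed) {
  if (length(ped$probands) == 0) stop("probands required")
  d <- ped$individuals
  L <- chrom_length_cM
  gmax <- max(d$generation)
  nind <- nrow(d)
  node_time <- rep(gmax - d$generation, each = 2)
  is_samp <- rep(d$id %in% ped$probands, each = 2)
  node_ind <- rep(d$id, each = 2)
  echunks <- vector("list", 2L * nind)
  for (i in seq_len(nind)) {
    for (side in 1:2) {                    # 1 = paternal copy, 2 = maternal
      par <- if (side == 1) d$father[i] else d$mother[i]
      if (is.na(par)) next                 # founder-style lineage: no edges
      child_node <- 2L * (i - 1L) + (side - 1L)
      set.seed(meiosis_seed(seed, 2L * (i - 1L) + side))
      nbp <- stats::rpois(1, 0.01 * L)
      bp <- sort(stats::runif(nbp, 0, L))
      start <- sample(0:1, 1)
      cuts <- c(0, bp, L)
      hap <- (start + (seq_len(length(cuts) - 1L) - 1L)) %% 2L
      echunks[[2L * (i - 1L) + side]] <- data.frame(
        left = cuts[-length(cuts)], right = cuts[-1],
        parent = 2L * par + hap, child = child_node)
    }
  }
  edges <- do.call(rbind, echunks[!vapply(echunks, is.null, logical(1))])
  nodes <- data.frame(id = seq_len(2L * nind) - 1L, time = node_time,
                      is_sample = is_samp, individual = node_ind)
  full <- tree_sequence(nodes, squash_edges(edges), NULL, L)
  simplify_ts(full, ts_samples(full), keep_input_roots = TRUE)
}

meiosis_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 16807) %% 2147483647)
}
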