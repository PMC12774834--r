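#' Pedigree kinship matrix by tabular recursion
#'
#' The kinship coefficient `theta[i, j]` is the probability that one
#' homologous allele drawn at random from each of i and j (with
#' replacement when i = j) is identical by descent within the pedigree.
#' Founders are taken as non-inbred and mutually unrelated, so
#' `theta = 1/2` on their diagonal and 0 elsewhere; for a non-founder i
#' younger than j, `theta(i, j) = (theta(father(i), j) +
#' theta(mother(i), j)) / 2`, and
#' `theta(i, i) = (1 + theta(father(i), mother(i))) / 2`. A missing
#' parent contributes 0 (anonymous founder).
#'
#' @param ped a `pedigree`.
#' @return symmetric matrix of class `relatedness_matrix`
#'   (mode `"pedigree"`), one row per individual, named by id.
#' @export
kinship_matrix <- function(ped) {
  d <- ped$individuals
  n <- nrow(d)
  th <- matrix(0, n, n)
  fa <- d$father + 1L; mo <- d$mother + 1L       # NA for founders
  for (i in seq_len(n)) {
    fi <- fa[i]; mi <- mo[i]
    if (is.na(fi) && is.na(mi)) {
      th[i, i] <- 0.5
      next
    }
    row_f <- if (!is.na(fi)) th[fi, ] else numeric(n)
    row_m <- if (!is.na(mi)) th[mi, ] else numeric(n)
    if (i > 1) {
      j <- seq_len(i - 1L)
      th[i, j] <- (row_f[j] + row_m[j]) / 2
      th[j, i] <- th[i, j]
    }
    fsel <- if (!is.na(fi) && !is.na(mi)) th[fi, mi] else 0
    th[i, i] <- (1 + fsel) / 2
  }
  dimnames(th) <- list(d$id, d$id)
  relatedness_matrix(th, "pedigree", ploidy_level = "individual")
}

#' Inbreeding coefficients
#'
#' `f[i]` is the kinship between i's parents (0 for founders or a missing
#' parent).
#'
#' @param ped a `pedigree`.
#' @return numeric vector named by individual id.
#' @export
inbreeding_coefficients <- function(ped) {
  th <- unclass(kinship_matrix(ped))
  d <- ped$individuals
  f <- ifelse(is.na(d$father) | is.na(d$mother), 0,
              th[cbind(d$father + 1L, d$mother + 1L)])
  names(f) <- d$id
  f
}

#' Monte Carlo kinship by allele gene dropping
#'
#' Unbiased estimator of the tabular kinship: in each replicate, founders
#' receive distinct allele labels and every child samples one allele from
#' each parent (fair Mendelian segregation; a missing parent transmits a
#' fresh unique label). The estimate for a pair is the proportion of
#' replicates, averaged over the four allele pairings (drawn with
#' replacement for i = j), in which the drawn alleles are copies of the
#' same founder allele.
#'
#' @param ped a `pedigree`.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @return estimate matrix with attribute `"se"` (per-entry standard
#'   errors over replicates).
#' @export
gene_drop_ibd_kinship <- function(ped, n_reps, seed) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  d <- ped$individuals
  n <- nrow(d)
  a1 <- matrix(0L, n, n_reps)        # allele labels, individuals x reps
  a2 <- matrix(0L, n, n_reps)
  next_label <- 0L
  fresh <- function() {
    next_label <<- next_label + 1L
    # unique per (lineage, replicate) label block
    next_label * n_reps + seq_len(n_reps)
  }
  for (i in seq_len(n)) {
    fi <- d$father[i]; mi <- d$mother[i]
    a1[i, ] <- if (is.na(fi)) fresh() else
      ifelse(stats::runif(n_reps) < 0.5, a1[fi + 1L, ], a2[fi + 1L, ])
    a2[i, ] <- if (is.na(mi)) fresh() else
      ifelse(stats::runif(n_reps) < 0.5, a1[mi + 1L, ], a2[mi + 1L, ])
  }
  est <- matrix(0, n, n); se <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    p <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
            (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
    est[i, j] <- est[j, i] <- mean(p)
    se[i, j] <- se[j, i] <- stats::sd(p) / sqrt(n_reps)
  }
  dimnames(est) <- list(d$id, d$id)
  structure(est, se = se)
}

#' Average founder depth per individual
#'
#' The expected number of generations back to a founder along a random
#' lineage path: founders have depth 0 and
#' `depth(i) = 1 + (depth(father) + depth(mother)) / 2`, a missing parent
#' counting as an anonymous founder of depth 0. Useful for excluding
#' probands with shallow (incomplete) pedigrees by thresholding.
#'
#' @param ped a `pedigree`.
#' @return numeric vector named by individual id.
#' @export
average_founder_depth <- function(ped) {
  d <- ped$individuals
  dep <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    fi <- d$father[i]; mi <- d$mother[i]
    if (is.na(fi) && is.na(mi)) next
    df_ <- if (is.na(fi)) 0 else dep[fi + 1L]
    dm_ <- if (is.na(mi)) 0 else dep[mi + 1L]
    dep[i] <- 1 + (df_ + dm_) / 2
  }
  names(dep) <- d$id
  dep
}

#' Predicted branch relatedness from pedigree kinship
#'
#' For closely related pairs, branch relatedness is approximately the
#' pedigree kinship scaled by the mean TMRCA `T` among pedigree founders:
#' `B[i, j] ~ theta[i, j] * T`. The approximation is derived for
#' off-diagonal pairs; diagonal entries are returned but should be treated
#' as indicative only.
#'
#' @param theta kinship matrix (as from [kinship_matrix()]).
#' @param T_founder mean TMRCA among distinct founder genomes
#'   (generations), e.g. from [mean_tmrca()] on a recapitated ARG.
#' @return matrix of predicted branch relatedness values.
#' @export
predict_branch_relatedness <- function(theta, T_founder) {
  stopifnot(T_founder > 0)
  unclass(theta) * T_founder
}
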