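#' Simulate an unselected population reference sample of blood pressures
#'
#' Draws independent individuals from the model's unselected population
#' distribution (QTL genotype under Hardy-Weinberg, polygenic and
#' environmental deviates). Such a sample plays the role of the large
#' general-practice screening reference from which blood-pressure centile
#' thresholds are derived.
#'
#' @param n Number of individuals (>= 2).
#' @param model A [trait_model()].
#' @param seed Integer random seed (required; runs are reproducible).
#' @return A data.frame with columns `sbp` and `dbp` (mmHg).
#' @seealso [centile_thresholds()]
#' @examples
#' ref <- simulate_reference_sample(1000, trait_model(), seed = 1)
#' centile_thresholds(ref$sbp, 10, 90)
#' @export
simulate_reference_sample <- function(n, model, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single count >= 2")
  }
  stopifnot(inherits(model, "trait_model"))
  n <- as.integer(n)
  set.seed(as.integer(seed))
  p <- model$qtl_allele_freq
  g <- stats::rbinom(n, 2L, p)
  val_s <- .qtl_values(p, model$additive_effect_sbp, model$dominance_sbp)
  val_d <- .qtl_values(p, model$additive_effect_dbp, model$dominance_dbp)
  env <- .bivariate_env(n, model)
  data.frame(
    sbp = model$mean_sbp + val_s[g + 1L] +
      stats::rnorm(n, 0, model$polygenic_sd_sbp) + env$sbp,
    dbp = model$mean_dbp + val_d[g + 1L] +
      stats::rnorm(n, 0, model$polygenic_sd_dbp) + env$dbp
  )
}

# n pairs of (SBP, DBP) environmental deviates with the model's correlation
.bivariate_env <- function(n, model) {
  u1 <- stats::rnorm(n)
  u2 <- stats::rnorm(n)
  rho <- model$env_corr_sbp_dbp
  list(sbp = model$env_sd_sbp * u1,
       dbp = model$env_sd_dbp * (rho * u1 + sqrt(1 - rho^2) * u2))
}

#' Simulate nuclear families of genotyped sib pairs with known-truth IBD
#'
#' Each family consists of two parents and two full sibs. Parental genotypes
#' at the QTL and at every marker are drawn under Hardy-Weinberg equilibrium.
#' Offspring gametes track grandparental origin jointly at the QTL and each
#' marker: the marker allele recombines against the QTL with probability
#' `theta`, markers being conditionally independent given the QTL
#' (single-point simulation). True identity-by-descent (IBD) counts for the
#' sib pair at the QTL and every marker are recorded from the parental-origin
#' labels. Sib phenotypes are genotype mean + a family-shared polygenic
#' deviate (variance half the polygenic variance) + an individual polygenic
#' deviate (the other half) + an environmental deviate; pulse pressure is
#' SBP - DBP. Ages are drawn N(39.8, 7.8) years and sexes at random,
#' mirroring an adult untreated sib cohort.
#'
#' @param n_families Number of families (>= 1).
#' @param model A [trait_model()].
#' @param markers Non-empty list of [marker_def()] objects (each needs a
#'   non-missing `theta`).
#' @param seed Integer random seed (required).
#' @param age_mean,age_sd Offspring age distribution in years.
#' @return An object of class `edsp_cohort`: a list with `individuals`
#'   (data.frame: family_id, individual_id, father_id, mother_id, sex, age,
#'   sbp, dbp, pp, role), `genotypes` (integer matrix, two columns per
#'   marker, 0 = missing), `pairs` (one row per sib pair), `true_ibd`
#'   (matrix of IBD counts in 0:2, columns `QTL` then marker names),
#'   `qtl_dosage` (high-allele counts of the two sibs), plus the `model`,
#'   `markers` and `seed` used.
#' @examples
#' mk <- list(marker_def("M1", n_alleles = 8, theta = 0))
#' ch <- simulate_families(50, trait_model(), mk, seed = 1)
#' table(ch$true_ibd[, "M1"] == ch$true_ibd[, "QTL"])
#' @export
simulate_families <- function(n_families, model, markers, seed,
                              age_mean = 39.8, age_sd = 7.8) {
  if (!is.numeric(n_families) || length(n_families) != 1L || n_families < 1) {
    stop("`n_families` must be a single count >= 1")
  }
  stopifnot(inherits(model, "trait_model"))
  markers <- .check_markers(markers)
  th <- vapply(markers, `[[`, numeric(1), "theta")
  if (any(is.na(th))) stop("every marker needs a non-missing `theta`")
  n <- as.integer(n_families)
  m <- length(markers)
  set.seed(as.integer(seed))

  p <- model$qtl_allele_freq
  # founder alleles: QTL coded 1 (low, q) / 2 (high, Q)
  FQ <- matrix(stats::rbinom(2L * n, 1L, p) + 1L, n, 2L)
  MQ <- matrix(stats::rbinom(2L * n, 1L, p) + 1L, n, 2L)
  Fmk <- lapply(markers, function(mk)
    matrix(sample.int(mk$n_alleles, 2L * n, replace = TRUE,
                      prob = mk$allele_freqs), n, 2L))
  Mmk <- lapply(markers, function(mk)
    matrix(sample.int(mk$n_alleles, 2L * n, replace = TRUE,
                      prob = mk$allele_freqs), n, 2L))

  # grandparental origin of each sib's gametes at the QTL
  opat <- matrix(sample(c(1L, 2L), 2L * n, replace = TRUE), n, 2L)
  omat <- matrix(sample(c(1L, 2L), 2L * n, replace = TRUE), n, 2L)
  ibd_qtl <- (opat[, 1L] == opat[, 2L]) + (omat[, 1L] == omat[, 2L])

  idx <- seq_len(n)
  sib_geno <- vector("list", m)       # per marker: n x 4 (s1a1 s1a2 s2a1 s2a2)
  true_ibd <- matrix(0L, n, m + 1L,
                     dimnames = list(NULL, c("QTL", .marker_names(markers))))
  true_ibd[, 1L] <- as.integer(ibd_qtl)
  for (j in seq_len(m)) {
    theta <- markers[[j]]$theta
    op <- opat; om <- omat
    # recombine marker origin against the QTL origin, per gamete
    flip_p <- matrix(stats::runif(2L * n) < theta, n, 2L)
    flip_m <- matrix(stats::runif(2L * n) < theta, n, 2L)
    op[flip_p] <- 3L - op[flip_p]
    om[flip_m] <- 3L - om[flip_m]
    true_ibd[, j + 1L] <- as.integer((op[, 1L] == op[, 2L]) +
                                       (om[, 1L] == om[, 2L]))
    Fa <- Fmk[[j]]; Ma <- Mmk[[j]]
    sib_geno[[j]] <- cbind(Fa[cbind(idx, op[, 1L])], Ma[cbind(idx, om[, 1L])],
                           Fa[cbind(idx, op[, 2L])], Ma[cbind(idx, om[, 2L])])
  }

  # sib QTL dosages (copies of the high allele Q)
  d1 <- (FQ[cbind(idx, opat[, 1L])] == 2L) + (MQ[cbind(idx, omat[, 1L])] == 2L)
  d2 <- (FQ[cbind(idx, opat[, 2L])] == 2L) + (MQ[cbind(idx, omat[, 2L])] == 2L)

  val_s <- .qtl_values(p, model$additive_effect_sbp, model$dominance_sbp)
  val_d <- .qtl_values(p, model$additive_effect_dbp, model$dominance_dbp)
  half_s <- model$polygenic_sd_sbp / sqrt(2)
  half_d <- model$polygenic_sd_dbp / sqrt(2)
  sh_s <- stats::rnorm(n, 0, half_s)   # family-shared polygenic deviates
  sh_d <- stats::rnorm(n, 0, half_d)
  env1 <- .bivariate_env(n, model)
  env2 <- .bivariate_env(n, model)
  sbp1 <- model$mean_sbp + val_s[d1 + 1L] + sh_s + stats::rnorm(n, 0, half_s) + env1$sbp
  sbp2 <- model$mean_sbp + val_s[d2 + 1L] + sh_s + stats::rnorm(n, 0, half_s) + env2$sbp
  dbp1 <- model$mean_dbp + val_d[d1 + 1L] + sh_d + stats::rnorm(n, 0, half_d) + env1$dbp
  dbp2 <- model$mean_dbp + val_d[d2 + 1L] + sh_d + stats::rnorm(n, 0, half_d) + env2$dbp

  sex <- matrix(sample(c(1L, 2L), 2L * n, replace = TRUE), n, 2L)
  age <- matrix(stats::rnorm(2L * n, age_mean, age_sd), n, 2L)

  fam <- sprintf("F%04d", seq_len(n))
  # family-major order: father, mother, sib1, sib2
  individuals <- data.frame(
    family_id = rep(fam, each = 4L),
    individual_id = rep(c("1", "2", "3", "4"), n),
    father_id = rep(c("0", "0", "1", "1"), n),
    mother_id = rep(c("0", "0", "2", "2"), n),
    sex = as.integer(rbind(1L, 2L, t(sex))),
    age = as.numeric(rbind(NA_real_, NA_real_, t(age))),
    sbp = as.numeric(rbind(NA_real_, NA_real_, sbp1, sbp2)),
    dbp = as.numeric(rbind(NA_real_, NA_real_, dbp1, dbp2)),
    role = rep(c("parent", "parent", "offspring", "offspring"), n),
    stringsAsFactors = FALSE
  )
  individuals$pp <- individuals$sbp - individuals$dbp

  G <- matrix(0L, 4L * n, 2L * m)
  colnames(G) <- paste(rep(.marker_names(markers), each = 2L), c("a1", "a2"),
                       sep = ".")
  rows_f <- seq(1L, 4L * n, by = 4L)
  for (j in seq_len(m)) {
    cols <- c(2L * j - 1L, 2L * j)
    G[rows_f, cols] <- Fmk[[j]]
    G[rows_f + 1L, cols] <- Mmk[[j]]
    G[rows_f + 2L, cols] <- sib_geno[[j]][, 1:2]
    G[rows_f + 3L, cols] <- sib_geno[[j]][, 3:4]
  }
  storage.mode(G) <- "integer"

  pairs <- data.frame(family_id = fam, sib1 = "3", sib2 = "4",
                      stringsAsFactors = FALSE)
  structure(list(individuals = individuals, genotypes = G, pairs = pairs,
                 true_ibd = true_ibd, qtl_dosage = cbind(sib1 = d1, sib2 = d2),
                 model = model, markers = markers, seed = as.integer(seed),
                 masked = FALSE),
            class = "edsp_cohort")
}

#' Remove parental genotypes from a simulated cohort
#'
#' Emulates a study design in which only the sib pairs are genotyped: all
#' parental genotypes are set to the missing code 0. Offspring genotypes,
#' phenotypes and the recorded true IBD are untouched, so downstream IBD
#' estimation must rely on sib-pair-only likelihoods. Idempotent.
#'
#' @param cohort An `edsp_cohort`.
#' @return The cohort with parental genotypes masked.
#' @export
mask_parents <- function(cohort) {
  stopifnot(inherits(cohort, "edsp_cohort"))
  cohort$genotypes[cohort$individuals$role == "parent", ] <- 0L
  cohort$masked <- TRUE
  cohort
}

#' @export
print.edsp_cohort <- function(x, ...) {
  cat(sprintf("Simulated sib-pair cohort: %d families (%d individuals), %d markers%s\n",
              nrow(x$pairs), nrow(x$individuals), length(x$markers),
              if (isTRUE(x$masked)) ", parents masked" else ""))
  off <- x$individuals[x$individuals$role == "offspring", ]
  cat(sprintf("  offspring SBP %.1f +/- %.1f, DBP %.1f +/- %.1f mmHg; seed %d\n",
              mean(off$sbp), stats::sd(off$sbp), mean(off$dbp),
              stats::sd(off$dbp), x$seed))
  invisible(x)
}

# row indices of the two sibs of each pair in cohort$individuals
.pair_rows <- function(cohort) {
  key <- paste(cohort$individuals$family_id, cohort$individuals$individual_id)
  list(s1 = match(paste(cohort$pairs$family_id, cohort$pairs$sib1), key),
       s2 = match(paste(cohort$pairs$family_id, cohort$pairs$sib2), key))
}
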