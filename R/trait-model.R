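#' Quantitative-trait model for blood-pressure simulation
#'
#' Defines the genetic architecture used by the simulators: a single biallelic
#' quantitative-trait locus (QTL) with additive and dominance effects on
#' systolic (SBP) and diastolic (DBP) blood pressure, a shared polygenic
#' component giving full sibs an additive covariance of half the polygenic
#' variance, and an individual environmental component that may be correlated
#' between SBP and DBP within a person. Pulse pressure (PP) is derived as
#' SBP - DBP and is not modelled separately.
#'
#' Genotype values at the QTL are \code{-a} for the low homozygote, \code{d}
#' for heterozygotes and \code{+a} for the high homozygote; they are centred
#' so that \code{mean_sbp}/\code{mean_dbp} are the exact population means.
#' The implied population variance of each trait is the sum of the QTL,
#' polygenic and environmental variances (see [trait_variance()]).
#'
#' The defaults describe an untreated adult sib cohort with population
#' SBP/DBP close to 125 +/- 18 and 77 +/- 13 mmHg, with the QTL explaining
#' roughly 15% of SBP variance.
#'
#' @param qtl_allele_freq Frequency of the high allele Q, in (0, 1).
#' @param additive_effect_sbp,additive_effect_dbp Additive effect `a` in mmHg.
#' @param dominance_sbp,dominance_dbp Dominance deviation `d` in mmHg.
#' @param polygenic_sd_sbp,polygenic_sd_dbp Polygenic SD in mmHg; full sibs
#'   share half the polygenic variance.
#' @param env_sd_sbp,env_sd_dbp Independent environmental SD in mmHg.
#' @param mean_sbp,mean_dbp Population trait means in mmHg.
#' @param env_corr_sbp_dbp Within-individual correlation of the SBP and DBP
#'   environmental deviates, in [-1, 1].
#' @return An object of class `trait_model`.
#' @seealso [trait_variance()], [simulate_families()],
#'   [simulate_reference_sample()]
#' @examples
#' m <- trait_model()
#' trait_variance(m)$sbp
#' @export
trait_model <- function(qtl_allele_freq = 0.5,
                        additive_effect_sbp = 10, dominance_sbp = 0,
                        additive_effect_dbp = 7, dominance_dbp = 0,
                        polygenic_sd_sbp = 12, polygenic_sd_dbp = 8.5,
                        env_sd_sbp = sqrt(130), env_sd_dbp = 8.5,
                        mean_sbp = 125, mean_dbp = 77,
                        env_corr_sbp_dbp = 0.5) {
  if (!is.numeric(qtl_allele_freq) || length(qtl_allele_freq) != 1L ||
      qtl_allele_freq <= 0 || qtl_allele_freq >= 1) {
    stop("`qtl_allele_freq` must be a single probability in (0, 1)")
  }
  sds <- c(polygenic_sd_sbp, polygenic_sd_dbp, env_sd_sbp, env_sd_dbp)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all standard deviations must be finite and >= 0")
  }
  if (!is.finite(env_corr_sbp_dbp) || abs(env_corr_sbp_dbp) > 1) {
    stop("`env_corr_sbp_dbp` must lie in [-1, 1]")
  }
  structure(list(
    qtl_allele_freq = qtl_allele_freq,
    additive_effect_sbp = additive_effect_sbp,
    dominance_sbp = dominance_sbp,
    additive_effect_dbp = additive_effect_dbp,
    dominance_dbp = dominance_dbp,
    polygenic_sd_sbp = polygenic_sd_sbp,
    polygenic_sd_dbp = polygenic_sd_dbp,
    env_sd_sbp = env_sd_sbp,
    env_sd_dbp = env_sd_dbp,
    mean_sbp = mean_sbp,
    mean_dbp = mean_dbp,
    env_corr_sbp_dbp = env_corr_sbp_dbp
  ), class = "trait_model")
}

#' Implied variance components of a trait model
#'
#' The QTL variance under Hardy-Weinberg is
#' \eqn{2pq[a + d(q - p)]^2 + (2pqd)^2}; the population trait variance is the
#' sum of QTL, polygenic and environmental variances.
#'
#' @param model A [trait_model()].
#' @return A list with elements `sbp` and `dbp`, each a named vector with
#'   components `qtl`, `polygenic`, `environment`, `total` (variances, mmHg^2).
#' @export
trait_variance <- function(model) {
  stopifnot(inherits(model, "trait_model"))
  p <- model$qtl_allele_freq
  q <- 1 - p
  comp <- function(a, d, sa, se) {
    vq <- 2 * p * q * (a + d * (q - p))^2 + (2 * p * q * d)^2
    c(qtl = vq, polygenic = sa^2, environment = se^2,
      total = vq + sa^2 + se^2)
  }
  list(
    sbp = comp(model$additive_effect_sbp, model$dominance_sbp,
               model$polygenic_sd_sbp, model$env_sd_sbp),
    dbp = comp(model$additive_effect_dbp, model$dominance_dbp,
               model$polygenic_sd_dbp, model$env_sd_dbp)
  )
}

# centred QTL genotype values (length 3: 0, 1, 2 copies of Q) for one trait
.qtl_values <- function(p, a, d) {
  q <- 1 - p
  vals <- c(-a, d, a)
  vals - (q^2 * vals[1] + 2 * p * q * vals[2] + p^2 * vals[3])
}

#' @export
print.trait_model <- function(x, ...) {
  v <- trait_variance(x)
  cat("Quantitative-trait model (biallelic QTL + polygenes + environment)\n")
  cat(sprintf("  QTL: freq(Q) = %.3f; a = %.2f/%.2f, d = %.2f/%.2f mmHg (SBP/DBP)\n",
              x$qtl_allele_freq, x$additive_effect_sbp, x$additive_effect_dbp,
              x$dominance_sbp, x$dominance_dbp))
  cat(sprintf("  SBP: mean %.1f, SD %.2f mmHg (QTL %.0f%%, polygenic %.0f%%, environment %.0f%%)\n",
              x$mean_sbp, sqrt(v$sbp[["total"]]),
              100 * v$sbp[["qtl"]] / v$sbp[["total"]],
              100 * v$sbp[["polygenic"]] / v$sbp[["total"]],
              100 * v$sbp[["environment"]] / v$sbp[["total"]]))
  cat(sprintf("  DBP: mean %.1f, SD %.2f mmHg (QTL %.0f%%, polygenic %.0f%%, environment %.0f%%)\n",
              x$mean_dbp, sqrt(v$dbp[["total"]]),
              100 * v$dbp[["qtl"]] / v$dbp[["total"]],
              100 * v$dbp[["polygenic"]] / v$dbp[["total"]],
              100 * v$dbp[["environment"]] / v$dbp[["total"]]))
  cat(sprintf("  env corr(SBP, DBP) = %.2f\n", x$env_corr_sbp_dbp))
  invisible(x)
}

#' Define a microsatellite marker
#'
#' A marker is identified by name, carries a multi-allelic frequency vector
#' and a recombination fraction `theta` to the trait locus (0 = fully linked,
#' 0.5 = unlinked). Fragment-size ranges from genotyping panels may be kept
#' as metadata; analysis uses only allele identity.
#'
#' @param name Marker label, e.g. `"D17S250"`.
#' @param n_alleles Number of alleles (>= 1).
#' @param allele_freqs Allele frequency vector summing to 1; defaults to
#'   equifrequent alleles.
#' @param theta Recombination fraction to the trait locus, in [0, 0.5].
#' @param chromosome Optional chromosome label.
#' @param bp_range Optional fragment-size range string (metadata only).
#' @return An object of class `marker_def`.
#' @export
marker_def <- function(name, n_alleles = 8,
                       allele_freqs = rep(1 / n_alleles, n_alleles),
                       theta = 0.5, chromosome = NA_character_,
                       bp_range = NA_character_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string")
  }
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 1L) stop("`n_alleles` must be >= 1")
  if (length(allele_freqs) != n_alleles) {
    stop("`allele_freqs` must have length `n_alleles`")
  }
  if (any(allele_freqs < 0) || abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("`allele_freqs` must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  if (!is.na(theta) && (theta < 0 || theta > 0.5)) {
    stop("`theta` must lie in [0, 0.5]")
  }
  structure(list(name = name, chromosome = chromosome,
                 n_alleles = n_alleles, allele_freqs = as.numeric(allele_freqs),
                 theta = theta, bp_range = bp_range),
            class = "marker_def")
}

#' @export
print.marker_def <- function(x, ...) {
  cat(sprintf("Marker %s (chr %s): %d alleles, theta = %s%s\n",
              x$name, ifelse(is.na(x$chromosome), "?", x$chromosome),
              x$n_alleles,
              ifelse(is.na(x$theta), "NA", format(x$theta)),
              ifelse(is.na(x$bp_range), "", paste0(", ", x$bp_range, " bp"))))
  invisible(x)
}

.check_markers <- function(markers) {
  if (inherits(markers, "marker_def")) markers <- list(markers)
  if (!is.list(markers) || length(markers) == 0L ||
      !all(vapply(markers, inherits, logical(1), "marker_def"))) {
    stop("`markers` must be a non-empty list of marker_def objects")
  }
  nm <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("marker names must be unique")
  markers
}

.marker_names <- function(markers) vapply(markers, `[[`, character(1), "name")

#' The packaged chromosome 11/17 microsatellite panel
#'
#' Loads the shipped panel of CA-repeat markers on chromosomes 11 and 17
#' (11 and 15 markers respectively) with their genotyping fragment-size
#' ranges as metadata. Allele frequencies are not published for this panel,
#' so markers are given `n_alleles` equifrequent alleles (the default of 8
#' gives heterozygosity 0.875, i.e. "highly polymorphic"); `theta` is a
#' simulation parameter, not a panel property, and must be supplied.
#'
#' @param theta Recombination fraction to the trait locus applied to every
#'   marker (default 0.05).
#' @param n_alleles Alleles per marker (default 8, equifrequent).
#' @param chromosome Optional filter, `"11"` or `"17"`.
#' @return A list of [marker_def()] objects.
#' @export
marker_panel <- function(theta = 0.05, n_alleles = 8, chromosome = NULL) {
  path <- system.file("extdata", "markers_table1.tsv", package = "edsplink")
  if (!nzchar(path)) stop("packaged marker table not found")
  tab <- utils::read.delim(path, colClasses = "character")
  if (!is.null(chromosome)) tab <- tab[tab$chromosome %in% chromosome, ]
  lapply(seq_len(nrow(tab)), function(i) {
    marker_def(tab$locus[i], n_alleles = n_alleles, theta = theta,
               chromosome = tab$chromosome[i], bp_range = tab$range_bp[i])
  })
}
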