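#' Pulse pressure
#'
#' Systolic minus diastolic blood pressure, a surrogate of arterial
#' compliance. Records with `sbp < dbp` are physiologically impossible and
#' are flagged: the result is `NA` and a warning reports the count.
#'
#' @param sbp,dbp Blood pressures in mmHg (vectorised).
#' @return `sbp - dbp` in mmHg, `NA` where `sbp < dbp`.
#' @examples
#' pulse_pressure(120, 80)  # 40
#' @export
pulse_pressure <- function(sbp, dbp) {
  pp <- sbp - dbp
  bad <- !is.na(pp) & pp < 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with SBP < DBP flagged (pulse pressure set NA)")
    pp[bad] <- NA_real_
  }
  pp
}

#' Extreme-discordance selection criteria
#'
#' Holds the ascertainment thresholds as data. Defaults follow the rules for
#' blood-pressure sib pairs: a pair is *extreme discordant* when one sib is
#' hypertensive (SBP > 139 or DBP > 85 mmHg) and the other hypotensive
#' (SBP < 112 or DBP < 66 mmHg), or when the pair differs by more than
#' 25/20 mmHg (SBP/DBP); pairs differing by more than 15/14 mmHg pass the
#' initial *discordance* screen. All inequalities are strict. An alternative
#' centile rule selects pairs from the top and bottom 10% of a reference
#' blood-pressure distribution.
#'
#' @param hi_sbp,hi_dbp High-BP thresholds (mmHg, exclusive).
#' @param lo_sbp,lo_dbp Low-BP thresholds (mmHg, exclusive below).
#' @param diff_sbp,diff_dbp Extreme pairwise difference margins (mmHg).
#' @param screen_diff_sbp,screen_diff_dbp Screening difference margins (mmHg).
#' @param centile_lower,centile_upper Centile bounds (percent) for the
#'   centile rule.
#' @param diff_rule `"and"` (default) requires both the SBP and DBP margins
#'   to be exceeded in the difference rules; `"or"` requires either (the
#'   "25/20" shorthand is conventionally read as AND, but an OR reading is
#'   provided).
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(hi_sbp = 139, hi_dbp = 85,
                               lo_sbp = 112, lo_dbp = 66,
                               diff_sbp = 25, diff_dbp = 20,
                               screen_diff_sbp = 15, screen_diff_dbp = 14,
                               centile_lower = 10, centile_upper = 90,
                               diff_rule = c("and", "or")) {
  diff_rule <- match.arg(diff_rule)
  vals <- c(hi_sbp, hi_dbp, lo_sbp, lo_dbp, diff_sbp, diff_dbp,
            screen_diff_sbp, screen_diff_dbp)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive and finite")
  }
  if (lo_sbp >= hi_sbp || lo_dbp >= hi_dbp) {
    stop("low thresholds must lie below the high thresholds")
  }
  if (centile_lower >= centile_upper) {
    stop("`centile_lower` must be below `centile_upper`")
  }
  structure(list(hi_sbp = hi_sbp, hi_dbp = hi_dbp, lo_sbp = lo_sbp,
                 lo_dbp = lo_dbp, diff_sbp = diff_sbp, diff_dbp = diff_dbp,
                 screen_diff_sbp = screen_diff_sbp,
                 screen_diff_dbp = screen_diff_dbp,
                 centile_lower = centile_lower, centile_upper = centile_upper,
                 diff_rule = diff_rule),
            class = "selection_criteria")
}

#' @export
print.selection_criteria <- function(x, ...) {
  cat("Extreme-discordant sib-pair selection criteria (strict inequalities)\n")
  cat(sprintf("  threshold rule: one sib SBP > %g or DBP > %g; other SBP < %g or DBP < %g mmHg\n",
              x$hi_sbp, x$hi_dbp, x$lo_sbp, x$lo_dbp))
  cat(sprintf("  difference rule: |dSBP| > %g %s |dDBP| > %g mmHg\n",
              x$diff_sbp, toupper(x$diff_rule), x$diff_dbp))
  cat(sprintf("  discordance screen: |dSBP| > %g %s |dDBP| > %g mmHg\n",
              x$screen_diff_sbp, toupper(x$diff_rule), x$screen_diff_dbp))
  cat(sprintf("  centile rule: below %g%% / above %g%% of a reference distribution\n",
              x$centile_lower, x$centile_upper))
  invisible(x)
}

#' Nearest-rank centile thresholds from a reference sample
#'
#' Returns the lower and upper nearest-rank percentiles (type-1 quantiles) of
#' a reference sample, e.g. blood pressures from a large healthy screening
#' cohort, for use as centile selection cut-offs.
#'
#' @param reference Numeric vector of reference values (length >= 20).
#' @param lower_pct,upper_pct Percentiles in (0, 100).
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' centile_thresholds(1:100, 10, 90)  # c(low = 10, high = 90)
#' @export
centile_thresholds <- function(reference, lower_pct = 10, upper_pct = 90) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 20L) {
    stop("reference sample must contain at least 20 values")
  }
  if (lower_pct >= upper_pct) stop("`lower_pct` must be below `upper_pct`")
  s <- sort(reference)
  n <- length(s)
  pick <- function(p) s[max(1L, ceiling(p / 100 * n))]
  c(low = pick(lower_pct), high = pick(upper_pct))
}

# vectorised rule engine; returns label/rule/affected over parallel vectors
.classify_vec <- function(sbp1, dbp1, sbp2, dbp2, criteria) {
  hi1 <- sbp1 > criteria$hi_sbp | dbp1 > criteria$hi_dbp
  hi2 <- sbp2 > criteria$hi_sbp | dbp2 > criteria$hi_dbp
  lo1 <- sbp1 < criteria$lo_sbp | dbp1 < criteria$lo_dbp
  lo2 <- sbp2 < criteria$lo_sbp | dbp2 < criteria$lo_dbp
  thr <- (hi1 & lo2) | (hi2 & lo1)
  ds <- abs(sbp1 - sbp2); dd <- abs(dbp1 - dbp2)
  comb <- if (criteria$diff_rule == "and") `&` else `|`
  dif <- comb(ds > criteria$diff_sbp, dd > criteria$diff_dbp)
  scr <- comb(ds > criteria$screen_diff_sbp, dd > criteria$screen_diff_dbp)
  label <- ifelse(thr | dif, "extreme_discordant",
                  ifelse(scr, "discordant", "neither"))
  rule <- ifelse(thr, "threshold_rule",
                 ifelse(dif, "difference_rule",
                        ifelse(scr, "screen_only", "none")))
  list(label = label, rule = rule)
}

# affected sib: higher SBP, ties by higher DBP, then lexicographically
# smaller id
.affected_sib <- function(sbp1, dbp1, id1, sbp2, dbp2, id2) {
  pick2 <- (sbp2 > sbp1) | (sbp2 == sbp1 & dbp2 > dbp1) |
    (sbp2 == sbp1 & dbp2 == dbp1 & id2 < id1)
  ifelse(pick2, id2, id1)
}

#' Classify one sib pair as extreme discordant, discordant or neither
#'
#' Applies the threshold and difference rules of a [selection_criteria()]
#' object. The classification is symmetric in the two sibs except for
#' `affected_sib`, which names the higher-BP sib (higher SBP; ties broken by
#' higher DBP, then by the lexicographically smaller id).
#'
#' @param sib1,sib2 Lists or one-row data.frames with at least `sbp` and
#'   `dbp` (mmHg); an `individual_id` field is used for `affected_sib`.
#' @param criteria A [selection_criteria()].
#' @return A list with `label` (`extreme_discordant`, `discordant`,
#'   `neither`), `which_rule` (`threshold_rule`, `difference_rule`,
#'   `screen_only`, `none`) and `affected_sib`.
#' @examples
#' crit <- selection_criteria()
#' classify_pair(list(sbp = 143, dbp = 89, individual_id = "3"),
#'               list(sbp = 108, dbp = 66, individual_id = "4"), crit)
#' @export
classify_pair <- function(sib1, sib2, criteria = selection_criteria()) {
  for (s in list(sib1, sib2)) {
    if (is.null(s$sbp) || is.null(s$dbp) || is.na(s$sbp) || is.na(s$dbp)) {
      stop("classification error: sib with missing SBP or DBP")
    }
  }
  cl <- .classify_vec(sib1$sbp, sib1$dbp, sib2$sbp, sib2$dbp, criteria)
  id1 <- if (!is.null(sib1$individual_id)) as.character(sib1$individual_id) else "1"
  id2 <- if (!is.null(sib2$individual_id)) as.character(sib2$individual_id) else "2"
  list(label = cl$label, which_rule = cl$rule,
       affected_sib = .affected_sib(sib1$sbp, sib1$dbp, id1,
                                    sib2$sbp, sib2$dbp, id2))
}

#' Classify every sib pair of a cohort
#'
#' Vectorised application of [classify_pair()] (threshold/difference rules)
#' or of the centile rule, which calls a pair extreme discordant when one
#' sib lies at or above the upper cut and the other at or below the lower
#' cut of a reference distribution.
#'
#' @param cohort An `edsp_cohort`, or a list with `pairs` and `individuals`
#'   in the same layout.
#' @param criteria A [selection_criteria()].
#' @param method `"threshold"` (default; threshold + difference rules) or
#'   `"centile"`.
#' @param reference Numeric reference sample for the centile rule; defaults
#'   to the cohort's own offspring values of `phenotype`.
#' @param phenotype Phenotype used by the centile rule (default `"sbp"`).
#' @return A data.frame with one row per pair: family_id, sib1, sib2, label,
#'   which_rule, affected_sib. Pairs with missing phenotypes are labelled
#'   `NA` and a warning reports the count.
#' @export
classify_pairs <- function(cohort, criteria = selection_criteria(),
                           method = c("threshold", "centile"),
                           reference = NULL, phenotype = "sbp") {
  method <- match.arg(method)
  rows <- .pair_rows(cohort)
  ind <- cohort$individuals
  s1 <- ind[rows$s1, ]; s2 <- ind[rows$s2, ]
  miss <- is.na(s1$sbp) | is.na(s1$dbp) | is.na(s2$sbp) | is.na(s2$dbp)
  if (method == "threshold") {
    cl <- .classify_vec(s1$sbp, s1$dbp, s2$sbp, s2$dbp, criteria)
    label <- cl$label; rule <- cl$rule
  } else {
    if (is.null(reference)) {
      off <- ind[ind$role == "offspring", phenotype]
      reference <- off[!is.na(off)]
    }
    cuts <- centile_thresholds(reference, criteria$centile_lower,
                               criteria$centile_upper)
    x1 <- s1[[phenotype]]; x2 <- s2[[phenotype]]
    ext <- (x1 >= cuts[["high"]] & x2 <= cuts[["low"]]) |
      (x2 >= cuts[["high"]] & x1 <= cuts[["low"]])
    label <- ifelse(ext, "extreme_discordant", "neither")
    rule <- ifelse(ext, "centile_rule", "none")
  }
  affected <- .affected_sib(s1$sbp, s1$dbp, s1$individual_id,
                            s2$sbp, s2$dbp, s2$individual_id)
  if (any(miss)) {
    warning(sum(miss), " pair(s) with missing phenotypes excluded from classification")
    label[miss] <- NA_character_; rule[miss] <- NA_character_
    affected[miss] <- NA_character_
  }
  data.frame(family_id = cohort$pairs$family_id,
             sib1 = cohort$pairs$sib1, sib2 = cohort$pairs$sib2,
             label = label, which_rule = rule, affected_sib = affected,
             stringsAsFactors = FALSE)
}

#' Select extreme discordant sib pairs from a cohort
#'
#' Classifies every pair and keeps those labelled extreme discordant, in
#' stable family-id order. The staged counts (families screened, pairs past
#' the discordance screen, extreme discordant pairs) are attached as the
#' `"counts"` attribute, mirroring the recruitment funnel of an EDSP study.
#'
#' @inheritParams classify_pairs
#' @return The selected subset of the classification data.frame, with a
#'   `counts` attribute.
#' @export
select_edsp <- function(cohort, criteria = selection_criteria(),
                        method = c("threshold", "centile"),
                        reference = NULL, phenotype = "sbp") {
  cl <- classify_pairs(cohort, criteria, method, reference, phenotype)
  cl <- cl[order(cl$family_id), , drop = FALSE]
  sel <- cl[!is.na(cl$label) & cl$label == "extreme_discordant", , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "counts") <- c(
    n_families = nrow(cl),
    n_screened = sum(!is.na(cl$label) & cl$label != "neither"),
    n_edsp = nrow(sel))
  sel
}
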