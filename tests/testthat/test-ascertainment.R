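test_that("pulse pressure is SBP minus DBP with impossible records flagged", {
  expect_equal(pulse_pressure(120, 80), 40)
  expect_equal(pulse_pressure(95, 95), 0)
  # cohort-scale means: 125/77 mmHg implies a mean pulse pressure near 48
  expect_equal(pulse_pressure(125, 77), 48)
  expect_warning(pp <- pulse_pressure(c(120, 70), c(80, 90)), "SBP < DBP")
  expect_equal(pp, c(40, NA))
})

test_that("centile thresholds use nearest-rank percentiles", {
  expect_equal(centile_thresholds(1:100, 10, 90), c(low = 10, high = 90))
  expect_equal(centile_thresholds(rep(7, 25), 10, 90), c(low = 7, high = 7))
  expect_error(centile_thresholds(1:10, 10, 90), "at least 20")
  # large normal reference: cuts within 3 SE of the analytic quantiles
  # (SE of a sample quantile: sqrt(p(1-p)/n)/phi(z_p))
  ref <- simulate_reference_sample(5000, trait_model(), seed = 41)
  cuts <- centile_thresholds(ref$sbp, 10, 90)
  se_q <- sqrt(0.1 * 0.9 / 5000) / stats::dnorm(stats::qnorm(0.9)) * 18
  expect_lt(abs(cuts[["low"]] - stats::qnorm(0.10, 125, 18)), 3 * se_q)
  expect_lt(abs(cuts[["high"]] - stats::qnorm(0.90, 125, 18)), 3 * se_q)
})

test_that("classify_pair applies the threshold and difference rules", {
  crit <- selection_criteria()
  # hypertensive vs hypotensive sib (group-mean blood pressures)
  cl <- classify_pair(list(sbp = 143, dbp = 89, individual_id = "3"),
                      list(sbp = 108, dbp = 66, individual_id = "4"), crit)
  expect_equal(cl$label, "extreme_discordant")
  expect_equal(cl$which_rule, "threshold_rule")
  expect_equal(cl$affected_sib, "3")
  # difference rule alone: 25.5 > 25 and 20.5 > 20, no sib past the
  # high/low thresholds (the threshold rule takes precedence when both fire)
  cl2 <- classify_pair(list(sbp = 138, dbp = 70), list(sbp = 112.5, dbp = 49.5), crit)
  expect_equal(cl2$label, "extreme_discordant")
  expect_equal(cl2$which_rule, "difference_rule")
  # identical phenotypes
  cl3 <- classify_pair(list(sbp = 120, dbp = 80), list(sbp = 120, dbp = 80), crit)
  expect_equal(cl3$label, "neither")
  # past the 15/14 screen but not extreme
  cl4 <- classify_pair(list(sbp = 130, dbp = 85), list(sbp = 114, dbp = 70), crit)
  expect_equal(cl4$label, "discordant")
  expect_equal(cl4$which_rule, "screen_only")
  expect_error(classify_pair(list(sbp = NA, dbp = 80), list(sbp = 120, dbp = 80),
                             crit), "missing")
})

test_that("classification is symmetric except for the affected sib", {
  crit <- selection_criteria()
  set.seed(43)
  for (i in 1:25) {
    s1 <- list(sbp = runif(1, 90, 160), dbp = runif(1, 50, 100),
               individual_id = "a")
    s2 <- list(sbp = runif(1, 90, 160), dbp = runif(1, 50, 100),
               individual_id = "b")
    a <- classify_pair(s1, s2, crit)
    b <- classify_pair(s2, s1, crit)
    expect_identical(a$label, b$label)
    expect_identical(a$which_rule, b$which_rule)
    expect_identical(a$affected_sib, b$affected_sib)
  }
  # ties: equal SBP broken by DBP, equal both broken lexicographically
  tie1 <- classify_pair(list(sbp = 130, dbp = 70, individual_id = "3"),
                        list(sbp = 130, dbp = 80, individual_id = "4"))
  expect_equal(tie1$affected_sib, "4")
  tie2 <- classify_pair(list(sbp = 130, dbp = 80, individual_id = "4"),
                        list(sbp = 130, dbp = 80, individual_id = "3"))
  expect_equal(tie2$affected_sib, "3")
})

test_that("tightening thresholds never increases the selected count", {
  ch <- simulate_families(400, model_qtl50(), equifreq_markers(1, theta = 0),
                          seed = 47)
  n_sel <- function(crit) nrow(select_edsp(ch, crit))
  base <- selection_criteria()
  for (arg in c("diff_sbp", "diff_dbp", "hi_sbp", "hi_dbp")) {
    for (bump in c(5, 10, 20)) {
      args <- list(); args[[arg]] <- base[[arg]] + bump
      tighter <- do.call(selection_criteria, args)
      expect_lte(n_sel(tighter), n_sel(base))
    }
  }
  # extreme pairs under the 25/20 AND-rule always pass the 15/14 screen
  cl <- classify_pairs(ch)
  dif <- cl$which_rule == "difference_rule"
  expect_true(all(cl$label[dif] == "extreme_discordant"))
})

test_that("select_edsp agrees with exhaustive per-pair reclassification", {
  ch <- simulate_families(300, model_qtl50(), equifreq_markers(1, theta = 0),
                          seed = 53)
  crit <- selection_criteria()
  sel <- select_edsp(ch, crit)
  # oracle: re-apply the scalar classifier to every pair
  rows <- ch$individuals
  oracle <- character(0)
  for (i in seq_len(nrow(ch$pairs))) {
    fam <- ch$pairs$family_id[i]
    s1 <- as.list(rows[rows$family_id == fam & rows$individual_id == "3", ])
    s2 <- as.list(rows[rows$family_id == fam & rows$individual_id == "4", ])
    if (classify_pair(s1, s2, crit)$label == "extreme_discordant") {
      oracle <- c(oracle, fam)
    }
  }
  expect_identical(sel$family_id, sort(oracle))
  counts <- attr(sel, "counts")
  expect_equal(unname(counts[["n_edsp"]]), nrow(sel))
  expect_lte(counts[["n_edsp"]], counts[["n_screened"]])
  # selection is invariant to sib ordering within a pair
  ch_swap <- ch
  ch_swap$pairs$sib1 <- ch$pairs$sib2
  ch_swap$pairs$sib2 <- ch$pairs$sib1
  sel_swap <- select_edsp(ch_swap, crit)
  expect_identical(sel$family_id, sel_swap$family_id)
  expect_identical(sel$affected_sib, sel_swap$affected_sib)
})

test_that("cohorts without extreme pairs select nothing", {
  m0 <- trait_model(additive_effect_sbp = 0, additive_effect_dbp = 0,
                    polygenic_sd_sbp = 0, polygenic_sd_dbp = 0,
                    env_sd_sbp = 0.1, env_sd_dbp = 0.1)
  ch <- simulate_families(50, m0, equifreq_markers(1), seed = 59)
  sel <- select_edsp(ch)
  expect_equal(nrow(sel), 0L)
})

test_that("the centile rule selects opposite-decile pairs", {
  ch <- simulate_families(2000, model_qtl50(), equifreq_markers(1, theta = 0),
                          seed = 61)
  sel <- select_edsp(ch, method = "centile")
  expect_gt(nrow(sel), 0L)
  off <- ch$individuals[ch$individuals$role == "offspring", ]
  cuts <- centile_thresholds(off$sbp, 10, 90)
  key <- paste(ch$individuals$family_id, ch$individuals$individual_id)
  for (i in seq_len(nrow(sel))) {
    x1 <- ch$individuals$sbp[match(paste(sel$family_id[i], sel$sib1[i]), key)]
    x2 <- ch$individuals$sbp[match(paste(sel$family_id[i], sel$sib2[i]), key)]
    expect_true((max(x1, x2) >= cuts[["high"]]) && (min(x1, x2) <= cuts[["low"]]))
  }
})
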