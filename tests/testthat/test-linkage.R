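test_that("squared trait difference is symmetric and zero at equality", {
  expect_equal(squared_trait_difference(143, 108), 1225)
  expect_equal(squared_trait_difference(108, 143), 1225)
  expect_equal(squared_trait_difference(95, 95), 0)
  expect_true(is.na(squared_trait_difference(NA, 100)))
})

test_that("the t transform reproduces the printed correlation p-values", {
  # n = 24 sib pairs, 22 df
  expect_equal(round(r_to_p(-0.51, 24), 3), 0.011)
  expect_equal(round(r_to_p(-0.44, 24), 3), 0.031)
  expect_equal(round(r_to_p(-0.42, 24), 3), 0.041)
  expect_equal(r_to_p(0, 24), 1)
  # dual route: agrees with cor.test on arbitrary data
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(24); y <- rnorm(24) - 0.3 * x
    ct <- stats::cor.test(x, y)
    pt_ <- pearson_linkage_test(y, x)
    expect_equal(pt_$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pt_$p_two_sided, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_linkage_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_linkage_test(rnorm(10), rep(0.5, 10)), "constant")
})

test_that("Haseman-Elston regression matches hand-computed least squares", {
  # collinear 4-point line: slope -2, intercept 4, r = -1
  suppressWarnings(fit <- haseman_elston(c(4, 2, 0, -2), c(0, 1, 2, 3)))
  expect_equal(unname(coef(fit)), c(4, -2), tolerance = 1e-10)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-10)
  # noisy case checked against an explicit normal-equations oracle
  set.seed(103)
  x <- c(0, 0, 1, 1, 1, 2, 2, 0.5, 1.5, 1)
  y <- 300 - 80 * x + rnorm(10, 0, 30)
  fit2 <- haseman_elston(y, x)
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(coef(fit2)), as.numeric(beta), tolerance = 1e-10)
  expect_equal(sign(fit2$pearson_r), sign(coef(fit2)[["slope"]]))
  # one/two-sided relationship for the slope test
  expect_equal(fit2$p_two_sided,
               2 * min(fit2$p_one_sided, 1 - fit2$p_one_sided))
  # methods behave
  expect_length(residuals(fit2), 10L)
  expect_equal(unname(predict(fit2, newdata = data.frame(x = 0))),
               unname(coef(fit2)[["intercept"]]), tolerance = 1e-10)
  expect_error(haseman_elston(rep(2, 8), seq(0, 2, length.out = 8)), "constant")
})

test_that("the null Haseman-Elston test is approximately exact", {
  # unlinked marker, modest replicate count (the full calibration lives in
  # the acceptance suite): rejection near the nominal level
  mk <- equifreq_markers(1, theta = 0.5)
  set.seed(107)
  seeds <- sample.int(2^31 - 2, 400)
  rej <- logical(400)
  for (i in seq_along(seeds)) {
    ch <- mask_parents(simulate_families(24, trait_model(), mk, seed = seeds[i]))
    sh <- sharing_table(ch)
    pp <- pair_phenotypes(ch)
    rej[i] <- haseman_elston(pp$d2_sbp, sh$expected_shared)$p_one_sided < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("adjusted regression returns standardized betas", {
  # single predictor: standardized beta equals the Pearson correlation
  set.seed(109)
  x <- rnorm(40); y <- 3 - x + rnorm(40)
  af <- adjusted_regression(y, x)
  expect_equal(af$terms$beta, stats::cor(x, y), tolerance = 1e-12)
  # known generating model recovered (n large enough for tight sampling)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y2 <- 2 * x1 - x2 + rnorm(n, 0, 0.1)
  af2 <- adjusted_regression(y2, x2, covariates = data.frame(x1 = x1),
                             marker_label = "x2")
  oracle <- ne_std_betas(y2, data.frame(x1 = x1, x2 = x2))
  expect_equal(af2$terms$beta, oracle, tolerance = 1e-8)
  pop <- c(2, -1) / sqrt(2^2 + 1 + 0.1^2)
  expect_lt(max(abs(af2$terms$beta - pop)), 0.05)
  expect_lte(af2$adjusted_r2, 1)
  expect_gt(af2$adjusted_r2, 0.99)
  # degenerate designs are refused with the offending term named
  expect_error(adjusted_regression(y2, x2,
                                   covariates = data.frame(const = rep(1, n))),
               "constant term.*const")
  expect_error(adjusted_regression(y2, x2,
                                   covariates = data.frame(dup = x2)),
               "collinear")
})

test_that("the sharing LRT has its closed form on fully informative pairs", {
  # all 10 pairs certainly IBD 0: LR = 2 * 10 * log(1/0.25)
  W0 <- matrix(rep(c(1, 0, 0), each = 10), ncol = 3)
  res <- sharing_lrt(W0, n_perm = 199, seed = 1)
  expect_equal(res$lr_stat, 20 * log(4), tolerance = 1e-9)
  expect_equal(unname(res$z_hat), c(1, 0, 0), tolerance = 1e-6)
  expect_lt(res$p_perm, 0.02)
  # the deficit-constrained alternative contains this maximiser
  res_d <- sharing_lrt(W0, direction = "deficit", n_perm = 199, seed = 1)
  expect_equal(res_d$lr_stat, 20 * log(4), tolerance = 1e-6)
  # empirical sharing exactly at the prior: LR 0, p near 1
  W1 <- matrix(rep(c(1, 0, 0, 0, 1, 0, 0, 1, 0, 0, 0, 1),
                   times = 3), ncol = 3, byrow = TRUE)
  res1 <- sharing_lrt(W1, n_perm = 199, seed = 2)
  expect_equal(res1$lr_stat, 0, tolerance = 1e-9)
  expect_gt(res1$p_perm, 0.9)
  # mixed-count closed form (counts 4/4/2 of IBD 0/1/2 over 10 pairs)
  W2 <- diag(3)[c(rep(1, 4), rep(2, 4), rep(3, 2)), ]
  res2 <- sharing_lrt(W2, n_perm = 99, seed = 3)
  expect_equal(res2$lr_stat, lrt_closed_form(c(4, 4, 2)), tolerance = 1e-7)
  expect_error(sharing_lrt(W0[1, , drop = FALSE]), "at least 2")
})

test_that("posterior input to the sharing LRT undoes the prior weighting", {
  # a posterior of (1,0,0) and a likelihood of (1,0,0) carry the same
  # information; mixed posteriors match the corresponding likelihood route
  set.seed(113)
  L <- matrix(runif(30), ncol = 3)
  L <- L / rowSums(L)
  post <- sweep(L, 2, c(0.25, 0.5, 0.25), `*`)
  post <- post / rowSums(post)
  a <- sharing_lrt(L, type = "likelihood", n_perm = 49, seed = 4)
  b <- sharing_lrt(post, type = "posterior", n_perm = 49, seed = 4)
  expect_equal(a$lr_stat, b$lr_stat, tolerance = 1e-8)
  expect_equal(a$z_hat, b$z_hat, tolerance = 1e-6)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(127)
  n_rep <- 400
  pvals <- numeric(n_rep)
  eye <- diag(3)
  for (i in seq_len(n_rep)) {
    k <- sample.int(3, 20, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    pvals[i] <- sharing_lrt(eye[k, ], type = "likelihood", n_perm = 99,
                            seed = 1000 + i)$p_perm
  }
  d <- suppressWarnings(stats::ks.test(pvals, "punif")$statistic)
  # KS band: 1.63/sqrt(400) ~ 0.082 at alpha = 0.01, plus permutation
  # discreteness of 1/100
  expect_lt(unname(d), 0.09)
})

test_that("cohort summaries split by the affected sib", {
  ch <- mask_parents(simulate_families(600, model_qtl50(),
                                       equifreq_markers(1, theta = 0),
                                       seed = 131))
  sel <- select_edsp(ch)
  expect_gt(nrow(sel), 10L)
  summ <- cohort_summary(ch, sel)
  expect_true(all(c("age", "sbp", "dbp", "pp") %in% summ$variable))
  sbp <- summ[summ$variable == "sbp", ]
  expect_gt(sbp$affected_mean, sbp$unaffected_mean)
  expect_lt(sbp$p_welch, 0.01)
  # ages should not differ systematically between the groups
  expect_gt(summ$p_welch[summ$variable == "age"], 0.001)
  # single pair: SD and p undefined but means reported
  one <- sel[1, , drop = FALSE]
  s1 <- cohort_summary(ch, one)
  expect_true(all(is.na(s1$affected_sd)))
  expect_true(all(is.na(s1$p_welch)))
  expect_false(any(is.na(s1$affected_mean)))
})

test_that("the linkage scan separates linked from unlinked markers", {
  mk <- list(marker_def("LINKED", 8, theta = 0),
             marker_def("UNLINKED", 8, theta = 0.5))
  ch <- mask_parents(simulate_families(800, model_qtl50(), mk, seed = 137))
  sel <- select_edsp(ch)
  sh <- sharing_table(ch, pairs = sel)
  pp <- pair_phenotypes(ch, sel)
  scan <- edsp_scan(sh, pp)
  expect_s3_class(scan, "edsp_scan")
  expect_equal(nrow(scan), 6L)
  expect_true(all(c("marker", "phenotype", "n_pairs", "r", "p_two_sided",
                    "he_slope", "he_p_one_sided", "beta_marker", "adj_r2",
                    "p_bonferroni") %in% names(scan)))
  r_linked <- scan$r[scan$marker == "LINKED" & scan$phenotype == "sbp"]
  expect_lt(r_linked, 0)
  expect_true(all(scan$p_bonferroni >= scan$p_two_sided, na.rm = TRUE))
  # adjusted marker beta carries the same sign as the raw correlation
  b_linked <- scan$beta_marker[scan$marker == "LINKED" & scan$phenotype == "sbp"]
  expect_lt(b_linked, 0)
})
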