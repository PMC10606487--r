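#' Squared sib difference of a phenotype
#'
#' The Haseman-Elston response variable: the squared within-pair difference
#' of a quantitative phenotype, in squared units (mmHg^2 for blood
#' pressure). Order-invariant; `NA` if either value is missing (the pair is
#' excluded for that phenotype).
#'
#' @param x1,x2 Phenotype values of the two sibs (vectorised).
#' @return `(x1 - x2)^2`.
#' @examples
#' squared_trait_difference(143, 108)  # 1225
#' @export
squared_trait_difference <- function(x1, x2) (x1 - x2)^2

#' Two-sided p-value from a Pearson correlation
#'
#' The exact t transform: \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} referred to the
#' t distribution on n - 2 degrees of freedom. With n = 24 pairs this maps
#' r = -0.51 to p = 0.011 and r = -0.44 to p = 0.031 (two-sided, 3 dp).
#'
#' @param r Pearson correlation coefficient(s).
#' @param n Sample size (number of pairs).
#' @param two_sided Two-sided (default) or one-sided (lower tail) p.
#' @return p-value(s).
#' @export
r_to_p <- function(r, n, two_sided = TRUE) {
  if (any(n < 3)) stop("`n` must be at least 3")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  if (two_sided) 2 * stats::pt(-abs(t), n - 2) else stats::pt(t, n - 2)
}

#' Pearson correlation linkage test
#'
#' Correlation between the squared sib phenotype differences and the
#' expected number of alleles shared IBD, with its two-sided t-based
#' p-value. A significant negative correlation is evidence of linkage.
#'
#' @param y Squared sib differences (one per pair).
#' @param x Expected alleles shared IBD per pair (`expected_shared`; using
#'   `pihat` instead rescales x by 2 and leaves r and p unchanged).
#' @return List with `r`, `p_two_sided`, `t_stat`, `n`.
#' @export
pearson_linkage_test <- function(y, x) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  r <- stats::cor(x, y)
  list(r = r, p_two_sided = r_to_p(r, n),
       t_stat = r * sqrt(n - 2) / sqrt(1 - r^2), n = n)
}

#' Haseman-Elston regression of squared sib differences on IBD sharing
#'
#' Ordinary least squares of the squared within-pair phenotype difference on
#' the expected number of alleles shared IBD at a marker. Under linkage the
#' slope is negative (pairs sharing more alleles are phenotypically more
#' alike), so the classical test is one-sided on the slope
#' (H1: slope < 0) using the t distribution on n - 2 df. The Pearson
#' correlation test is embedded; slope and correlation always share sign.
#'
#' @param y Squared sib phenotype differences (mmHg^2), one per pair.
#' @param x Expected alleles shared IBD per pair.
#' @param phenotype,marker Optional labels stored in the fit.
#' @return An object of class `he_fit` with coefficients, slope SE, t
#'   statistic, one- and two-sided slope p-values, the embedded Pearson
#'   test, and the underlying `lm` fit. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()`, `fitted()` and `plot()`.
#' @examples
#' fit <- haseman_elston(c(4, 2, 0, 3), c(0, 1, 2, 0.5))
#' coef(fit)
#' @export
haseman_elston <- function(y, x, phenotype = NULL, marker = NULL) {
  ok <- stats::complete.cases(x, y)
  dat <- data.frame(x = x[ok], y = y[ok])
  n <- nrow(dat)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(dat$x) == 0 || stats::sd(dat$y) == 0) {
    stop("undefined correlation: constant input")
  }
  fit <- stats::lm(y ~ x, data = dat)
  sm <- summary(fit)$coefficients
  t_slope <- sm["x", "t value"]
  p_one <- stats::pt(t_slope, n - 2)          # H1: slope < 0
  pear <- pearson_linkage_test(dat$y, dat$x)
  structure(list(
    call = match.call(), n_pairs = n,
    coefficients = c(intercept = unname(sm["(Intercept)", "Estimate"]),
                     slope = unname(sm["x", "Estimate"])),
    slope_se = unname(sm["x", "Std. Error"]),
    t_stat = unname(t_slope),
    p_one_sided = unname(p_one),
    p_two_sided = unname(2 * min(p_one, 1 - p_one)),
    pearson_r = pear$r, pearson_p = pear$p_two_sided,
    phenotype = phenotype, marker = marker,
    lm = fit, data = dat
  ), class = "he_fit")
}

#' @export
print.he_fit <- function(x, digits = 4, ...) {
  lab <- paste0(
    if (!is.null(x$phenotype)) paste0(x$phenotype, " ") else "",
    if (!is.null(x$marker)) paste0("@ ", x$marker, " ") else "")
  cat(sprintf("Haseman-Elston regression %s(%d pairs)\n", lab, x$n_pairs))
  cat(sprintf("  slope = %s mmHg^2 per shared allele (SE %s), one-sided p = %s\n",
              format(x$coefficients[["slope"]], digits = digits),
              format(x$slope_se, digits = digits),
              format(x$p_one_sided, digits = digits)))
  cat(sprintf("  Pearson r = %s, two-sided p = %s\n",
              format(x$pearson_r, digits = digits),
              format(x$pearson_p, digits = digits)))
  invisible(x)
}

#' @export
summary.he_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying OLS fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.he_fit <- function(object, ...) object$coefficients

#' @export
predict.he_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$lm)
  else stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.he_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.he_fit <- function(object, ...) stats::fitted(object$lm)

#' Scatter of squared differences against IBD sharing with the fitted line
#'
#' @param x An `he_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.he_fit <- function(x, ...) {
  ylab <- if (!is.null(x$phenotype)) {
    sprintf("Squared %s difference (mmHg²)", toupper(x$phenotype))
  } else "Squared sib difference"
  main <- if (!is.null(x$marker)) x$marker else ""
  graphics::plot(x$data$x, x$data$y, xlab = "Alleles shared IBD (expected)",
                 ylab = ylab, main = main, pch = 19, ...)
  graphics::abline(x$lm, lty = 2)
}

#' Covariate-adjusted linkage regression (standardized coefficients)
#'
#' Multiple OLS of the squared sib phenotype difference on IBD sharing plus
#' confounders (pair mean age and number of males by default), with the
#' response and every predictor z-scored so coefficients are standardized
#' betas; reported per term with its p-value plus the adjusted R^2. With a
#' single predictor the standardized beta equals the Pearson r.
#'
#' @param y Response (squared sib differences), one per pair.
#' @param x IBD sharing predictor (`expected_shared`).
#' @param covariates Data.frame of confounders (e.g. `mean_age`, `n_males`),
#'   or `NULL`.
#' @param marker_label Label for the sharing term (default `"marker"`).
#' @param condition_limit Condition-number threshold above which the design
#'   is declared collinear.
#' @return An object of class `adjusted_fit`: list with `terms` (data.frame
#'   term, beta, p), `adjusted_r2` and `n`.
#' @export
adjusted_regression <- function(y, x, covariates = NULL,
                                marker_label = "marker",
                                condition_limit = 1e8) {
  X <- if (is.null(covariates)) data.frame(row.names = seq_along(y))
       else as.data.frame(covariates)
  X[[marker_label]] <- x
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("need more pairs than model terms")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("collinear design: constant term(s): ",
         paste(names(X)[sds == 0], collapse = ", "))
  }
  if (stats::sd(y) == 0) stop("constant response")
  Z <- scale(as.matrix(X))
  if (kappa(cbind(1, Z), exact = TRUE) > condition_limit) {
    stop("collinear design (condition number above threshold): ",
         paste(names(X), collapse = ", "))
  }
  zy <- as.numeric(scale(y))
  fit <- stats::lm(zy ~ Z)
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  structure(list(
    terms = data.frame(term = names(X), beta = unname(co[, "Estimate"]),
                       p = unname(co[, "Pr(>|t|)"]), stringsAsFactors = FALSE),
    adjusted_r2 = sm$adj.r.squared, n = n, lm = fit
  ), class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Adjusted linkage regression (standardized betas, %d pairs)\n", x$n))
  tab <- x$terms
  tab$beta <- round(tab$beta, digits)
  tab$p <- round(tab$p, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Adjusted R^2 = %.3f\n", x$adjusted_r2))
  invisible(x)
}

# mixture MLE of sharing probabilities z over the simplex by EM;
# W is an n x 3 matrix of renormalized prior-free weights
.sharing_mle <- function(W, start = c(0.25, 0.5, 0.25), tol = 1e-10,
                         max_iter = 1000L) {
  z <- start
  for (it in seq_len(max_iter)) {
    R <- sweep(W, 2L, z, `*`)
    R <- R / rowSums(R)
    z_new <- colMeans(R)
    if (max(abs(z_new - z)) < tol) { z <- z_new; break }
    z <- z_new
  }
  z
}

.sharing_loglik <- function(z, W) sum(log(as.vector(W %*% z)))

# constrained MLE for the deficit direction: z0 >= 1/4 and z2 <= 1/4
.sharing_mle_deficit <- function(W) {
  nll <- function(par) {
    z <- c(par[1L], par[2L], 1 - par[1L] - par[2L])
    if (any(z < 0) || any(z > 1)) return(1e10)
    -.sharing_loglik(pmax(z, 1e-12), W)
  }
  ui <- rbind(c(1, 0), c(0, 1), c(-1, -1), c(1, 1))
  ci <- c(0.25, 0, -1, 0.75)
  opt <- stats::constrOptim(c(0.3, 0.55), nll, grad = NULL,
                            ui = ui, ci = ci - 1e-9)
  z <- c(opt$par, 1 - sum(opt$par))
  pmin(pmax(z, 0), 1)
}

#' Allele-sharing likelihood-ratio linkage test
#'
#' Non-parametric likelihood-ratio test of the sib-pair IBD sharing
#' probabilities \eqn{z = (z_0, z_1, z_2)} against the null full-sib values
#' (1/4, 1/2, 1/4), in the style of sib-pair allele-sharing linkage
#' software. Each pair contributes a prior-free weight vector
#' \eqn{w_k \propto L_k} (its genotype likelihoods given IBD state,
#' renormalized); the sharing likelihood
#' \eqn{L(z) = \prod_i \sum_k z_k w_{ik}} is maximized over the probability
#' simplex (direction `"deficit"` constrains \eqn{z_0 \ge 1/4} and
#' \eqn{z_2 \le 1/4}, the relevant alternative for extreme *discordant*
#' pairs). The statistic is \eqn{2[\log L(\hat z) - \log L(1/4,1/2,1/4)]}.
#' Because the MLE often lies on the simplex boundary at small n, the
#' p-value is obtained by seeded permutation: each pair's weight vector is
#' re-drawn under the null prior and the statistic recomputed.
#'
#' @param posteriors An n x 3 matrix/data.frame of per-pair IBD posteriors
#'   `(f0, f1, f2)` at one marker (rows with `NA` are dropped as
#'   uninformative), as produced by [sharing_table()]; or a matrix of raw
#'   likelihoods with `type = "likelihood"`.
#' @param direction `"any"` (unconstrained) or `"deficit"`.
#' @param n_perm Number of permutation replicates (>= 1000 recommended).
#' @param seed Integer seed for the permutation draws.
#' @param prior IBD prior used to undo the posterior weighting and to draw
#'   null permutations.
#' @param type Whether `posteriors` are prior-weighted posteriors (default)
#'   or prior-free likelihoods.
#' @return An object of class `sharing_lrt`: list with `z_hat`, `lr_stat`,
#'   `p_perm`, `n_perm`, `n_pairs`, `seed`, `direction`.
#' @examples
#' # 10 fully informative pairs all sharing 0 alleles: LR = 2 * 10 * log 4
#' f <- matrix(rep(c(1, 0, 0), each = 10), ncol = 3)
#' sharing_lrt(f, n_perm = 99, seed = 1)$lr_stat
#' @export
sharing_lrt <- function(posteriors, direction = c("any", "deficit"),
                        n_perm = 1000L, seed = 1L,
                        prior = c(0.25, 0.5, 0.25),
                        type = c("posterior", "likelihood")) {
  direction <- match.arg(direction)
  type <- match.arg(type)
  W <- as.matrix(posteriors)[, 1:3, drop = FALSE]
  W <- W[stats::complete.cases(W), , drop = FALSE]
  if (nrow(W) < 2L) stop("need at least 2 informative pairs")
  if (type == "posterior") W <- sweep(W, 2L, prior, `/`)
  W <- W / rowSums(W)
  n <- nrow(W)

  max_stat <- function(W) {
    z <- .sharing_mle(W)
    if (direction == "deficit" && !(z[1L] >= 0.25 - 1e-9 && z[3L] <= 0.25 + 1e-9)) {
      z <- .sharing_mle_deficit(W)
    }
    list(z = z,
         lr = max(0, 2 * (.sharing_loglik(z, W) - .sharing_loglik(prior, W))))
  }
  obs <- max_stat(W)

  set.seed(as.integer(seed))
  perm <- numeric(n_perm)
  eye <- diag(3)
  for (b in seq_len(n_perm)) {
    k <- sample.int(3L, n, replace = TRUE, prob = prior)
    perm[b] <- max_stat(eye[k, , drop = FALSE])$lr
  }
  p <- (1 + sum(perm >= obs$lr - 1e-12)) / (n_perm + 1)
  structure(list(z_hat = stats::setNames(obs$z, c("z0", "z1", "z2")),
                 lr_stat = obs$lr, p_perm = p, n_perm = n_perm,
                 n_pairs = n, seed = as.integer(seed), direction = direction),
            class = "sharing_lrt")
}

#' @export
print.sharing_lrt <- function(x, ...) {
  cat(sprintf("Allele-sharing likelihood-ratio test (%d pairs, direction = %s)\n",
              x$n_pairs, x$direction))
  cat(sprintf("  z_hat = (%.3f, %.3f, %.3f); LR = %.3f; permutation p = %.4f (%d perms)\n",
              x$z_hat[1L], x$z_hat[2L], x$z_hat[3L], x$lr_stat, x$p_perm,
              x$n_perm))
  invisible(x)
}

#' Pair-level phenotype table for the linkage tests
#'
#' For each sib pair: squared differences of SBP, DBP and pulse pressure,
#' pair mean age, number of males and a same-sex indicator.
#'
#' @param cohort An `edsp_cohort` (or list with `individuals` and `pairs`).
#' @param pairs Optional subset of pairs (e.g. a [select_edsp()] result).
#' @return A data.frame: family_id, sib1, sib2, d2_sbp, d2_dbp, d2_pp,
#'   mean_age, n_males, same_sex.
#' @export
pair_phenotypes <- function(cohort, pairs = NULL) {
  if (is.null(pairs)) pairs <- cohort$pairs
  key <- paste(cohort$individuals$family_id, cohort$individuals$individual_id)
  r1 <- match(paste(pairs$family_id, pairs$sib1), key)
  r2 <- match(paste(pairs$family_id, pairs$sib2), key)
  i1 <- cohort$individuals[r1, ]; i2 <- cohort$individuals[r2, ]
  data.frame(
    family_id = pairs$family_id, sib1 = pairs$sib1, sib2 = pairs$sib2,
    d2_sbp = squared_trait_difference(i1$sbp, i2$sbp),
    d2_dbp = squared_trait_difference(i1$dbp, i2$dbp),
    d2_pp = squared_trait_difference(i1$pp, i2$pp),
    mean_age = (i1$age + i2$age) / 2,
    n_males = (i1$sex == 1L) + (i2$sex == 1L),
    same_sex = i1$sex == i2$sex,
    stringsAsFactors = FALSE
  )
}

#' Marker-by-phenotype linkage scan
#'
#' Runs the Pearson correlation test, the Haseman-Elston regression and
#' (optionally) the covariate-adjusted regression for every marker and
#' phenotype, assembling the standard results table. Raw p-values are
#' reported; a Bonferroni-adjusted column is emitted for reference but is
#' never used for gating.
#'
#' @param sharing A [sharing_table()] data.frame.
#' @param pair_pheno A [pair_phenotypes()] data.frame.
#' @param phenotypes Phenotypes to scan (subset of `"sbp"`, `"dbp"`, `"pp"`).
#' @param adjust Include the age/sex-adjusted regression terms.
#' @return An object of classes `edsp_scan`/`data.frame`: one row per
#'   (marker, phenotype) with n_pairs, r, p_two_sided, he_slope, he_se,
#'   he_p_one_sided, p_bonferroni and, when `adjust = TRUE`, the
#'   standardized betas and p-values for age, sex and marker plus the
#'   adjusted R^2.
#' @export
edsp_scan <- function(sharing, pair_pheno, phenotypes = c("sbp", "dbp", "pp"),
                      adjust = TRUE) {
  phenotypes <- match.arg(phenotypes, several.ok = TRUE)
  markers <- unique(sharing$marker)
  key <- paste(pair_pheno$family_id, pair_pheno$sib1, pair_pheno$sib2)
  rows <- list()
  for (mk in markers) {
    sh <- sharing[sharing$marker == mk & sharing$informative, , drop = FALSE]
    idx <- match(paste(sh$family_id, sh$sib1, sh$sib2), key)
    pp <- pair_pheno[idx, , drop = FALSE]
    for (ph in phenotypes) {
      y <- pp[[paste0("d2_", ph)]]
      x <- sh$expected_shared
      row <- data.frame(marker = mk, phenotype = ph,
                        n_pairs = sum(stats::complete.cases(x, y)),
                        r = NA_real_, p_two_sided = NA_real_,
                        he_slope = NA_real_, he_se = NA_real_,
                        he_p_one_sided = NA_real_, stringsAsFactors = FALSE)
      fit <- tryCatch(haseman_elston(y, x, phenotype = ph, marker = mk),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        row$r <- fit$pearson_r
        row$p_two_sided <- fit$pearson_p
        row$he_slope <- fit$coefficients[["slope"]]
        row$he_se <- fit$slope_se
        row$he_p_one_sided <- fit$p_one_sided
      }
      if (adjust) {
        row$beta_age <- row$p_age <- row$beta_sex <- row$p_sex <-
          row$beta_marker <- row$p_marker <- row$adj_r2 <- NA_real_
        af <- tryCatch(
          adjusted_regression(y, x,
                              covariates = data.frame(age = pp$mean_age,
                                                      sex = pp$n_males),
                              marker_label = mk),
          error = function(e) NULL)
        if (!is.null(af)) {
          row$beta_age <- af$terms$beta[1L]; row$p_age <- af$terms$p[1L]
          row$beta_sex <- af$terms$beta[2L]; row$p_sex <- af$terms$p[2L]
          row$beta_marker <- af$terms$beta[3L]; row$p_marker <- af$terms$p[3L]
          row$adj_r2 <- af$adjusted_r2
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_two_sided * nrow(out))
  class(out) <- c("edsp_scan", "data.frame")
  out
}

#' @export
print.edsp_scan <- function(x, ...) {
  cat(sprintf("Linkage scan: %d markers x %d phenotypes\n",
              length(unique(x$marker)), length(unique(x$phenotype))))
  show <- as.data.frame(x)[c("marker", "phenotype", "n_pairs", "r",
                             "p_two_sided", "he_slope", "he_p_one_sided")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], function(v) round(v, 3))  # display only
  print(show, row.names = FALSE)
  invisible(x)
}

#' Cohort summary table split by affected status
#'
#' Demographic and haemodynamic summary of selected sib pairs in the style
#' of a cohort characteristics table: per variable, mean and SD for all
#' genotyped individuals and for the affected (higher-BP) and unaffected
#' sibs separately, with a two-sample Welch t-test p-value. SDs of
#' single-observation groups and their p-values are reported as `NA`.
#'
#' @param cohort An `edsp_cohort`.
#' @param classification A [classify_pairs()]/[select_edsp()] data.frame
#'   (the `affected_sib` column drives the split).
#' @param variables Individual-level variables to summarise; entries absent
#'   from the cohort (e.g. height) are skipped.
#' @return An object of classes `cohort_summary`/`data.frame`.
#' @export
cohort_summary <- function(cohort, classification,
                           variables = c("age", "height", "weight", "bmi",
                                         "sbp", "dbp", "pp")) {
  cl <- classification[!is.na(classification$affected_sib), , drop = FALSE]
  if (nrow(cl) == 0L) stop("no classified pairs")
  ind <- cohort$individuals
  key <- paste(ind$family_id, ind$individual_id)
  aff <- match(paste(cl$family_id, cl$affected_sib), key)
  other <- ifelse(cl$affected_sib == cl$sib1, cl$sib2, cl$sib1)
  unaff <- match(paste(cl$family_id, other), key)
  variables <- intersect(variables, names(ind))
  stat <- function(v, rows) {
    x <- ind[rows, v]
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) >= 2L) stats::sd(x) else NA_real_)
  }
  rows <- lapply(variables, function(v) {
    a <- stat(v, aff); u <- stat(v, unaff); al <- stat(v, c(aff, unaff))
    p <- tryCatch(stats::t.test(ind[aff, v], ind[unaff, v])$p.value,
                  error = function(e) NA_real_)
    data.frame(variable = v, all_mean = al[["mean"]], all_sd = al[["sd"]],
               affected_mean = a[["mean"]], affected_sd = a[["sd"]],
               unaffected_mean = u[["mean"]], unaffected_sd = u[["sd"]],
               p_welch = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(m, s) ifelse(is.na(m), "-",
                               sprintf("%.1f ± %s", m,
                                       ifelse(is.na(s), "NA", sprintf("%.1f", s))))
  show <- data.frame(variable = x$variable,
                     all = fmt(x$all_mean, x$all_sd),
                     affected = fmt(x$affected_mean, x$affected_sd),
                     unaffected = fmt(x$unaffected_mean, x$unaffected_sd),
                     p = ifelse(is.na(x$p_welch), "-", sprintf("%.3f", x$p_welch)))
  print(show, row.names = FALSE)
  invisible(x)
}
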