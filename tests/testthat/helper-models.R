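# shared fixtures: trait models and independent oracles used across tests

# additive QTL explaining half the SBP variance (total SD 18 mmHg), the
# remainder split equally between polygenic and environmental components
model_qtl50 <- function() {
  trait_model(additive_effect_sbp = 18, polygenic_sd_sbp = 9, env_sd_sbp = 9)
}

# trait model with no QTL effect at all
model_null_qtl <- function() {
  trait_model(additive_effect_sbp = 0, additive_effect_dbp = 0)
}

equifreq_markers <- function(n_markers, n_alleles = 8, theta = 0.5) {
  lapply(seq_len(n_markers), function(i)
    marker_def(paste0("M", i), n_alleles = n_alleles, theta = theta))
}

# independent least-squares oracle: standardized betas via the normal
# equations, never via lm()
ne_std_betas <- function(y, X) {
  Z <- scale(as.matrix(X))
  zy <- as.numeric(scale(y))
  as.numeric(solve(crossprod(Z), crossprod(Z, zy)))
}

# closed-form allele-sharing LRT for fully informative pairs: the MLE is the
# empirical IBD distribution and the statistic is 2 * sum n_k log(z_k / prior_k)
lrt_closed_form <- function(counts, prior = c(0.25, 0.5, 0.25)) {
  n <- sum(counts)
  z <- counts / n
  keep <- counts > 0
  2 * sum(counts[keep] * log(z[keep] / prior[keep]))
}
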