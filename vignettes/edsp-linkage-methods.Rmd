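---
title: "Extreme discordant sib-pair linkage analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme discordant sib-pair linkage analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsplink)
```

## The problem

Blood pressure is a polygenic quantitative trait: individual loci contribute
small fractions of its variance, and affected-sib-pair genome scans have
struggled to localise them consistently. The extreme discordant sib pair
(EDSP) design attacks the power problem from the sampling side. Two full
sibs drawn from *opposite tails* of the trait distribution are unlikely to
have inherited the same alleles at any locus that actually influences the
trait; at such a locus their identity-by-descent (IBD) sharing is pushed
below the unconditional full-sib expectation of one allele (prior
(1/4, 1/2, 1/4) over 0/1/2 alleles shared). A few tens of such pairs can
therefore carry the linkage information of hundreds of unselected or
affected pairs.

`edsplink` implements the full desk-side workflow around this idea:
simulation with recorded truth, ascertainment, IBD estimation from sib
genotypes alone, the linkage tests, and a Monte-Carlo power calculator.

## The trait model

`trait_model()` describes the generating architecture used everywhere:

* a biallelic QTL with high-allele frequency $p$ and genotype values $-a$,
  $d$, $+a$ (mmHg), centred so the stated population means are exact. Its
  variance under Hardy–Weinberg is $2pq[a+d(q-p)]^2 + (2pqd)^2$;
* a polygenic component with SD $\sigma_A$, realised as a family-shared
  normal deviate of variance $\sigma_A^2/2$ plus an individual deviate of
  variance $\sigma_A^2/2$ — the standard additive full-sib covariance of
  $\sigma_A^2/2$;
* an individual environmental deviate, bivariate normal across SBP and DBP
  with correlation `env_corr_sbp_dbp` (default 0.5; the within-person
  correlation of systolic and diastolic environmental influences is not
  something a sib-pair study pins down, so it is a configurable default).
  Polygenic deviates are drawn independently per trait.

Pulse pressure is defined as SBP − DBP and inherits its distribution from
the two.

The defaults describe an untreated adult sib cohort with population
SBP/DBP of 125 ± 18 / 77 ± 13 mmHg and an additive QTL explaining ~15% of
SBP variance ($p = 0.5$, $a = 10$, $\sigma_A = 12$,
$\sigma_E = \sqrt{130}$; the three variances sum exactly to $18^2$).
No real study states this architecture — these are illustrative,
moment-matched choices, not estimates. Where a stronger signal is wanted
(power studies, worked examples) we use an additive QTL explaining half
the SBP variance: $a = 18$, $\sigma_A = \sigma_E = 9$, which gives a sib
phenotypic correlation of 0.375; the equal split of the residual half into
shared-polygenic and environmental parts is again a choice, made once.

```{r}
m <- trait_model()
trait_variance(m)$sbp
```

## Simulation and what it does (not) emulate

`simulate_families()` builds two-parent/two-offspring families. Parental
genotypes at the QTL and at each microsatellite are drawn under
Hardy–Weinberg; each offspring gamete tracks grandparental origin jointly
at the QTL and each marker, recombining with the marker's $\theta$
(per gamete, per marker). Markers are conditionally independent given the
QTL — a *single-point* simulation matching the per-marker analysis; no
marker–marker map exists, so multipoint methods cannot be studied with it.
True IBD counts at every locus are recorded from the origin labels, which
is what makes every downstream estimator testable. Sibship size is fixed
at two because the pair is the analysis unit.

Ages are drawn N(39.8, 7.8) years and sexes at random, mirroring an adult
cohort. The simulator does **not** emulate: genotyping error, microsatellite
mutation, treatment effects, parental phenotype ascertainment, X linkage,
or age/sex effects on BP (covariate-adjusted regression is exercised on
null covariates plus synthetic fixtures instead). Passing tests therefore
demonstrate correctness of the estimators under the model, not robustness
to those real-data complications.

`mask_parents()` zeroes parental genotypes, reproducing the common design
in which only the sibs are genotyped; all IBD estimation below assumes
exactly this.

The packaged chromosome 11/17 microsatellite panel (`marker_panel()`)
carries real marker names and fragment-size ranges as metadata; since
allele frequencies for the panel are not published, markers default to 8
equifrequent alleles (heterozygosity 0.875, "highly polymorphic").
Recombination fractions to the trait locus are simulation parameters, not
panel properties.

## Ascertainment rules

`selection_criteria()` encodes the EDSP rules with strict inequalities
throughout: a pair is extreme discordant when one sib is hypertensive
(SBP > 139 or DBP > 85 mmHg) and the other hypotensive (SBP < 112 or
DBP < 66 mmHg), **or** when the pair differs by more than 25/20 mmHg; the
15/14 mmHg rule is the initial discordance screen. The "25/20" notation is
read as *both* margins exceeded (AND); because the shorthand is genuinely
ambiguous an OR reading is available via `diff_rule = "or"`. When both the
threshold and difference rules fire, `which_rule` reports the threshold
rule — the stricter clinical definition takes precedence. An alternative
centile rule selects pairs from opposite tails (default deciles) of a
reference distribution with nearest-rank cut-offs
(`centile_thresholds()`); the threshold/difference path is the default
because genotyped cohorts of this kind are defined by the strictest mmHg
rules. The affected sib is the higher-SBP sib, ties broken by DBP and then
lexicographically, purely for determinism.

## IBD estimation without parents

Marker allele frequencies are estimated by gene counting over all genotyped
individuals (`estimate_allele_frequencies()`), deliberately ignoring the
sib correlation — the standard practice for this design, with second-order
bias — and external frequency tables can be supplied instead. Genotypes
containing alleles absent from the table raise an error rather than being
smoothed: silent pseudo-counts would mask data corruption.

For a sib pair with unordered genotypes $g_1, g_2$,
`pair_likelihoods_given_ibd()` evaluates
$L_k = P(g_1, g_2 \mid \text{IBD} = k)$ in closed form under HWE: $L_0$ is
the product of the genotype probabilities; $L_2$ is $P(g_1)$ iff
$g_1 = g_2$; $L_1$ takes the shared allele uniformly from $g_1$ and draws
the other from the population. These forms are validated *exhaustively*
against `ibd_oracle()`, which enumerates all ordered parental genotypes
with their HWE probabilities crossed with the 16 equally likely
transmission patterns — for every genotype pair at 2–4-allele markers the
two routes agree to 10⁻¹².

The posterior (`ibd_posterior()`) combines $L_k$ with the (1/4, 1/2, 1/4)
prior (no inbreeding); a monomorphic marker returns the prior, opposite
homozygotes return certain IBD 0. One quantifiable consequence of
plugging in frequencies estimated from the analysis sample itself: with
only 24 pairs the mean posterior $\hat\pi$ under no linkage sits slightly
below 0.5 (about 0.490 with an 8-allele marker) because alleles present
in the sample have inflated frequency estimates, making the observed
sharing look less surprising. The bias disappears when true or external
frequencies are supplied and shrinks with sample size; it does not affect
the calibration of the Haseman–Elston test, which conditions on the
estimated sharing. Derived statistics are
$\hat\pi = f_1/2 + f_2$ and the expected shared count $f_1 + 2 f_2$.
Missing genotypes flag the marker uninformative for that pair
(pairwise-complete analysis); no imputation is attempted.

## Linkage tests

**Haseman–Elston regression** (`haseman_elston()`): OLS of the squared sib
difference $y = (x_1 - x_2)^2$ on the expected shared count. Under linkage
the slope is negative, and the classical test is the one-sided t test on
$n-2$ df. The predictor is the expected *number* of alleles shared;
$\hat\pi$ differs by a factor two and gives identical correlations and
p-values.

**Pearson correlation** (`pearson_linkage_test()`): $r$ with the exact
transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$. The two-sided convention matches
the printed values of the motivating study: with $n = 24$, $r = -0.51$
gives $p = 0.011$ and $r = -0.44$ gives $p = 0.031$, which we verified
numerically before freezing the default; one-sided slope p-values are
reported separately because classical Haseman–Elston is one-sided.

**Adjusted regression** (`adjusted_regression()`): the response and all
predictors are z-scored, so coefficients are standardized betas reported
per term with p-values and the adjusted $R^2$. The analysis unit is the
pair, so the dependent variable is the squared pair difference and the
covariates are pair summaries — mean age and the number of males (a
0/1/2 count; an indicator coding is equally defensible and the choice is
deliberately explicit here). Collinear designs (constant or dependent
columns, condition number above 10⁸) are refused with the offending terms
named.

**Allele-sharing LRT** (`sharing_lrt()`): each pair contributes prior-free
weights $w_k \propto L_k$; $L(z) = \prod_i \sum_k z_k w_{ik}$ is maximized
over the simplex by EM (tolerance 10⁻¹⁰), with the `"deficit"` direction
($z_0 \ge 1/4$, $z_2 \le 1/4$ — the relevant alternative for discordant
pairs) handled by constrained optimization when the unconstrained MLE
falls outside. Because at $n \approx 24$ the MLE often sits on the simplex
boundary, the asymptotic mixture-χ² null is unreliable and the p-value is
obtained by seeded permutation instead: each pair's weight vector is
re-drawn under the null prior as the indicator of an IBD state sampled
from (1/4, 1/2, 1/4). This resampling is exact for fully informative
markers and conservative for partially informative ones (indicator weights
maximize the spread of the resampled statistic); with 8–12-allele
microsatellites the markers are close to fully informative and the
approximation is mild.

Raw p-values are the primary output, mirroring small-study practice; a
Bonferroni column is emitted for reference but never used for gating.
Tables display three decimals; machine outputs keep full precision (TSV
round-trips preserve 12 significant digits).

## Power module

`conditional_sharing()` estimates, by straight Monte Carlo, the mean and
variance of the true IBD proportion among pairs retained by a design
(EDSP by opposite deciles or by the mmHg rules, affected pairs, or
unselected). Monte Carlo was chosen over numerical integration of the
conditional bivariate normal because it is transparent, oracle-checkable
and fast at desk scale. `required_pairs()` converts the moments into a
one-sided normal-approximation sample size against the null mean of 0.5
with null variance 0.125 (fully informative markers; an informativeness
deflation can be supplied). `fold_reduction()` is the ratio of required
sizes, computed from the unrounded sizes so that rounding a ~13-pair EDSP
requirement up to the next integer does not quantize the fold.

Two caveats are deliberate. For an *unselected* design the conditional
mean sharing is exactly 0.5, so its "required n" is infinite in truth and
any finite Monte-Carlo estimate is noise-driven; the EDSP-vs-unselected
fold is therefore only meaningful directionally (it is huge), while the
EDSP-vs-affected-pair fold is a stable, interpretable number (about 5–6×
under the default model). Second, published fold-reduction figures for
this design depend on threshold and architecture parameters that are
rarely stated; we assert direction, not magnitude.

## Numerical and design choices

* Strict inequalities in all ascertainment rules, following the printed
  conventions; ties in the affected-sib label broken deterministically.
* Nearest-rank (type-1) centiles, so reference thresholds are always
  observed values.
* IBD prior fixed at (1/4, 1/2, 1/4); frequencies by gene counting;
  unobserved alleles are errors, never smoothed.
* EM for the sharing MLE with analytic fixed point; `constrOptim` only on
  the constrained boundary case.
* Seeds are required arguments of every stochastic function and are
  recorded in the returned objects; equal seeds give bit-identical output,
  including end-to-end pipeline runs.
* Degenerate inputs (constant response or predictor, monomorphic markers,
  missing phenotypes, all-zero likelihoods) raise informative errors or
  uninformative flags rather than NaNs.

## Problem sizes used in the test suite

The shipped tests run at deliberate desk scale: moment checks on 1,000 to
5,000 individuals; IBD-oracle equivalence exhaustively at 2–4 alleles;
null calibration of the Haseman–Elston test with 2,000 replicates of 24
pairs (rejection rate within [0.035, 0.065] at the 5% level); EDSP signal
detection with 500 replicates of 24 decile-selected pairs from 8,000
simulated families; power-module runs at 20,000–50,000 simulated pairs.

## A known limitation worth stating plainly

Within a *selected* EDSP sample, the Haseman–Elston regression of $y$ on
sharing is attenuated: conditioning on both sibs lying in opposite tails
truncates $y$ from below, so even at a fully informative, fully linked
marker the within-sample slope test has modest power (we measure one-sided
rejection around 12–18% at 24 pairs with a QTL explaining half the
variance — and only ~19% even using the recorded true IBD as predictor).
The EDSP design's power lives in the *mean sharing deficit* itself, which
is dramatic under the same conditions (mean $\hat\pi \approx 0.24$; a
one-sided mean-sharing z test rejects in ~100% of replicates, and
`sharing_lrt()` with `direction = "deficit"` targets the same signal).
Users analysing selected pairs should read the Haseman–Elston scan as an
effect-direction summary and lean on the sharing tests for significance.
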