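---
title: "Methods: observational and Mendelian randomization analysis of a circulating biomarker"
author: "adipomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: observational and Mendelian randomization analysis of a circulating biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipomr)
```

# The scientific problem

Plasma adiponectin is repeatedly found *positively* associated with heart
failure, atrial fibrillation and related outcomes in cohort studies, even
though its biology (insulin-sensitizing, anti-inflammatory) suggests
protection. The central question is whether that observational association
is causal, confounded, or driven by reverse causation — preclinical disease
raising the biomarker before diagnosis. `adipomr` implements both sides of
that comparison: conventional survival analysis of measured biomarker
levels, and Mendelian randomization (MR), which uses genetic variants fixed
at conception as instrumental variables and is therefore immune to classical
reverse causation.

The package works end-to-end on synthetic cohorts because the individual
-level data such studies use are access-restricted. The synthetic generator
is a first-class, tested module: it defines the statistical structure the
analyses assume, so every downstream claim can be verified against a known
truth.

# Observational model

`fit_cox()` fits a Cox proportional-hazards model with **age as the
timescale** and **delayed entry**: an individual enters the risk set at
their study-entry age and leaves at their exit age, so age confounding is
absorbed into the baseline hazard and no one contributes person-time before
enrolment. Ties are handled with the Efron correction. The exposure can
enter as:

* the natural log of the biomarker (one log-HR per log-unit — the scale on
  which observational and MR estimates are compared),
* untransformed concentration (per 1 µg/mL),
* a restricted cubic spline, or
* quartiles, with the bottom quartile as referent and within-quartile
  geometric means (t-based CIs on the log scale) for display.

The spline is the truncated-power restricted cubic basis — linear beyond
the boundary knots — with 5 knots at the 5/27.5/50/72.5/95th exposure
percentiles (the Harrell convention) by default, configurable. The number
and placement of knots, and whether the spline is fitted on the log or
natural scale, are genuinely open choices in this kind of analysis; both
scales are provided (`spline_log`), log by default because the biomarker is
approximately log-normal. `spline_curve()` reports HR(x) = exp{f(x) −
f(ref)} with delta-method pointwise intervals; the reference exposure
(default: the sample median, 16 µg/mL in the default generator) gets HR
exactly 1 with a zero-width interval. Trimming of the top percentiles is a
plotting option only and is never applied to fitting.

Effect modification is tested by a likelihood-ratio test between Cox models
with and without an exposure × modifier product term
(`interaction_lrt()`); continuous modifiers are first dichotomized at
conventional clinical cuts (age 60 years, BMI 30 kg/m², waist 88/102 cm by
sex). Reverse causation is probed by `exclude_early_followup()`: the
default removes every individual with total follow-up shorter than the
window (0–4 years), matching the way such sensitivity analyses are usually
phrased; an alternative mode administratively censors early events instead.
Complete-case analysis is used throughout: rows without a measured exposure
are dropped rather than imputed, which is adequate here because the
generator produces data missing completely at random and real analyses of
this design report negligible sensitivity to imputation.

# Genetic instruments

`build_score()` collapses the per-variant dosages into an allele score
after orienting every variant to its exposure-increasing allele (a beta of
exactly zero keeps the input orientation). Three weighting schemes mirror
standard practice: *unweighted* (allele counting), *internal* (weights from
per-variant marginal regressions of log exposure on dosage, age- and
sex-adjusted, in the measured subsample — marginal rather than joint fits
because the variants are simulated independent; a joint option exists), and
*external* (weights supplied from an independent exposure GWAS).

Instrument validity checks are the usual battery: Hardy–Weinberg
equilibrium per variant (1-df Pearson χ²; monomorphic variants return p = 1
with a warning), a confounder screen regressing each covariate on the score
and, for contrast, on the measured exposure (Bonferroni at 0.05/m), and
instrument strength. For strength, R² is taken from the one-predictor
regression of log exposure on the score, and **two** F conventions are
reported: the analytic formula F = ((N−K−1)/K)·R²/(1−R²) with K the number
of variants, and the regression F of the score fit ((N−2)·R²/(1−R²)). The
two answer different questions and can differ several-fold, so
`instrument_diagnostics()` refuses to collapse them into one number.

# Causal-effect estimators

All summary-data estimators consume the same per-variant table
(`id, effect_allele, other_allele, eaf, beta, se, n`), whether it comes
from a real GWAS export, `simulate_summary_stats()`, or
`per_variant_associations()` run on an individual-level cohort — so the
one-sample and two-sample worlds share one code path.

* **Wald ratio** (`mr_wald()`): θ = β_Y/β_X, the ratio of the
  score–outcome log-odds coefficient to the score–exposure coefficient
  (both age- and sex-adjusted), with the first-order delta-method standard
  error √(σ_Y²/β_X² + β_Y²σ_X²/β_X⁴). Estimates with instrument F < 10 are
  flagged weak but still returned.
* **IVW** (`mr_ivw()`): the γ²/σ_Y²-weighted mean of per-variant ratios,
  identical to the zero-intercept weighted regression of Γ on γ (the two
  formulations are asserted to agree to 1e-12 in the tests). The default
  variance is multiplicative random effects: the fixed-effect SE is
  inflated by √(Q/(L−1)) when Cochran's Q exceeds its df, and never
  deflated; fixed-effect is available by flag. Which variant a published
  analysis used is often unstated, so both are provided.
* **MR-Egger** (`mr_egger()`): weighted regression with a free intercept
  after orienting all γ ≥ 0; the intercept estimates directional
  pleiotropy, the slope the causal effect under the InSIDE assumption.
  Standard errors use multiplicative overdispersion bounded below at 1.
  I²_GX = (Q_X − (L−1))/Q_X quantifies regression-dilution susceptibility;
  values near 1 mean the slope is barely attenuated.
* **Weighted median** (`mr_weighted_median()`): ratios sorted, cumulative
  midpoint weights s_j = Σ_{k≤j} w_k − w_j/2, linear interpolation where s
  crosses ½; consistent when valid instruments carry ≥ 50% of the weight.
* **Weighted mode** (`mr_weighted_mode()`): argmax of a weighted normal
  kernel density over the ratios; bandwidth is a factor (default 1) times
  the modified Silverman rule 0.9·min(sd, mad)·L^(−1/5). When the majority
  of ratios are exactly tied the mad degenerates to floating-point dust,
  so the rule falls back to the sd below a relative tolerance of 1e-8 —
  without this the estimator loses its exact rescaling equivariance.
* Ratio variances use the first-order delta method by default; the
  second-order term is available by flag. Median/mode standard errors come
  from a parametric bootstrap (default 1000 draws, explicit seed; the
  global RNG state is restored afterwards).

`mr_power()` implements the standard normal approximation for a binary
outcome: power = Φ(|effect|·√(n·R²·cf·(1−cf)) − z_{1−α/2}).

# Harmonization and LD pruning

`harmonize()` aligns two summary tables on shared variant ids and resolves
each variant by a four-case rule: exact allele match (kept), swapped
alleles (outcome beta and EAF flipped), strand-complement match
(complemented, kept), complement-swap (complemented, flipped); anything
else is removed as incompatible. Palindromic variants (A/T, C/G) cannot be
resolved from alleles alone; the default policy removes them — the
conservative choice a careful two-sample analysis makes — while
`"infer"` aligns by allele frequency when both EAFs are at least 0.08 from
0.5, and `"keep"` trusts the strand. Every input variant appears exactly
once in the returned action log, and the operation is idempotent; the
allele flip is an involution (both tested exactly).

`ld_prune()` is greedy clumping given an LD correlation matrix: variants in
descending |beta|/se order, each kept only if r² with every kept variant is
below the threshold (default 0.24). Matching is by rsid only; positional
matching and reference-panel LD computation are out of scope.

# Non-linear MR

`doubly_ranked_strata()` implements doubly-ranked stratification: sort by
allele score (stable ties), cut into consecutive pre-strata of size S,
rank by exposure within each pre-stratum, and send exposure-rank q to
stratum q. Only ranks are used, so the assignment is *exactly* invariant to
monotone exposure transformations — the property that distinguishes this
construction from residual-based stratification, and an exact test in the
suite. The n mod S leftover individuals form one final partial pre-stratum
assigned by the same within-ranking, keeping stratum sizes within one.
S = 10 by default. At least S² individuals are required.

Within each stratum, `lace_per_stratum()` computes the localized average
causal effect as the stratum's Wald ratio (age- and sex-adjusted); strata
with no events or a degenerate score are flagged and excluded.
`fit_causal_curve()` reconstructs the causal curve by treating each LACE as
the derivative of the log-RR curve at the stratum's mean exposure:

* **Fractional polynomials**: weighted meta-regression of θ_q on powers of
  the natural-scale stratum mean from {−2, −1, −0.5, 0 (log), 0.5, 1, 2,
  3}, degree 1 or 2 (distinct powers only), best powers by maximized
  weighted Gaussian likelihood; the constant-effect model is itself a
  candidate, so flat stratum estimates yield an exactly linear curve. The
  curve is the analytic integral of the fitted effect function from the
  reference (default: the middle stratum's mean), with delta-method bands.
* **Piecewise linear**: each θ_q is the constant slope over its stratum's
  exposure range; the curve is the running integral anchored at 0 at the
  reference, hence continuous by construction.

Non-linearity is assessed by (a) Cochran's Q across the stratum estimates
and (b) a 1-df LRT of the best degree-1 fractional polynomial against the
constant-effect model. The LRT df is approximate — power selection is not a
smooth parameter — which makes the test mildly conservative; the null
simulations in the test suite confirm rejection stays at or below nominal.
Curves should be interpreted over the span of stratum means; outside it
they are pure extrapolation.

# The synthetic-data generator

`simulate_cohort()` emulates the structure these analyses assume, not any
particular dataset:

* genotypes: L independent biallelic variants, dosage ~ Binomial(2, f_j);
  no LD, no population structure, no genotyping error (matching the
  design's assumption of uncorrelated instruments).
* exposure: log-normal, mean log(16) µg/mL and sd 0.5 on the log scale
  (typical of circulating adiponectin); equal standardized per-variant
  genetic effects rescaled so the allele score explains `score_r2`
  (default 3%, the one-sample instrument's strength) of log-exposure
  variance in expectation; a single standard-normal shared confounder
  stands in for the usual covariate battery — enough to create confounded
  observational estimates with a minimal parameter count.
* outcomes: exponential event times on the age axis with log-hazard linear
  in log exposure (`true_causal_effect`, default 0), the confounder and
  sex; entry ages uniform on 40–80 so delayed entry is exercised by
  construction; administrative censoring after 15 years. The default
  baseline hazard (0.005/yr, ~7% cumulative incidence) is in the range of
  heart-failure-like endpoints in an ageing cohort.
* reverse causation: individuals whose event falls within `reverse_window`
  (default 2) years of entry have their *measured* log exposure shifted by
  `reverse_causation_effect` — preclinical disease raising the biomarker —
  which reproduces the qualitative discordance pattern (observational
  HR > 1, causal RR ≈ 1) without any true causal effect.

`simulate_summary_stats()` generates paired exposure/outcome GWAS tables:
γ_j ~ |N(0.1, 0.02²)| per allele on the log-exposure scale (per-variant R²
~1%, matching a 12-variant instrument explaining ~14%), standard errors
implied by the stated GWAS sizes and case fraction, outcome effects
Γ_j = θ·γ_j + α_j + noise with α_j the pleiotropic term, and a configurable
number of palindromic allele pairs to exercise harmonization.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage disequilibrium and proxy variants,
population stratification and relatedness, assay measurement error and
batch effects, time-varying hazards and competing risks, registry-based
outcome misclassification, and selection into the measured subsample.
Passing tests certify the estimators and their calibration under the stated
model, not robustness to violations the model does not contain.

# Problem sizes and numerics

The test suite and `scripts/acceptance.R` use: 1000 replicates for IVW
null calibration (12 variants); 200 replicates at n = 100,000 for Wald
recovery (per-replicate sampling sd ≈ 0.14–0.28 depending on the event
rate, so the Monte-Carlo standard error of the mean is ~0.01 against a
±0.02 tolerance); 200 replicates for the pleiotropy and weighted-median
scenarios at outcome-GWAS size 10⁶ (the scale of the disease consortia
this design uses — at 10⁵ the ratio noise dominates the asymptotic
robustness guarantees being tested); and 60 replicates for the non-linear
null. In the weighted-median scenario the five invalid variants are given
smaller γ so their weight share (~17%) sits comfortably inside the < 50%
validity condition. All randomness flows from explicit integer seeds kept
below 2³¹.

Degenerate inputs fail loudly rather than silently: zero events, zero
overlap after harmonization, fewer than 3 variants for regression-based
estimators, fewer than S² individuals for stratification, all-equal
exposures for quartiles, constant allele scores, and references outside
the data range are all explicit errors. Constant adjustment covariates are
dropped from Cox fits (they carry no information and break the optimizer).
Weak instruments (F < 10) are flagged, never silently discarded.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 50000, true_causal_effect = 0,
                  reverse_causation_effect = 0.5, seed = 42)
coh <- simulate_cohort(cfg)

# observational: positive association driven purely by reverse causation
fit_cox(coh, encoding = "log", covariates = "sex")

# genetic: allele score, diagnostics, causal estimate near the null
sc <- build_score(coh, scheme = "internal")
instrument_diagnostics(coh, sc)
mr_wald(coh, sc)

# two-sample path on the same cohort
mr_all(per_variant_associations(coh), bootstrap = 500)

# non-linear MR
st <- lace_per_stratum(coh, doubly_ranked_strata(coh, sc, 10), sc)
fit_causal_curve(st)
```

# Known limitations

The logistic instrument–outcome regressions interpret the binary outcome
cross-sectionally; for common outcomes the log-odds and log-hazard scales
diverge (a few percent at ~10% incidence), which is inherent to Wald-type
estimation with binary outcomes rather than to this implementation.
MR-Egger's slope is attenuated by the factor I²_GX; with precisely
estimated exposure associations (I²_GX ≳ 0.9) this is a few percent. The
weighted median and mode are consistent only as per-ratio noise vanishes;
at small GWAS sizes their finite-sample bias can be material. The
fractional-polynomial non-linearity test's 1-df calibration is approximate.
MR-PRESSO-style outlier removal, multivariable MR, Steiger filtering,
competing risks and time-varying covariates are deliberately out of scope.
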