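---
title: "Methods: meta-analysis of pre/post continuous outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of pre/post continuous outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepostMA)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## Data model

One row per trial arm, columns
`trial_id, arm, n, mean_B, sd_B, se_B, mean_F, sd_F, se_F, mean_CS, sd_CS,
se_CS, r` (`B` baseline, `F` follow-up, `CS` change score, `r` the
within-group baseline–follow-up correlation). Two arms per trial
(`control`/`treatment`; `0`/`1` accepted on input), SDs with the sample
(n − 1) denominator throughout. The column order is this package's own
canonical choice — documented here and in `write_template()` — because a
fixed order must be *some* order; files from other tools may need reordering.

**Sign convention.** Internally `mean_CS = mean_F − mean_B`, so follow-up
and change-score mean differences share sign (improvement points the same
way in both analyses). All SD/correlation algebra and the pooled magnitude
are sign-symmetric, so this is pure convention; `read_dataset(...,
negate_change = TRUE)` (CLI `--negate-change`) converts files recorded as
baseline − follow-up.

## The fill-in engine

Steps run in a fixed order (no user reordering):

1. `sd = se·√n` for all three quantities;
2. missing `sd_F ← sd_B` (imputation: the follow-up spread is assumed
   unchanged);
3. `r = (sd_B² + sd_F² − sd_CS²)/(2·sd_B·sd_F)` where all three SDs exist;
4. mean identities (any one of the triplet from the other two);
5. correlations still missing are imputed — by default the (n − 1)-weighted
   mean of all observed/calculated correlations, or a user-fixed value.
   The weighted mean is this package's choice for the default rule, made
   once: correlations estimated from larger arms carry more information,
   and a dataset-internal average is more defensible than an arbitrary
   constant. With no observed correlation at all the engine refuses and
   asks for a fixed value rather than inventing one;
6. `sd_CS = √(sd_B² + sd_F² − 2·r·sd_B·sd_F)` for remaining change SDs;
7. a final mean pass and a consistency check of the complete-dataset
   invariants (relative tolerance 1e-6).

Every cell carries provenance (`observed`, `calculated:<rule>`,
`imputed:<rule>`), so reports can separate data from assumptions.
Implied correlations within 1e-8 outside [−1, 1] are clamped to ±1 with a
warning (published summaries are rounded); anything further out is an error
— the three SDs cannot coexist. No multiple imputation and no sensitivity
analysis over imputed correlations are provided.

## Aggregate-data effect measures

For a trial with arms (C, T), the three mean-difference estimators are
follow-up scores, change scores, and the ANCOVA recovered estimate with
pooled within-group sums of squares/products `S_xx, S_yy, S_xy`:

- `β̂ = S_xy/S_xx` (single pooled slope),
- `θ̂ = (m_F,T − m_F,C) − β̂(m_B,T − m_B,C)`,
- `σ̂² = (S_yy − S_xy²/S_xx)/(N − 3)`,
- `Var(θ̂) = σ̂²(1/n_T + 1/n_C + (m_B,T − m_B,C)²/S_xx)`.

Two deliberate choices: the *pooled* (not per-arm) slope, so the recovered
estimate is exactly the coefficient of a single-slope per-trial ANCOVA and
therefore exactly what the two-stage pseudo-IPD route pools; and the full
model-based OLS variance including the baseline-imbalance term
`(m_B,T − m_B,C)²/S_xx`, so the equivalence with OLS on pseudo-IPD is exact
(to 1e-8 in the tests) rather than approximate. Software that drops the
imbalance term will show slightly narrower CIs.

## Pooling

Inverse-variance common-effect and random-effects models. Under RE, τ² is
estimated by REML only — restricted maximum likelihood has good bias
properties among the usual estimators, and offering a single estimator
keeps results unambiguous. The restricted log-likelihood is maximised by
bounded one-dimensional search plus Newton polishing, with an explicit
comparison against the τ² = 0 boundary; the suite checks it against a
1e-4-resolution grid search. Heterogeneity is summarised by Cochran's Q (at
CE weights) and I²/H² based on the typical within-study variance
`s² = (k−1)Σw/((Σw)² − Σw²)`.

**Hartung–Knapp.** With `w*_i = 1/(v_i + τ̂²)`,
`se²_HK = Σw*_i(θ_i − θ̂)²/((k−1)Σw*_i)` and the CI uses t(k−1). The HK
variance is used **untruncated**, matching the originally proposed
estimator. A consequence worth knowing: in a minority of small-k datasets
(about 8% in our k = 9 simulations) the HK interval is *narrower* than the
normal-theory interval; some software truncates at the conventional RE
variance to prevent this. We do not, and the tests assert the ordering
holds in the large majority — not all — of replicates, while HK coverage
stays within 95% ± 2 points.

## Pseudo-IPD: exact moment matching

Per arm, draw an n×2 standard-normal matrix, column-centre, orthonormalise
(QR), scale so the sample covariance is the identity (n − 1 denominator),
multiply by the Cholesky factor of the target covariance and add the target
means. The five sample moments then match *by construction* (the tests
demand 1e-10 across 1000 random configurations), not asymptotically. The
marginal shape of the points is irrelevant: every model fitted downstream
is a function of the matched sufficient statistics only, which the suite
verifies by requiring identical one- and two-stage results across pseudo
seeds. Because the construction fixes five moments with n points, n ≥ 3 per
arm is required, and |r| = 1 targets are rejected as rank-deficient.
Per-arm seeds are a stable hash of (master seed, trial_id, arm), so
subsetting or reordering trials never changes another trial's points.

## One-stage model

For participant j in arm k of trial i, with `b̄_i` the trial baseline mean:

`y_Fijk = α_i + β_i(b_ijk − b̄_i) + (θ + u_i)·1[T] + γ_W·1[T](b_ijk − b̄_i)
 + γ_B·1[T](b̄_i − b̄) + ε_ijk`,

`u_i ~ N(0, τ²)` (RE) or τ² ≡ 0 (CE); residual variances per
arm-and-study, study, arm, or single. Intercepts are study-stratified
(never random — the stratified model is what compares naturally with the
two-stage estimate), and the baseline slopes `β_i` are study-stratified by
default with a `common_slope` option; stratified nuisance parameters avoid
assumptions on between-trial baseline distributions, and the app-level
convention being unknowable from the published description, the package
fixes and documents its own.

Centring at `b̄_i` makes `γ_W` the within-trial interaction — the
participant-level, clinically interpretable component — while `γ_B`
absorbs the ecological between-trial component; `γ_B` is reported but
flagged as not causally interpretable. The between-trial term is
additionally centred at the grand mean `b̄` of the trial baseline means so
that θ remains the treatment effect at an average baseline rather than an
extrapolation to baseline zero (this reparameterisation changes only θ's
meaning, not γ̂_B).

**Fitting.** REML: for fixed variance parameters the fixed effects are
profiled out by generalised least squares. The marginal covariance is block
diagonal by trial — diagonal residuals plus the rank-one τ²tt′ block from
the random treatment effect — inverted by Sherman–Morrison, and per-trial
cross-products are scattered into the global normal equations, so one
likelihood evaluation is O(N). The restricted log-likelihood (constants
included; the tests compare it to a dense-matrix evaluation at 1e-8) is
maximised over log residual SDs and log τ by `nlminb`, with three seeded
random restarts, followed by a finite-difference Newton polish declared
converged at gradient norm < 1e-6 (or negligible Newton decrement, which
is the attainable criterion when |logLik| is large) and step < 1e-8. The
polish pins the optimum to the resolution needed for results to be
reproducible across pseudo-IPD seeds and is applied when there are at most
12 variance parameters (beyond that the finite-difference Hessian is not
worth its cost, and `nlminb`'s own tolerances stand). An interior τ̂² whose
restricted-likelihood gain over the τ = 0 boundary fit is below 1e-4 is
snapped to the boundary: such a τ̂² is below the optimiser's resolution and
the snap keeps fits deterministic. Wald (normal) intervals are the
default; a t-interval option with N − p df exists because other software
reports t-based CIs and the df convention differs between implementations —
small CI differences against other tools are expected.

Residual-df guards: `arm_study` needs ≥ 4 observations per arm (≥ 2
residual df); fits report `converged`, iteration counts and a boundary
flag for collapsed residual variances.

## Synthetic data

`simulate_ipd()` draws trial effects `θ_i ~ N(θ, τ²)`, per-trial baseline
means uniform on `mu_B_range`, baselines `N(μ_Bi + shift_i·1[T], σ_B²)`,
and follow-ups from the one-stage mean structure plus residual noise under
any of the four variance structures. Baseline imbalance is injected as a
per-trial random shift `N(0, baseline_imbalance_sd²)` of the treatment
arm's baseline mean — a mechanism chosen once, for being the simplest that
produces chance imbalance of controllable size in either direction.

Defaults describe a body-weight-like outcome: baselines 60–90 kg with SD
10 kg, slope 0.9 with residual SD 4 kg (implying within-group correlations
near 0.9 — weight tracks strongly over months), θ = −0.5 kg, τ² = 0.25.
These were fixed before any acceptance measurement and are not tuned.

What the generator does **not** emulate: non-normal outcomes, dropout,
measurement error, rounding of published summaries, multi-arm or
cluster-randomised designs, correlations between trial size and effect
(small-study effects). A green simulation test therefore establishes
correctness of the estimators under the assumed model, not robustness to
real-data pathologies — with one exception: the exact-moment pseudo-IPD
contract and the algebraic fill-in rules are distribution-free, so their
tests transfer to any data meeting the schema.

## Known limitations

* Mean differences only; no standardised mean difference or ratio of
  means.
* The worked-example acceptance test requires an external dataset that
  cannot be bundled (`inst/extdata/README`); without it that single test
  fails by design rather than being silently skipped.
* XLSX files can be read (via readxl) but not written; CSV is the primary
  format.
* No prediction intervals, meta-regression, or publication-bias tests
  beyond the funnel plot.
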