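---
title: "Benchmarking ddG predictors: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ddG predictors: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgbench)
```

## The problem

A point mutation in a drug target changes the binding free energy of an
inhibitor by ΔΔG = −RT ln(P_WT / P_mut), where P is a potency (IC₅₀ or Kd).
Positive ΔΔG means weaker binding to the mutant; beyond some fold-change in
affinity the mutation is expected to defeat therapy. Physics-based methods
predict ΔΔG directly from structure, and a benchmark asks: how accurate are
those predictions, quantitatively (MUE, RMSE) and as a resistant/susceptible
classifier?

The statistical difficulty is that every quantity involved is noisy in a
different way:

* experimental ΔΔG values differ between laboratories by roughly 0.8
  kcal/mol RMSE, implying a per-measurement noise of about 0.57 kcal/mol;
* some mutant potencies exceed the dynamic range of the assay, so their ΔΔG
  is only a lower bound (censored);
* stochastic predictors (alchemical free-energy calculations run in
  triplicate with different random seeds) carry replicate statistical error
  on top of their intrinsic inaccuracy, while single-structure scoring is
  deterministic.

ddgbench implements the full analysis stack around these facts. This
vignette records the models, the defaults and why they were chosen, and the
limits of what the package's own tests demonstrate.

## Unit conversion and thresholds

For an ATP-competitive inhibitor, `ki_from_ic50()` implements
Ki = IC₅₀ · (1 + S₀/K_M). Note this is the reciprocal of the conventional
Cheng–Prusoff correction (IC₅₀ = Ki · (1 + S₀/K_M)); we implement the form
used by the benchmark compilations this package is designed around, and both
coincide in the K_M ≫ S₀ limit that is invoked when ΔpIC₅₀ differences are
equated with binding free-energy changes. Relative quantities (ΔΔG) are
unaffected whenever the correction factor is shared between wild type and
mutant, which is why the discrepancy has no effect downstream.

Temperature: potency-to-energy conversion text often quotes T = 300 K, but
the fold-change cutoffs in universal use — 1.36 kcal/mol for 10-fold, 1.77
for 20-fold — are RT ln(fold) at room temperature, 298.15 K. We default to
298.15 K so that `resistance_cutoff(10)` reproduces the published constants,
and leave `temperature` configurable. (Exact values: RT ln 10 = 1.3642,
RT ln 20 = 1.7749, RT ln 100 = 2.7285; the last is usually quoted as 2.72,
i.e. 2 × the rounded 1.36.)

Classification is tie-susceptible by definition: susceptible means
ΔΔG ≤ cutoff, resistant means ΔΔG > cutoff. A censored record is always
called experimentally resistant — the assay ceiling implies at least the
recorded affinity loss — and censored records are *included* in truth-table
analysis but *excluded* from MUE/RMSE, whose values would otherwise be
biased by the truncation. Predictions are never censored: predictors return
point values.

## Uncertainty

All confidence intervals are percentile bootstrap: whole (TKI, mutation)
rows resampled with replacement, 1000 resamples by default, interval at the
2.5th/97.5th percentiles with linear interpolation between order statistics.
We chose plain percentiles (not BCa) because they are the convention for
this kind of benchmark report; the resampling unit is the unstratified row,
with per-stratum resampling available through `strata=` for per-TKI
analyses. Resamples on which a statistic is undefined (a sensitivity when no
resistant row was drawn) are skipped and counted rather than coerced to 0,
which would bias the interval.

Experimental noise is calibrated from paired measurements of the same
mutation by independent sources: if each source has independent noise σ,
the RMSE of their differences converges to σ√2, so
`sigma_from_pairwise_rmse()` inverts this as σ = RMSE/√2. An inter-lab RMSE
of 0.81 kcal/mol gives the default σ_exp = 0.57 used throughout. (Where a
directly computed standard error of 0.58 is reported for a comparable set,
we adopt the √2 rule's 0.57 for internal consistency; the difference is
immaterial at the precision of the analysis.)

## ROC by stepped cutoff sweep

`roc_curve()` reproduces the sweep procedure exactly: experimental classes
fixed at the primary cutoff; the prediction cutoff stepped from the minimum
to the maximum predicted value in 0.001 kcal/mol increments; resistant means
prediction > cutoff; AUC by the trapezoidal rule. Two numerical choices
matter:

* **Corner anchoring.** The sweep over `[min, max]` of the predictions
  cannot reach (0,0) or (1,1) when extreme predictions are tied — for a
  constant predictor it produces a single interior point. We always append
  the two anchor points, which makes the trapezoid well defined and gives
  the all-zero naive model an AUC of exactly 0.50, the published baseline
  value. Ties between classes produce diagonal segments, so the sweep AUC
  agrees with the Mann–Whitney pairwise statistic with ties counted one
  half, up to one sweep step (a property test in the suite).
* **Strict ties.** `prediction > cutoff` (not ≥), consistent with the
  tie-susceptible classification rule.

The consensus model follows the two-stage recipe: each predictor is scaled
by the slope minimising its RMSE against experiment (least squares through
the origin, `slope = Σ(pred·exp)/Σ(pred²)`, non-censored records only, the
slope then applied to all records), and the scaled predictions are combined
by inverse-variance weights 1/RMSE² using each method's *minimised* RMSE —
the same weight for every record. "Inverse variance" could alternatively
mean per-record 1/σᵢ²; that variant is available via `per_record = TRUE`,
but the global-weight reading is the default because the per-record sigmas
of a deterministic method are all zero, which would degenerate. If both
minimised RMSEs are zero the weights are undefined; we fall back to an
unweighted mean with a warning.

## The hierarchical intrinsic-error model

Observed performance conflates three error sources. The model separates
them. For mutation i = 1, …, M (censored records excluded; at least 5
required):

* ΔΔG_true,i ~ N(μ_mut, σ_mut²) — the background distribution of true
  effects, with μ_mut ~ U(−6, 6) kcal/mol and a flat prior on σ_mut;
* latent prediction ~ N(ΔΔG_true,i, RMSE_method²) — the predictor's
  intrinsic, zero-bias normal error; RMSE_method is the estimand, with a
  flat prior;
* for a *deterministic* predictor the latent prediction is observed exactly;
  for a *stochastic* one the observed value (the replicate mean) is further
  drawn as N(latent, σ_stat,i²) with the per-record statistical standard
  error supplied as data;
* the experimental value is N(ΔΔG_true,i, σ_exp²) with σ_exp known (0.57 by
  default).

The flat priors on the two scales are truncated to (0, 10] kcal/mol to make
them proper; 10 kcal/mol is roughly twice the dynamic range of a realistic
benchmark (≈5 kcal/mol), so the truncation carries no information about
plausible values. Under the zero-bias normal error model the intrinsic MUE
follows in closed form, MUE = √(2/π)·RMSE (`mue_from_rmse()`); the suite
cross-checks this against Monte-Carlo integration.

Sampling is ordinary adaptive MCMC via JAGS: 4 chains with distinct seeded
RNGs, 500 adaptation + 500 burn-in iterations, 5000 retained draws in total
by default. Any sampler meeting the convergence targets would do; we check
split-R̂ < 1.05 (each chain halved, potential scale reduction over the
half-chains) and effective sample size > 400 for (μ_mut, σ_mut,
RMSE_method), and flag — not fail — the fit when the targets are missed, so
a user can inspect `$diagnostics` and rerun longer. A genuinely boundary
posterior (a near-perfect predictor pushing RMSE_method against 0) mixes
slowly and is expected to trip the flag.

Posterior-predictive performance metrics (`posterior_metrics()`) are
computed by simulation because there is no closed form for the
classification metrics: for each posterior draw we simulate a synthetic
benchmark at that draw's parameters (1 replicate dataset per draw by
default; more reduce Monte-Carlo noise at linear cost), score predictions
against the simulated *truth* — these are intrinsic metrics, not
apparent-versus-experiment metrics — and summarise across draws with means
and 2.5/97.5 percentiles. Draw-wise MUE is consistent with
√(2/π)·RMSE_draw by construction, which the suite verifies. Whether one
(μ_mut, σ_mut) should be shared across all inhibitors or stratified per TKI
is a modelling choice; the default pools (fit the model per TKI by
subsetting the table if stratification is wanted).

## The synthetic generator

`generate_benchmark()` draws data from exactly the generative model above,
plus the censoring mechanism (experimental values above `censor_at` flagged
and truncated, mimicking an assay ceiling), so every stage of the pipeline
is testable against known ground truth with no external inputs. Defaults
describe a realistic kinase-resistance benchmark:

* `m = 131` records cycled over 6 inhibitors;
* `sigma_mut = 1.2` kcal/mol and `mu_mut = 0.05`, chosen so that the
  resistant fraction at the 10-fold cutoff is P(N(0.05, 1.2²) > 1.364) ≈
  13.7%, the class imbalance typical of clinically observed mutation panels;
* `sigma_exp = 0.57` (inter-source RMSE 0.81);
* one stochastic predictor (intrinsic RMSE 1.0, triplicate runs with
  statistical standard error 0.3 on the reported mean — a representative
  magnitude for triplicate alchemical calculations) and one deterministic
  predictor (intrinsic RMSE 1.75), mirroring the accuracy gap between
  rigorous free-energy methods and single-structure scoring.

Replicates are drawn per run with standard deviation `sigma_stat·√k` so the
reported mean has standard deviation `sigma_stat`; the `{method}_sigma`
column stores the *standard error of the reported mean* (that is the σᵢ of
the stochastic observation law, and what the Bayesian fit consumes).
`aggregate_replicates()` itself defaults to the between-replicate sample
standard deviation — the convention used for ±1.96σ interval reporting on
individual predictions — with `se = TRUE` opting into the standard-error
convention; the two conventions differ by √k and are both exposed
deliberately.

What the generator does *not* emulate: fat-tailed or biased predictor
errors (deterministic scoring methods in particular are known to have
non-Gaussian error distributions, which is why their intrinsic MUE can
exceed the naive √(2/π) relation on real data), correlations between
methods' errors, per-TKI heterogeneity of the background distribution, and
any structural realism. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not the field accuracy of
any particular predictor.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data.
Law-of-large-numbers checks use 10⁵ records; Bayesian recovery checks use
M = 150 with 5000 draws/500 burn-in (a fit takes on the order of a second),
with a 20-repetition coverage study for the intrinsic RMSE. Every stochastic
function takes a `seed` argument, restores the caller's RNG state, and
reruns byte-identically given the same seed; `run_benchmark()` logs the seed
and all settings in `run_log.json` so each reported number can be reproduced
by calling the underlying function with the logged settings.

## Known limitations

* The normal, zero-bias error model is adopted as-is; no model comparison
  (WAIC/LOO) or robust alternatives are provided.
* `read_benchmark_table()` ingests delimited text only; structure files,
  trajectories and vendor formats are out of scope, as are residue
  renumbering conventions (mutation strings are validated, not renumbered).
* Censoring is handled by exclusion (quantitative metrics, Bayesian fit) or
  forced classification (truth tables), not by likelihood-based truncation.
* The consensus model combines exactly two predictors.
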