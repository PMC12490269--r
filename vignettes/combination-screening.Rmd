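---
title: "Methods: fixed-ratio combination screening, synergy scoring and growth testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-ratio combination screening, synergy scoring and growth testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
library(dplyr)
```

comboscreen implements the analysis chain of a C_max-anchored
drug-combination viability screen: plate normalization, median-effect
curve fitting, fixed-ratio combination design, Chou–Talalay
combination-index (CI) scoring, cross-model AUC ranking, and a
randomization test for in vivo growth arms. This vignette explains the
models, the defaults and the design choices, and states precisely what the
synthetic-data generator does and does not emulate.

## Viability normalization

Percent viability is defined as treated absorbance over the mean
vehicle-control absorbance of the same model line, times 100. Two
behaviors are deliberate:

* **Controls anchor at 100% on average**, not individually — replicate
  control wells scatter around 100% and that scatter propagates honestly
  into every treated well's viability.
* **Viability above 100% is retained and flagged** (`over_control`), never
  clamped. Downstream, such wells give a fraction affected below 0 and are
  handled by fa clipping (below); heatmap rendering shows them as white.

## The median-effect model

Single-agent response is modeled as `fa/fu = (D/Dm)^m`, linear in log–log
coordinates: `log10(fa/fu) = m·log10(D) − m·log10(Dm)`. We fit by
unweighted ordinary least squares on this line, matching the classical
median-effect plot; the linearization is exact on noiseless model data, so
round-trip recovery of `(Dm, m)` to machine precision is a test invariant,
not an approximation claim.

Choices the model forces:

* **fa clipping** (`clip_eps = 0.005`): `log10(fa/fu)` is undefined at
  fa = 0 or 1, so replicate-mean fa values outside
  `[clip_eps, 1 − clip_eps]` are clipped and, by default, *excluded* from
  the regression (configurable via `include_clipped`). Exclusion is the
  conservative choice: a clipped point's position on the line is an
  artifact of the clip bound, not of the data.
* **Regression on replicate means**: replicates are averaged to one fa per
  dose, with per-dose SD retained in the fit object. The source protocol
  does not state replicate handling; means keep each dose's leverage equal
  regardless of replicate count.
* **Dose ladders**: 6 points by default, anchored at the drug's clinical
  C_max. The dilution factor is not stated in the source protocol; the
  default is `sqrt(10)` (half-log), which spans 2.5 orders of magnitude
  and — usefully — makes 10% C_max an exact ladder point (two half-log
  steps below the top). It is configurable.

## Fixed-ratio combinations and the combination index

A combination design fixes the molar ratio of two drugs at
`cmax_a : cmax_b` and scales both together; the screen evaluates the
levels `s = 1` (full C_max) and `s = 0.1` (10% C_max), at which the
combination delivers `(s·cmax_a, s·cmax_b)`. Reading "combined at two
fixed ratios, C_max and 10% C_max" as *each drug at the stated fraction of
its own C_max* is the design's definition here: it keeps the mixing
weights `w_a = cmax_a/(cmax_a + cmax_b)`, `w_b = 1 − w_a` constant across
levels, which is what "fixed ratio" requires.

The CI at a combination point with total dose `D` and observed fraction
affected `fa` is the **mutually exclusive** Chou–Talalay form

    CI = w_a·D / Dx_a(fa) + w_b·D / Dx_b(fa)

with `Dx_i(fa) = Dm_i·(fa/(1−fa))^(1/m_i)` from the single-agent fits.
The source names only the tool it used, not the CI variant; the mutually
exclusive (no cross-term) form is the one in common use and the one whose
sham-combination algebra is exact (a drug paired with itself gives CI = 1
identically). The conservative non-exclusive form is out of scope.

Two asymmetries are intentional and mirror stated practice: `fa` at each
combination point comes from the *measured combination viability*, while
the `Dx` values come from the *single-agent fits*. Points whose
combination fa falls outside the clip bounds are flagged and excluded
from interpretation (a fully ineffective combination yields an
all-flagged profile with a warning rather than an error).

**Interpretation band.** Strict `CI < 1 / = 1 / > 1` labels are unusable
with noise, since an exact 1 has measure zero; values within ±0.05 of 1
are labeled "additive". The band is a reporting convention only — the CI
values themselves are never altered.

Noise propagation is strongly fa-dependent: `Dx` errors scale like
`(fa/fu)^(1/m)`, so CI points at extreme fa (near 0 or 1) amplify fit
noise severely. Tests and examples therefore judge calibration by the
median CI across the profile, or at interior fa.

## Cross-model ranking

Treatments × model-lines matrices hold percent viability at a fixed-ratio
level, or trapezoidal AUC (`Σ ΔX(Y1+Y2)/2`) over the ladder. The AUC
x-axis is `log10(dose)` by default: the source does not state its axis,
and log-dose is the standard domain in which sigmoidal viability curves
are compared; a linear axis is available. AUC confidence limits are
obtained by a seeded nonparametric bootstrap over replicate wells (the
original used an unnamed commercial method). Ranking is by ascending
cross-model mean (most effective first); exact ties break
lexicographically and are flagged; missing cells are a hard error — a
silently zeroed cell would corrupt the ranking, so completeness is
enforced, never imputed.

## In vivo growth testing

Volumes are `length × width²/2`; caliper rows violating the
length ≥ width convention are swapped and flagged. The randomization test
permutes animals between two arms and compares the difference in group
means of a per-animal summary. The source does not state the permuted
statistic; the default is the **trapezoidal AUC of volume over days**
(whole-trajectory burden, robust to a noisy final day), with endpoint
volume as the alternative. The test is two-sided via the absolute mean
difference. With `choose(n_a + n_b, n_a) ≤ 20000` the null is enumerated
exhaustively (the observed labeling counts, so p ≥ 1/N and the test is
exact); otherwise seeded Monte Carlo with the add-one correction
`p = (b+1)/(n_perm+1)` is used. Bonferroni correction multiplies by the
family size and caps at 1.

## The synthetic-data generator

The generator is the package's stated world, fixed once:

* **Plates**: control absorbance mean 1.0; treated absorbance
  `(1 − fa(D))`; multiplicative Gaussian noise truncated at 0 (plate
  readers scale with signal), default relative SD 0.05 — a typical CV for
  absorbance/luminescence viability reads; 3 replicate wells per dose and
  8 vehicle wells.
* **Interaction ground truth**: a single potency-boost factor ψ inside
  the Loewe equation — the combination's fa at doses `(d_a, d_b)` solves
  `ψ·d_a/Dx_a(fa) + ψ·d_b/Dx_b(fa) = 1` (vectorized bisection; the left
  side is strictly decreasing in fa so the root is unique). ψ = 1 is the
  Loewe-additive null, and by construction the downstream CI equals
  `1/ψ` exactly in the noiseless limit — a closed-form oracle that
  validates the whole generator → normalize → fit → CI chain.
  fa-dependent interaction surfaces are deliberately out of scope.
* **Screens**: per-model drug potencies `Dm ~ lognormal(log C_max, 0.3)`
  and `m ~ lognormal(log 1.5, 0.1)` — IC50s scattered around the
  clinically achievable dose, slopes near the typical 1–2 range — with
  one planted pair given ψ = 4 and the rest additive.
* **Growth**: exponential volumes `v0·exp(rate·effect·day)` with
  lognormal measurement noise; defaults v0 = 70 mm³ (the randomization
  threshold of the emulated studies), rate 0.15/day (doubling ≈ 4.6 days,
  reaching ≈ 1600 mm³ untreated by day 21, typical of aggressive murine
  melanoma), noise SD 0.1 on the log scale (≈10% caliper error), 8
  animals/arm, measurements every 3 days for 3 weeks. Lengths and widths
  are emitted equal (`(2V)^{1/3}`), consistent with the volume formula.

What the generator does **not** emulate: plate spatial effects and edge
artifacts, inter-plate batch drift, fa-dependent (non-constant-ψ)
interaction, drug-specific toxicity floors, tumor regression dynamics or
inter-animal growth-rate heterogeneity beyond measurement noise. A green
validation suite therefore establishes internal consistency of the
estimators under the stated world — not robustness to those real-data
features.

## Numerical choices and degenerate inputs

* Loewe bisection: interval `(1e-15, 1 − 1e-15)`, tolerance 1e-12, error
  with diagnostics on non-convergence; zero total dose maps to fa = 0.
* Median-effect fits with fewer than 2 usable points, nonpositive fitted
  slope, or zero/negative doses are errors, not NA results.
* Exact permutation comparisons use a relative tolerance when counting
  relabelings "at least as extreme", so floating-point ties count as ties.
* Level-dose lookup in screen matrices matches `level × top` within a
  1e-8 relative tolerance; a ladder lacking that dose is an incomplete
  cell, reported in the completeness error.
* CSV validation is strict: one bad row rejects the file, with line
  numbers; silent row-dropping is never performed.
* All generators and resampling routines take explicit seeds and restore
  the RNG state (`withr::with_seed`), so every bundle is bit-reproducible
  from inputs + config + seed; `run_pipeline()` records package version,
  seed and a config hash in its log.

## Known limitations

* CI confidence intervals are not computed; the profile reports point
  values, and calibration statements ride on the synthetic null.
* 4PL/5PL logistic fits with profile-likelihood IC50 limits are out of
  scope (delegated to commercial tools in the source workflow), as are
  Bliss/HSA/ZIP scores, isobolograms and the dose-reduction index.
* The randomization test assumes exchangeability of animals between two
  arms; repeated-measures ANOVA-style longitudinal modeling is out of
  scope.
* With 6-point ladders and default noise, `m` is estimated with
  noticeably more variance than `Dm`; screens that need tight slope
  estimates should increase replicates.

## Worked check

A sham self-combination must be additive by algebra, through the full
simulate → fit → CI path:

```{r sham}
tr <- drug_truth("x", Dm = 1, m = 1.5, cmax = 10)
fit <- fit_median_effects(normalize_viability(
  simulate_single_agent_plate(tr, noise_sd = 0, seed = 1)
))$fit[[1]]
design <- combination_design("x", "x'", 1, 1)
sapply(c(0.2, 0.5, 0.8), function(fa) {
  combination_index(fit, fit, design, dose_for_effect(fit, fa), fa)
})
```
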