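---
title: "Organ dosimetry and efficacy analysis for astatine-211 targeted alpha therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ dosimetry and efficacy analysis for astatine-211 targeted alpha therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tatdose)
```

`tatdose` implements the analysis chain of a preclinical targeted alpha
therapy (TAT) study: organ absorbed doses from biodistribution
time–activity curves, survival comparison across injected-activity arms,
and hematologic toxicity metrics. This vignette explains the models, the
choices behind the defaults, and what the synthetic-data generators do and
do not emulate.

## Physical decay model

²¹¹At decays along a branched chain: an alpha branch (fraction 0.418,
5.8695 MeV) to ²⁰⁷Bi, and an electron-capture branch (0.582) to ²¹¹Po,
which alpha-decays to stable ²⁰⁷Pb at 7.4503 MeV with a 0.516 s
half-life. On the hour scale of antibody kinetics ²¹¹Po is in secular
equilibrium with its parent, so the chain collapses to a single
branching-weighted alpha energy per parent decay:

```{r energy}
chain <- read_nuclide_chain()
mean_alpha_energy_per_decay(chain)
```

The branch constants ship with the package as a plain-text table
(`inst/extdata/at211_chain.tsv`), sourced from the ENSDF/MIRD decay
schemes; a config may point to an alternative file. ²⁰⁷Bi (half-life
31.6 y, no alpha) terminates the chain for dosimetry purposes. Photon,
X-ray and electron contributions are deliberately ignored: alpha particles
dominate the absorbed dose and their ~70 µm range justifies local energy
deposition.

## Time–activity curves and their integration

Biodistribution values are %ID/g per organ, animal and sacrifice time
(whole-organ %ID for the neck, which stands in for the thyroid and is
excluded from per-gram dosimetry). Gamma counters conventionally report
decay-corrected values, so tables carry an explicit `decay_corrected`
flag; dosimetry always converts to the **un**corrected scale before
fitting, because the quantity that matters for dose is the number of
decays actually occurring in the tissue. The conversion
(`set_decay_correction()`) multiplies or divides by `exp(-λ·t)` and is
exactly invertible. Whether a given laboratory's export is corrected is a
property of the data, not something this package guesses — hence the flag.

Two fixed model shapes are used, assigned per organ a priori (a
config-level map; no information-criterion selection): monoexponential
decay for organs maximal at the first sacrifice, and the difference of
exponentials `A1·[exp(−λ1·t) − exp(−λ2·t)]`, `λ2 > λ1`, for gut, skin and
stomach, whose activity rises first as dehalogenated astatide accumulates.
The degenerate case `λ1 = λ2` is rejected rather than taken to its
`A·t·e^{−λt}` limit, keeping the difference form and its positivity.

Fitting is Levenberg–Marquardt least squares (`minpack.lm`), by default on
the per-timepoint group means — one curve per organ from 3-mouse means, the
way such studies are usually summarised — with an option to fit all animal
points. Starting values are deterministic: a log-linear regression for the
monoexponential; for the biexponential a coarse grid over `λ2/λ1 ∈ {5, 10,
50}` (with a tail-slope estimate of `λ1`) and `A1` matched to the observed
peak. All parameters are box-constrained to `(1e-6, 1e4)` and the ordering
constraint is structural: the fitter works in `(A1, λ1, δ = λ2 − λ1 > 0)`.
Non-convergence is reported as a flagged result, not an exception, so one
misbehaving organ cannot abort a dose table.

The time-integrated activity is the analytic integral over `[0, ∞)` from
injection — `A0/λ` or `A1·(1/λ1 − 1/λ2)` — checked in the tests against
adaptive quadrature at 1e-6 relative tolerance.

## From integrated activity to absorbed dose

With the AUC on the uncorrected scale, local energy deposition gives

D [Gy/MBq] = (AUC/100) × 3.6×10⁹ × E × 1.602×10⁻¹³ × 10³,

linear in AUC, energy and injected activity. Since %ID/g is already
per-mass, no organ-mass table is needed; a whole-organ (%ID + mass) route
is provided and asserted equal — the mass cancels. Report values round to
one decimal (Gy/MBq and Gy); unrounded values are always retained.
Reported doses at a given activity are products of *rounded* coefficients
only at display time, which is why a table value of 8.0 Gy/MBq at
0.740 MBq can legitimately print as 6.0 Gy in a source report (computed
from unrounded intermediates) while the rounded product gives 5.9 — the
package keeps both honest by retaining the raw coefficient.

Uncertainty: the default SE propagates the fit covariance through the AUC
gradient (delta method) and then the linear dose map. A seeded residual
bootstrap (resample per-point residuals, refit, SD over replicates;
2000 replicates by default) is available as a cross-check and as fallback
when the covariance is unusable. Which method produced a published SE is
rarely stated in reports of this kind; both are labelled as this package's
choices. Note that Wald-type intervals for the *intercept-like* parameter
`A0` undercover noticeably under multiplicative noise (skewed sampling
distribution); intervals for `λ` and for the AUC are near-nominal, and the
AUC is what the dose inherits.

An RBE factor (default 4, the lower end of the 4–5 range used for alpha
particles) converts Gy to photon-equivalent Gy(RBE) for comparison with
external-beam toxicity thresholds.

## Survival and toxicity stages

The Kaplan–Meier estimator and the Mantel–Cox log-rank test are
implemented from their definitions (the `survival` package serves as an
independent oracle in the test suite): deaths before censorings at tied
times, no continuity correction, median defined as the first time `S(t)`
reaches 0.5 **or below** (undefined — `NA`, not an error — when more than
half the arm survives follow-up). Administrative censoring at study end
(day 160 by default, configurable) is `event = 0`. Deaths of undetermined
cause are events by default.

Hematologic toxicity is summarised as the nadir percent decrease from the
pre-treatment baseline (last sample at day ≤ 0), computed per animal and
then averaged per group — whether published group figures were computed
per-animal-first or on group means is usually unstated; per-animal is the
default here and the SD refers to animals. Default nadir search windows
are days 1–7 for WBC, 5–15 for platelets, 1–30 for RBC, matching the
typical day-3 leukocyte and day-10 platelet nadirs; all configurable.
Enzyme values (ASAT/ALAT/creatinine) are flagged against normal ranges
that live entirely in the run configuration with a citation field —
reference intervals are strain- and laboratory-specific, so the package
hard-codes none (the shipped config carries clearly-labelled example
values).

## What the synthetic generators emulate

The generators exist so that every stage — and the full pipeline — can be
tested end to end with known truth:

* **Biodistribution** (`gen_biodistribution()`): 6 sacrifice timepoints
  (0.25, 1, 4, 7, 14, 21 h) × 3 mice × 14 tissues. Truth curves live on
  the uncorrected scale; multiplicative log-normal noise with CV 15%
  (mean 1, so truth is recovered in expectation) emulates the roughly
  constant CVs of such data. Defaults are calibrated so the headline group
  means emerge: blood ≈ 14.9 %ID/g at 21 h and liver ≈ 33.0 %ID/g at
  15 min on the corrected scale. Each synthetic mouse contributes all
  organs at its timepoint, but organ noise is drawn independently — real
  animals induce between-organ correlation that is not modelled, so tests
  say nothing about its effect on SEs.
* **Survival** (`gen_survival()`): a cure-fraction model per arm — cured
  animals are censored at day 160, others draw a log-normal event time
  around the arm median. Arm sizes and cure fractions mirror the study
  design (e.g. 11/17 surviving at 740 kBq, none in the untreated arm,
  median 45 days); medians for arms without a published median are chosen
  to respect the reported ordering. Real cause-of-death structure
  (paraplegia vs extramedullary lesions) is reduced to a single label.
* **Hematology** (`gen_hematology()`): piecewise log-linear
  baseline → nadir → recovery trajectories with multiplicative noise,
  nadir fractions calibrated so reported group decreases (69.9/56.1/53.6%
  WBC at 740/555/370 kBq; 39.0% platelets at 1110 kBq) emerge in
  expectation.

Generators are pure functions of `(truth, seed)` and restore the caller's
RNG state; the pipeline fans one global seed into fixed per-generator
substreams. Problem sizes used by the test suite — 200 fit replicates for
coverage, 40 replicate studies for full-pipeline dose recovery, 200 seeds
for survival calibration — were chosen as the smallest giving stable Monte
Carlo estimates of those properties.

Passing tests on this synthetic design demonstrate estimator correctness
and calibration under the stated noise model; they do not validate the
kinetic model forms against real curves, nor the noise model against a
specific gamma counter.

## Numerical and degenerate-input conventions

* Branch fractions must sum to 1 within 1e-9 per parent; chains must be
  acyclic (checked at load).
* Times and values must be non-negative; mixed decay-correction flags in
  one table are an error rather than silently resolved.
* Zero fit covariance yields SE 0; an absent or non-finite covariance
  falls back to the bootstrap with a warning.
* KM ties: deaths processed before censorings; log-rank variance uses the
  hypergeometric form with the `(n − d)/(n − 1)` factor.
* A single-animal toxicity group reports a mean with `NA` SD.

## Known limitations

Single-nuclide, alpha-only dosimetry (no Bateman chains, no photon
cross-dose, no marrow microdosimetry); two fixed TAC shapes with a priori
assignment; two-group log-rank only (no trend test, no Cox model); no
mechanistic link from dose to survival — the survival and dosimetry stages
share inputs but not a model.
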