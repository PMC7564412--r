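# tatdose

Preclinical dosimetry and efficacy analysis for targeted alpha therapy
(TAT) with astatine-211-labeled antibodies.

When an alpha-emitter-labeled radioimmunoconjugate is tested in mice, three
datasets decide whether a given injected activity is worth carrying
forward: an organ biodistribution study (%ID/g over time), a survival
study across activity arms, and serial blood counts for hematologic
toxicity. `tatdose` turns those tables into the standard report quantities:
per-organ absorbed doses in Gy/MBq with standard errors, Kaplan–Meier
curves with Mantel–Cox log-rank comparisons, and nadir percent-decrease
summaries — plus seeded synthetic-data generators so the whole pipeline is
testable without animal data.

## The dosimetry model

Each organ's time–activity curve (TAC), fitted on the decay-**un**corrected
scale so that physical decay is part of the effective clearance, is either

* mono-exponential, `f(t) = A0·exp(−λ·t)` (blood, liver, kidneys, spleen,
  lungs, heart, brain, muscle, flat bone, femur), or
* bi-exponential, `f(t) = A1·[exp(−λ1·t) − exp(−λ2·t)]` with `λ2 > λ1`
  (gut, skin, stomach — organs that accumulate free astatide first).

The time-integrated activity is the analytic area under the fitted curve
(`A0/λ`, respectively `A1·(1/λ1 − 1/λ2)`), and — because alpha particles
deposit their energy within ~70 µm — the absorbed dose per unit injected
activity follows by local energy deposition:

```
D [Gy/MBq] = (AUC/100) [ID·h/g] × 3.6e9 [decays·MBq⁻¹·h⁻¹]
             × E [MeV] × 1.602e-13 [J/MeV] × 1e3 [g/kg]
```

with `E = 6.79 MeV` per ²¹¹At decay: the branching-ratio-weighted alpha
energy of the chain (41.8% α to ²⁰⁷Bi at 5.8695 MeV; 58.2% EC to ²¹¹Po,
which alpha-decays at 7.4503 MeV). Standard errors propagate the fit
covariance through the AUC gradient (delta method), with a seeded residual
bootstrap as cross-check. Multiplying by the injected activity and an RBE
factor of 4–5 gives photon-equivalent organ doses.

## Worked example

```r
library(tatdose)
cfg <- read_run_config()            # packaged defaults: 740 kBq, RBE 4, seed 1
sim <- simulate_study(cfg, seed = 1)    # synthetic biodist + survival + hematology
res <- run_all(cfg, sim$biodist, sim$survival, sim$hematology)
print(res$dose_table)
```

```
<dose_table> At-211, 6.79 MeV/decay, 13 organs
     organ   model converged     auc dose_gy_per_mbq se_gy_per_mbq
     blood monoexp      TRUE 248.100             9.7           0.7
     liver monoexp      TRUE 256.800            10.1           0.2
    spleen monoexp      TRUE 231.300             9.1           0.6
   kidneys monoexp      TRUE 103.400             4.0           0.4
   stomach   biexp      TRUE 229.700             9.0           0.5
       ...
```

Each row is one organ: the fitted model, the analytic time-integrated
activity (`auc`, %ID·h/g), the dose coefficient (Gy per MBq injected) and
its delta-method SE. `res$dose_at_activity` scales these to the configured
740 kBq injection (blood 7.2 Gy, liver 7.4 Gy here) and applies the RBE
factor; `res$survival_summary` gives per-arm medians and survival
percentages (e.g. the synthetic 740 kBq arm: 11/17 censored survivors,
65%, median undefined because S never reaches 0.5); `res$logrank` holds
the pairwise Mantel–Cox tests against control (740 kBq vs control:
χ² = 35.6, p = 2.4e-09); `res$toxicity` the nadir decreases (synthetic
740 kBq WBC arm: 69.9% mean decrease, nadir day 3). `run_all(...,
out_dir =)` writes the same tables as a CSV bundle with a provenance
manifest. A thin command-line wrapper is available as
`Rscript scripts/tatdose <simulate|run-all> --seed N --out-dir DIR`.

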