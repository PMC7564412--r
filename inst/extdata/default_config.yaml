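# Default run configuration.
# Every constant used by a pipeline run is declared here and echoed into the
# run manifest for provenance.
nuclide_file: null          # null = the 211At chain shipped with the package
energy_override_mev: null   # set to force an energy per decay (MeV)
injected_kbq: 740           # activity for the dose-at-activity report line
activities_kbq: [370, 555, 740, 1110]
rounding_digits: 1          # report rounding for Gy/MBq and Gy
rbe: 4.0                    # lower bound of the usual 4-5 alpha RBE range
seed: 1                     # global seed; generators use fixed offsets of it
censor_day: 160             # administrative censoring, days from engraftment
fit_means: true             # fit per-timepoint means (one curve per organ)
se_method: delta            # delta | bootstrap
n_boot: 2000
# organ -> time-activity model assignment
organ_models:
  blood: monoexp
  flat_bone: monoexp
  femur: monoexp
  muscle: monoexp
  liver: monoexp
  kidneys: monoexp
  lungs: monoexp
  spleen: monoexp
  brain: monoexp
  heart: monoexp
  gut: biexp
  intestine: biexp
  skin: biexp
  stomach: biexp
# nadir search windows, days post treatment
nadir_windows:
  wbc: [1, 7]
  platelets: [5, 15]
  rbc: [1, 30]
# Normal ranges for enzyme flagging. EXAMPLE values typical of published
# C57BL/6 reference intervals; replace with your laboratory's intervals.
normal_ranges:
  alat: [7, 60]        # IU/L
  asat: [37, 150]      # IU/L
  creatinine: [0.2, 0.9]  # mg/dL
  citation: "user-supplied laboratory reference intervals (example values)"
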