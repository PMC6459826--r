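# Scaled-down scenario profile: 50 replicates per treatment, fast
# (run-to-convergence) burn-in. Values omitted here fall back to the
# package defaults (see ?scenario_defaults).
n_reps: 50
base_seed: 1
burn_in: fast
plateau_F: 1.0
treatments: [0, 0.02, 0.025, 0.033, 0.05, 0.10]
grid:
  n_classes: 100
  w_min: 5
  w_max: 40000
years:
  burn_in_start: 1667
  historic_start: 1967
  plateau_start: 2010
  release_start: 2040
  end_year: 2200
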