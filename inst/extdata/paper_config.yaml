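# Full-scale scenario profile: 300 replicates per treatment (1800 runs)
# and the stochastic 300-year burn-in from 1667.
n_reps: 300
base_seed: 1
burn_in: full
plateau_F: 1.0
treatments: [0, 0.02, 0.025, 0.033, 0.05, 0.10]
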