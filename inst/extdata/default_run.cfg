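[elastic_model]
kT_pNnm = 4.114
trap_stiffness_pN_per_nm = 0.15
handle_contour_nm = 600
handle_persistence_nm = 40
handle_stretch_modulus_pN = 1000
ss_contour_per_nt_nm = 0.65
ss_persistence_nm = 1
folded_offset_nm = 2

[hmm]
n_states = 6
seed = 1
min_dwell = 3

[kinetics]
dead_time_s = 0.5
bins = 0

[energetics]
bootstrap_n = 1000
seed = 1

[network]
tolerance_nm = 1.5

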