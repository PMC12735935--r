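# desk-scale demo configuration for run_end_to_end()
grid_shape: [16, 16, 8]
n_hc: 24
n_mtbi: 19
snr: 100.0
k: 3
seed: 42
include_gose: yes
n_regions: 90
asl_pairs: 20
asl_snr: 50.0
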