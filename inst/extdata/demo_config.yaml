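# Demonstration run: small simulated cohort through the full
# simulate -> extract -> correlate -> report workflow.
seed: 7
simulate: true
n_patients: 10
eq_missing_fraction: 0.2
ssf_list: [0.0, 2.0, 3.0, 4.0, 5.0, 6.0]
entropy_bins: 256
erosion: true
kurtosis_excess: true
alpha: 0.05
out_dir: eqctta_demo
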