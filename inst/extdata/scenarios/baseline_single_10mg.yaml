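name: baseline_single_10mg
fw: 0
dose_mg: 10
mode: representative
t_end: 504
seed: 1
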