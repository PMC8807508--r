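name: trimester3_qd
trimester: 3
dose_mg: 10
interval_h: 24
parameter_mode: table2_canonical
mode: representative
seed: 1
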