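n_persons: 2000
within_sd: 0.4
missing_rate: 0.01
careless_rate: 0.03
seed: 42
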