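# Example derivation configuration for `hfclust derive`
n_components: 20
schemes: [quartiles, deciles, p10_90, p20_80]
scheme_k: 3
k_max: 4
B: 99
n_starts: 12
seed: 5
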