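# Example synthetic-cohort configuration for `hfclust simulate`
n_samples: 600
n_proteins: 120
n_informative: 36
n_classes: 3
seed: 421
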