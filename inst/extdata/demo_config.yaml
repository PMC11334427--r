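# Demo pipeline configuration: synthetic genomes with a conserved (16S-like)
# and a fast (dnaK-like) marker, a count cohort, and all analysis stages.
seed: 20240716
n_taxa: 12
divergence: 0.025
background_length: 3000
ssu_length: 800
fast_length: 130
fast_rate: 3
n_samples: 80
n_asvs: 120
n_da_asvs: 10
da_fold_change: 4
richness_slope: -0.08
fdr_alpha: 0.20
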