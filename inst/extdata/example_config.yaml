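seed: 101
genome_length: 1500000
n_genes: 600
group_sizes: [40, 24, 18]
n_repressed: [5, 2]
background_depth: 20.0
enrichment_fold: 8.0
fragment_len_mean: 300.0
fragment_len_sd: 80.0
nb_mean_baseline: 100.0
nb_dispersion: 0.02
induction_fold: 8.0
partial_fold: 2.0
replicates: 3
gene_length: 900
contig: synth1
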