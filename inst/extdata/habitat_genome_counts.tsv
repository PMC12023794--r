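# Per-habitat genome counts of the curated reference comparative dataset
# (fungus-associated bacteria versus bacteria of other hosts and habitats).
habitat	n_genomes
fungi	163
plants	316
humans	212
soil	284
water	236
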