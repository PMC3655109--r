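# Simulation settings for a small barcoded amplicon study.
# Omitted keys fall back to the package defaults.
n_individuals = 8
copies_prob = 1:0.2,2:0.35,3:0.3,4:0.15
substitution_rate = 0.005
homopolymer_indel_rate = 0.01
chimera_rate = 0.03
reads_per_replicate = 40
mid_length = 10
seed = 11
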