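clade,n_species,solidity_mean,solidity_sd,ar_mean,ar_sd,amp_noise_sd,jitter_sd,abaxial_amp_offset,leaf_link
fern,30,0.68,0.06,0.60,0.08,0.02,0.01,0.05,TRUE
monocot,30,0.88,0.04,0.35,0.08,0.02,0.01,0.05,TRUE
eudicot,30,0.78,0.06,0.65,0.08,0.02,0.01,0.05,FALSE
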