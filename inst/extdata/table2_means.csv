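response,nestbox_mean,nestbox_se,control_mean,control_se,p_printed
richness,4.23,0.39,3.67,0.19,0.104
insectivore_richness,2.01,0.07,1.21,0.25,0.002
total_abundance,3.71,0.43,2.09,0.33,0.003
bluebird_abundance,1.82,0.14,0.18,0.05,<0.001
nonbluebird_insectivore_abundance,0.84,0.11,0.47,0.15,0.119
omnivore_abundance,0.14,0.09,0.18,0.02,0.307
granivore_abundance,1.20,0.31,1.23,0.11,0.454
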