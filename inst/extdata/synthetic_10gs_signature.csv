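gene_id,coefficient
AR,-0.021
JUN,0.034
STAT1,-0.018
PRKCB,0.027
RelA,-0.04
ABL1,0.012
SUMO1,-0.009
PAK2,0.031
HDAC1,-0.025
IRF1,0.016
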