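1	500	1500	gene_causal
1	30500	31500	gene_mid
1	59990	60500	gene_end
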