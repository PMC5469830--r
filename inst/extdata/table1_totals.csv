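block,dmc_total,analysed_total
gene_region,5302,479691
island,4856,408329
enhancer,4856,408329
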