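block,hyper_total,hypo_total
gene_region,1613,3243
island,1613,3243
enhancer,1613,3243
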