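block,category,hyper_count,hypo_count
gene_region,TSS1500,237,445
gene_region,TSS200,86,106
gene_region,5UTR,166,322
gene_region,FirstExon,39,78
gene_region,Body,705,1249
gene_region,3UTR,77,96
gene_region,Intergenic,468,1228
island,Island,270,183
island,Shore,489,719
island,Shelf,138,350
island,OpenSea,716,1991
enhancer,Enhancer,637,1611
enhancer,NonEnhancer,976,1632
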