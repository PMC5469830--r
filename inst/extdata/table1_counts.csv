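block,category,dmc_count,analysed_count
gene_region,TSS1500,682,73530
gene_region,TSS200,192,55640
gene_region,5UTR,488,57408
gene_region,FirstExon,117,34391
gene_region,Body,1954,148809
gene_region,3UTR,173,16571
gene_region,Intergenic,1686,93342
island,Island,453,133415
island,Shore,1208,97243
island,Shelf,488,37691
island,OpenSea,2707,139980
enhancer,Enhancer,2248,90996
enhancer,NonEnhancer,2608,317333
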