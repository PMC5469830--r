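# dmc450

Two-group differential-methylation analysis for Infinium 450K-style
arrays, for epigenomics researchers comparing methylation between a case
and a reference group of samples (e.g. tumour-derived vs normal
fibroblast lines) starting from a beta-value matrix.

The pipeline:

1. **Probe filtering** — excludes non-CpG targets, SNP-overlapping,
   multi-mapping and SNP-proximal probes (distance ≤ 2 nt to a SNP with
   MAF > 0.05), probes with detection p > 0.01 or bead count < 3 in any
   sample, and sex-chromosome probes, with an auditable per-rule ledger.
2. **DMC calling** — per-probe Welch's t-test on beta-values,
   Benjamini–Hochberg correction, and the DMC definition
   *adjusted p < 0.01 and |Δβ| > 0.15* (Δβ = case mean − reference mean;
   Δβ > 0 is hypermethylated, Δβ < 0 hypomethylated).
3. **Genomic context** — gene regions (TSS1500, TSS200, 5′UTR, 1st exon,
   body, 3′UTR, intergenic), CpG-island relation (island / shore ≤ 2 kb /
   shelf 2–4 kb / open sea), intragenic vs intergenic islands, enhancer
   flags.
4. **Enrichment** — per-category 2×2 tables of DMC vs non-DMC probes,
   with odds ratio `OR = ad/bc`, Katz 95% CI
   `exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d))`, Yates-corrected chi-square
   p-values, and hyper-vs-hypo direction tables.
5. **TSS mapping** — DMCs within ±1,500 nt of a TSS, collapsed to gene
   lists, with a hypergeometric over-representation test against
   user-supplied GMT gene sets.
6. **Exploratory** — classical MDS of sample profiles, hierarchical
   clustering of DMCs, per-group CV of median beta, Brown–Forsythe
   variance test.

A synthetic-data generator (`sim_config()`, `simulate_study()`) emulates
a 450K experiment — annotation frequencies, Beta-distributed beta-values
with planted differential probes, QC artifacts — so every stage is
testable without array data, and the package bundles the printed
contingency counts of a published 12-vs-10 fibroblast study as exact
regression anchors for the enrichment statistics.

## Worked example

```r
library(dmc450)

cfg  <- sim_config(n_probes = 10000, seed = 42)   # 12 ref vs 10 case samples
sim  <- simulate_study(cfg)
filt <- filter_probes(sim$study, sim$manifest)
print(filt$ledger)
#> Probe filter ledger
#>   input:    10000
#>   retained: 8500
#>   - non_cpg         70
#>   - snp_aligned     188
#>   - multi_mapping   524
#>   - snp_proximal    455
#>   - detection_p     37
#>   - bead_count      18
#>   - sex_chromosome  208

dmc <- dmc_analysis(filt$study)
summary(dmc)
#>     total     hyper      hypo pct_hyper  pct_hypo
#> 408.00000 200.00000 208.00000  49.01961  50.98039

ctx <- assign_context(filt$manifest, islands = sim$islands)
t1  <- build_table1(count_by_region(ctx, dmc))
t1[t1$block == "island", c("category", "count_dmc", "pct_dmc",
                           "odds_ratio", "ci_low", "ci_high", "p_value")]
#>    category count_dmc pct_dmc odds_ratio ci_low ci_high p_value
#> 8    Island       131   32.11      0.990  0.800    1.22   0.969
#> 9     Shore        95   23.28      0.972  0.769    1.23   0.862
#> 10    Shelf        39    9.56      1.052  0.750    1.48   0.839
#> 11  OpenSea       143   35.05      1.013  0.823    1.25   0.944
```

Reading this: the filter removed 1,500 of 10,000 probes (each charged to
its first failing rule); 408 probes passed the DMC thresholds, split
roughly evenly between directions because the simulation plants both; and
the island-block odds ratios sit near 1 with p ≈ 1 because this synthetic
run plants differential probes uniformly across contexts — no enrichment
exists, and none is reported.

On the bundled reference counts the same machinery reproduces the
published enrichment statistics exactly:

```r
ref <- reference_table1()
ref[c(2, 5, 8, 11, 12), c("block", "category", "odds_ratio",
                          "ci_low", "ci_high", "p_value")]
#>          block category odds_ratio ci_low ci_high    p_value
#> 2  gene_region   TSS200     0.2839 0.2457  0.3280  3.536e-74
#> 5  gene_region     Body     1.3017 1.2306  1.3768  3.066e-20
#> 8       island   Island     0.2093 0.1900  0.2306 1.636e-266
#> 11      island  OpenSea     2.4427 2.3074  2.5860 2.394e-220
#> 12    enhancer Enhancer     3.0568 2.8877  3.2357  0.000e+00
```

i.e. DMCs depleted at TSS200 and in CpG islands, enriched in gene bodies,
open seas and enhancers, relative to the non-DMC background.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/dmc450.R simulate --out study_dir --n-probes 50000 --seed 1
Rscript inst/cli/dmc450.R run --dir study_dir --out results_dir
```

## Vignette

`vignettes/dmc450-methods.Rmd` documents the statistical model, every
threshold and boundary convention, the design decisions taken where the
conventional workflow is underspecified, what the simulator does and does
not emulate, and known limitations.
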