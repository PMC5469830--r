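---
title: "Methods: differential CpG methylation and genomic-context enrichment"
author: "dmc450"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential CpG methylation and genomic-context enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmc450)
```

## Scope and model

`dmc450` implements a two-group analysis of Infinium 450K-style DNA
methylation data starting from a matrix of per-probe beta-values. The
beta-value at a CpG is the fraction of methylated signal, from 0 (no
methylation) to 1 (complete methylation). The pipeline has six analysis
stages — probe filtering, differentially methylated CpG (DMC) calling,
genomic-context annotation, contingency-table enrichment, TSS mapping with
gene-set over-representation, and sample-level exploratory statistics —
plus a synthetic-data generator that makes the whole chain testable
without array data.

The package bundles, as plain-text fixtures, the per-category contingency
counts of a published comparison of 12 normal vs 10 tumour-derived
oesophageal fibroblast lines (4,856 DMCs over 408,329 analysed probes).
The raw arrays of that study were never deposited, but the printed counts
fully determine its enrichment statistics, so they serve as exact
regression anchors for the odds-ratio / confidence-interval / chi-square
machinery (see `reference_table1()`).

## Probe filtering

A probe is excluded when it (1) does not target a cytosine within a CpG,
(2) aligns to a known SNP, (3) aligns to multiple genomic locations,
(4) targets a cytosine two or fewer nucleotides from a SNP whose minor
allele frequency exceeds 0.05, (5) has a detection p-value above 0.01 in
*any* sample, (6) has a bead count below 3 in *any* sample, or (7) lies on
the X or Y chromosome. Two conventions matter and are tested explicitly:

* comparisons are strict — detection p exactly 0.01 and MAF exactly 0.05
  are retained; "two or fewer nucleotides" means `distance <= 2`;
* the retained set is the set of probes failing *no* rule, so it is
  independent of rule order; the audit ledger, by contrast, attributes
  each excluded probe to the *first* failing rule in the order above, so
  its per-rule counts always sum to the number excluded.

SNP and mapping flags are consumed from the manifest, not recomputed from
genome sequence: which published blacklists produced them is an input
decision, not something the pipeline can recover.

## DMC calling

Group means are arithmetic means per probe within each group, with missing
entries pairwise-deleted and counted. The effect size is
`delta beta = mean(case) - mean(ref)`.

The per-probe test is Welch's unequal-variance two-sample t-test on
beta-values, two-sided, with Welch–Satterthwaite degrees of freedom. The
array-vendor software historically used for this comparison implements a
proprietary, undocumented probe model; Welch's t is the standard,
symmetric, small-n replacement and is exposed as a pluggable strategy
(`dmc_analysis(test_fun = ...)`) so alternatives can be registered.
Degenerate probes (zero variance in both groups) return p = 1 at equal
means and the smallest representable positive p otherwise, keeping p in
(0, 1].

Raw p-values are corrected by Benjamini–Hochberg step-up (through
`stats::p.adjust`; the test suite checks it against a brute-force
threshold-scan oracle). A probe is a DMC when `adjusted p < 0.01` **and**
`|delta beta| > 0.15`, both strict; DMCs with positive delta are
*hypermethylated* (case above reference), negative *hypomethylated*.
Because the effect gate is far from the null sampling noise at these group
sizes (s.e. of delta ≈ 0.02), the caller is conservative: on null
synthetic data the false-call rate is essentially zero.

## Genomic context

*Coordinates.* Manifest positions (`MAPINFO`) are 1-based; island
intervals travel as BED (0-based half-open) and are converted internally.
Exported BED records are 0-based half-open single-base intervals.

*Island context.* A probe inside a (merged) island interval is `Island`.
Otherwise its distance to the nearest island edge — with the base directly
adjacent to the island at distance 1 — decides: distances 1–2000 are
`Shore`, 2001–4000 `Shelf`, beyond that `OpenSea`. The outer boundaries
are closed (exactly 2,000 nt is still Shore, exactly 4,000 nt still
Shelf); the common "2 kilobase" definition does not specify open or closed
edges, so the choice is documented here and pinned by boundary tests.
North/south shore and shelf distinctions are collapsed, matching the
granularity of the bundled reference tables. Strand is ignored for island
distances (CpGs are strand-symmetric).

*Gene regions.* Probes carry zero or more region annotations (TSS1500,
TSS200, 5'UTR, 1st exon, gene body, 3'UTR); a probe with none is
intergenic. Region tallies therefore sum over annotations and may exceed
the probe count, while island-relation and enhancer tallies partition the
probes exactly — an invariant asserted on every synthetic run.

*Intragenic islands.* An island is intragenic when **any** of its member
probes carries a gene-region annotation, else intergenic; probe-less
islands are reported as unclassifiable rather than guessed.

## Enrichment statistics

Each report row is built from a 2×2 contingency table.

*DMC vs background.* The "all CpGs analysed" column of a published-style
report **includes** the DMCs, so `dmc_vs_background_table()` subtracts
them: the comparison is DMC vs non-DMC probes, in-category vs not. This
convention is deliberate and load-bearing: it, and only it, reproduces the
reference odds ratios to four significant figures (e.g. TSS200 0.2839,
enhancer 3.057); the naive construction that leaves DMCs in the background
column gives visibly different values (0.8154 instead of 0.8137 for
TSS1500) and is rejected by a regression test.

*Statistics.* The odds ratio is the plain cross-product `(a·d)/(b·c)`. The
95% interval is the Katz log-scale approximation
`exp(log OR ± 1.959964 · sqrt(1/a + 1/b + 1/c + 1/d))`. The test is the
Yates-corrected chi-square,
`N(|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))` with the correction floored
at zero, referred to chi-square with 1 df. Zero cells make the OR/CI
undefined; no continuity correction is silently added — the row instead
carries an explicit `status` (`undefined_or` / `undefined_ci`), because a
hidden +0.5 would corrupt the exact regression anchors. A zero margin
yields p = 1 by convention. A multi-category goodness-of-fit chi-square
(`goodness_of_fit_distribution()`) compares the DMC distribution across
regions with expectations proportional to the analysed distribution.

*Direction (hyper vs hypo) reports.* `build_table2()` compares, per
category, the hyper/hypo composition of DMCs inside the category with
those outside (`direction_table()`). For the enhancer block this exactly
reproduces the reference ratio 0.6612. The reference study's printed
per-gene-region and island direction ratios, however, are not derivable
from their own printed row counts under any standard 2×2 construction we
tried (e.g. TSS200 prints 16.78 against row counts 86/106 whose direct
ratio is 0.83); the package computes the documented direct ratio and those
rows are excluded from the regression suite rather than reverse-fitted.

The Katz interval reproduces the reference CI bounds to printed precision
on most rows and to within ~0.3% on the rest; the residual last-digit
differences are consistent with the reference values having been produced
by different software with its own interval method and rounding.

## TSS mapping and over-representation

DMCs are assigned to **all** transcripts whose TSS lies within 1,500 nt
(boundary inclusive), with the nearest transcript flagged — a superset
that supports both "nearest transcript" and "all transcripts in window"
readings. The signed distance is strand-aware: negative means upstream of
the TSS in the transcript's reading direction (plus strand: `pos − tss`;
minus strand: `tss − pos`).

Gene lists (all / hyper-only / hypo-only; a gene carrying both directions
appears in both) feed a hypergeometric over-representation test:
`P(X ≥ overlap)` for drawing the selection from the universe, BH-adjusted
across sets. Gene sets arrive as flat GMT files; no ontology database is
bundled and no term-graph propagation is attempted — identical statistic,
user-supplied sets.

## Exploratory statistics

* `mds_embed()` — classical (Torgerson) scaling of Euclidean distances
  between sample beta-profiles over all retained probes. Common array
  toolchains default to a leading-log-fold-change distance for this plot;
  Euclidean-on-all-probes is chosen as the parameter-free option and the
  divergence is noted. Exactly embeddable configurations reproduce their
  distance matrices to 1e-9.
* `hier_cluster()` — agglomerative clustering, Euclidean + average
  linkage by default (unstated in the usual workflow; chosen for
  determinism and familiarity, configurable).
* `median_beta_cv()` — per-group coefficient of variation of per-sample
  median beta.
* `levene_median_test()` — Brown–Forsythe test (ANOVA F on absolute
  deviations from group medians) of equal group variances, via
  `car::leveneTest(center = median)` and cross-checked against a
  from-scratch F computation in the tests.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
the reference study's design by default: 12 reference vs 10 case samples,
gene-region / island-relation / enhancer category frequencies matching the
reference "all CpGs analysed" composition (e.g. enhancer 22.3%, islands
32.7%), and QC artifacts at rates with 450K-annotation-list magnitudes
(≈0.7% non-CpG targets, ≈6% multi-mapping, ≈2% SNP-overlapping, ≈5%
SNP-proximal, ≈2.4% sex-chromosome probes, plus sporadic detection and
bead-count failures).

Chromosomes are tiled with a 20 kb period containing one 1 kb island per
tile, so island/shore/shelf/open-sea zones are disjoint by construction
and a probe's island relation is decided by its position alone — the
manifest's relation strings and the position-derived assignment can be
cross-validated exactly, which the test suite does.

Beta noise is `Beta(mu·phi, (1 − mu)·phi)`: mean exactly `mu`, two
interpretable parameters, support bounded in [0, 1]. The default precision
`phi = 100` gives a within-group s.d. of ≈0.05 at mu = 0.5 (less near the
boundaries). No public dispersion estimate exists for the reference
study's within-group beta variability, so this default is a documented
field-realistic choice, not a claim about that study. Baseline means are
island-context dependent (islands mostly unmethylated, open sea mostly
methylated). A configured fraction of probes (default 5%) is truly
differential with the case mean shifted by exactly `true_delta` (default
0.3), split evenly between directions by default; reference means for
shifted probes are drawn so the shift never hits the clip boundaries, so
the expected observed effect equals `true_delta` exactly. One global seed
drives a named sub-stream per stage, making every stage independently
reproducible.

What the generator does **not** emulate: probe-type (Infinium I/II)
chemistry differences, batch and chip effects, spatially correlated
methylation along the genome, cell-composition heterogeneity, and
correlated multi-gene annotations. Passing recovery tests therefore show
the pipeline is correct under its stated model, not that the model
captures every feature of real arrays.

## Problem sizes and numerical conventions

The recovery and invariant suites run at 50,000 probes × 22 samples — big
enough that binomial sampling error on category frequencies is ~0.2% and
the Welch t at the planted effect is decisive (t ≈ 14), small enough to
keep the full suite fast. At these conditions sensitivity for planted DMCs
is ~1 and the empirical false-discovery proportion ~0, against acceptance
floors of 0.9 and 0.01.

Numerical conventions collected in one place: strict threshold
inequalities everywhere; Welch degenerate-case p-values as above; BH ties
handled by the step-up running minimum; undefined OR/CI as explicit
statuses, never exceptions; hclust tie-breaks inherited from
`stats::hclust` (deterministic); TSV output with fixed column order and
probe-id-sorted rows so re-runs are byte-identical.

## Known limitations

* The per-probe test is Welch's t on beta-values, not a reimplementation
  of the proprietary model used by the vendor software; headline DMC
  counts from studies that used that model are therefore not comparable
  and are not regression targets.
* Beta-values near 0/1 are heteroscedastic; no M-value transform is
  offered because the DMC definition is stated on the beta scale.
* Enrichment is marginal per category; no GC-content or probe-density
  correction, no logistic-regression or permutation nulls.
* The intragenic/intergenic island classification depends on probe
  coverage of the island: islands without probes are unclassifiable.
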