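---
title: "Ontology-guided refinement of bulk-segregant QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-guided refinement of bulk-segregant QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoqtl)
```

## The problem

Bulk segregant analysis (BSA) locates trait loci by sequencing *pools* of
individuals from a segregating cross, binned by extreme trait values, and
contrasting pooled allele frequencies. It is cheap relative to genotyping
every individual, but it trades resolution for it: a pooled contrast
yields broad candidate regions containing thousands of genes. `ontoqtl`
implements both halves of a refinement strategy for this situation:

1. the **statistical half** — pooled-variant filtering, per-SNP contrast
   statistics, and simulation-calibrated candidate calling that turns a
   multi-pool VCF into QTL intervals; and
2. the **ontological half** — a cascade of gene-set arguments
   (per-contrast term enrichment, cross-contrast comparison, pruning of
   the enriched subgraph beneath an anchor term, zooming to a focus
   term, pathway enrichment) that shrinks the QTL gene lists down to a
   handful of mechanistically coherent candidates.

The motivating application is flowering time in a *Brassica oleracea*
cross between a rapid-cycling doubled-haploid (DH) line and a
late-flowering heterozygous kale, phenotyped into four flowering-time
pools; the package, however, is agnostic about organism and trait: the
anchor and focus terms are parameters, not constants.

## The statistics

### SNP-index and Δ(SNP-index)

For one pool at one biallelic site, the SNP-index is the alternate-allele
read fraction $\mathrm{idx} = a/(r+a)$. For a contrast (A, B) the package
reports $\Delta = \mathrm{idx}_B - \mathrm{idx}_A$. Pools are given in
trait order, so a positive $\Delta$ means the alternate allele is
enriched in the higher-trait pool. Under no linkage to the trait,
$\Delta$ is symmetric about zero.

### G and G′

Per SNP, the G statistic is the likelihood-ratio (G-test) statistic of
the 2×2 allele-by-pool count table,

$$G = 2 \sum_{i=1}^{4} n_i \ln (n_i/\hat n_i),$$

with expected counts under row/column independence and $0\ln 0 \equiv 0$.
G is zero exactly when the two pools have identical allele proportions.
Because single-SNP counts are noisy, G is smoothed along each chromosome
with a tricube kernel over physical distance:

$$G'_i = \frac{\sum_j k_j G_j}{\sum_j k_j},\qquad
k_j = \left(1 - (d_j/h)^3\right)^3 \ \text{for}\ d_j \le h ,$$

where $d_j$ is the distance from the focal SNP. The window is specified
by its total width $W$ (default 1 Mb); we interpret "width" as the full
window, i.e. half-width $h = W/2$ on each side, and expose
`width_is_total = FALSE` for the other convention, since implementations
of this smoother disagree on it. Smoothing never crosses chromosome
boundaries.

### Candidate calling and its calibration

Candidates are SNPs with $G' > 2.5$ (strictly), optionally required to
also have $\Delta$ outside a simulated null confidence interval.
The CI is built by Monte-Carlo (default 10,000 replicates, two-sided
95%): each replicate draws per-pool allele frequencies from the cross
design's segregation — for the default `f1_het_dh` design every pooled
individual carries the segregating allele with probability ½ on the 0/1
haplotype scale; an `f2` design (dosage Binomial(2, ½)/2) is provided —
then draws read counts Binomial(depth, frequency) and records
$\Delta$. Bounds are tabulated per depth and interpolated.

**Why the Δ-CI gate is on by default in the pipeline.** The null
distribution of G at a marker reflects two noise sources: read sampling
*and* the binomial sampling of which individuals ended up in each pool.
With large pools the second source vanishes and null G′ concentrates
near 1, so a fixed cutoff of 2.5 is conservative. With small pools —
8–11 individuals, the scale this workflow targets — pool-composition
sampling alone puts the null mean of G around
$1 + d\,\overline{(f_A-f_B)^2}/(2\bar p\bar q) \approx 13$ at 110×
depth, far above 2.5, and smoothing does not reduce the mean. A bare G′
cutoff is therefore not a null-calibrated test at small pool sizes. The
Δ-CI simulation *is* calibrated to the pool sizes by construction, which
is precisely why a QTL-seq-style confidence simulation accompanies the
G′ scan; `run_refine()` accordingly uses
`threshold_config(2.5, use_delta_ci = TRUE)` unless told otherwise.

As an alternative to the fixed threshold, `null_pvalues()` fits a
log-normal null to the bulk of the G′ distribution by robust
location/scale (median and MAD of log G′ after trimming beyond 3 MADs),
on the reasoning that most of the genome is unlinked to the trait; it
reports right-tail p-values and Benjamini–Hochberg q-values. It refuses
degenerate (constant) G′ input.

### From SNPs to regions

QTL regions are maximal runs of flagged SNPs whose consecutive gaps do
not exceed `max_gap` (default 1 Mb, matching the smoothing window), with
at least `min_snps` members (default 10). Unflagged SNPs never break a
run. The region span is the first and last member SNP — deliberately
conservative; we do not extend by the kernel half-width, so a region is
reproducible from the flagged set alone. Coordinates are 1-based
inclusive internally (VCF/GFF3 convention); the BED6+3 export is the one
place that converts to 0-based half-open, and it round-trips.

## Variant filtering

Filters are applied per contrast in a fixed order, each record
attributed to the first rule it fails: per-pool AD depth < 40×; combined
depth of the pair outside [100×, 400×]; per-pool genotype quality < 99;
reference-allele frequency < 0.2. The last guards against
collapsed paralogs when one parent is a homozygous reference line.
Depth means `ref + alt` from the AD field, not DP, so the filters see
exactly the counts the statistics use. The reference-frequency rule is
computed on the summed depths of the two pools by default (the pairing
the combined-depth rule uses); a stricter per-pool mode is available,
as is a per-pool reading of GQ (always per-pool, since GQ is a
per-sample annotation). Multi-allelic records are kept only when one
alternate carries ≥ 95% of the alternate depth over the requested pools;
the rest are dropped and counted. Indels pass through tagged by type —
the BSA statistics use SNPs only, but the effect classifier uses both.

## Variant effects

`classify_effect()` is a compact, strand- and phase-aware
coding-sequence classifier: SNPs in the CDS are translated codon-wise
(standard nuclear code) and labelled synonymous / non-synonymous /
stop_gained / stop_lost, with `start_lost` for any change destroying an
ATG initial codon (only ATG is recognized as a start). Length-changing
variants in the CDS are frameshift when the length difference is not a
multiple of 3, else in-frame. Variants within 2 bp of a CDS/intron
junction on the intron side are splice_site (the canonical GT/AG core);
within the gene span but outside the CDS, intronic; otherwise
intergenic. Multi-nucleotide substitutions are handled codon-wise only
when contained in one codon and conservatively called non-synonymous
(with a note) otherwise. One transcript represents each gene — the
longest CDS — since the downstream gene lists are gene-level. The
impact mapping is fixed: start_lost/stop_gained/frameshift/splice_site
are high; non_synonymous/inframe_indel/stop_lost moderate; synonymous
low; intronic/intergenic modifier.

The test suite holds this classifier against an independent oracle that
mutates the genome, re-extracts and translates the entire CDS, and
diffs the proteins — across fuzzed multi-exon genes on both strands and
all codon phases.

## The ontology cascade

The OBO parser keeps `is_a` edges always and `part_of` behind a flag;
the default is_a-only reading is the conservative interpretation of
"subtended by" as pure subsumption. The graph must be acyclic (checked
with a topological sort) and complete (dangling edge endpoints are
fatal). Descendants of an anchor are all terms from which the anchor is
reachable child→parent, anchor included.

Enrichment is one-sided over-representation only: for each term
annotating $k \ge 1$ study genes, the upper hypergeometric tail
$P(X \ge k)$ given universe size $N$, term size $K$ and study size $n$,
corrected with Benjamini–Yekutieli (valid under the arbitrary positive
dependence of nested GO terms; BH is available as an option and the
correction used is recorded on the result). Annotations are propagated
under the true-path rule before testing. The universe defaults to all
genes in the annotation table — the pragmatic choice when no curated
reference list is available — and is user-overridable.

The cascade in `run_refine()` is: per contrast, the study set is the
genes overlapping that contrast's QTL regions that carry at least one
non-synonymous SNP; SEA per contrast; a term-by-contrast FDR matrix
with shared/unique counts; pruning of each contrast's enriched set to
the subgraph under the anchor (default `GO:0003006`); genes transitively
annotated to the focus term (default `GO:0010228`) intersected with the
study genes; and finally pathway over-representation of that gene set
against a GMT collection. The anchor and focus are parameters so the
same machinery transfers to other traits.

## The synthetic-data generator

`simulate_cross()` emulates the experimental design rather than sequencing
mechanics: a heterozygous × DH cross where each marker allele segregates
1:1, individuals inherit haplotypes along each chromosome by a Markov
walk with Haldane-map switch probabilities, the trait is
`effect × causal dosage + N(0, noise_sd)`, and individuals are ranked
and binned into trait-ordered pools. Read data are Poisson depths and
binomial allele counts; GQ is written as 99 (a configurable miscall
rate ε perturbs allele draws). Defaults mirror the motivating
experimental design:
four pools of 11/8/11/9 individuals, ~110× mean depth, effect/noise
ratio 2, 500 markers over a 10 Mb two-chromosome toy genome with the
causal locus at C1:3,000,000.

Two scale choices deserve a note. First, the toy chromosomes compress
whole chromosomes into a few Mb, so the genetic map is compressed with
them: the default 0.25 Morgans/Mb makes the 6 Mb toy chromosome ≈ 150 cM,
a realistic chromosome map length; at a literal per-Mb rate the whole
toy chromosome would be one ~24 cM linkage block and "the" locus would
be everywhere. Second, an optional right-censoring threshold bins all
individuals above it into the last pool, emulating a final pool that
mixes very-late and never-scored phenotypes; it is off by default.

`generate_fixtures()` adds the annotation side with recorded ground
truth: a genome FASTA; ≥ 20 multi-exon gene models on both strands, a
block inside the planted QTL and the rest elsewhere; planted
non-synonymous SNPs in every QTL gene and one stop-gain far outside (so
the impact-by-location cross-tab has a known expected pattern:
moderate inside, high outside); a ≥ 30-term toy ontology whose
reproduction branch nests the focus under the anchor; direct
annotations over a 200-gene universe; and a GMT collection with one
circadian-like pathway enriched among the focus genes by construction.
A JSON manifest records every truth.

What the generator does **not** emulate: read-level errors and mapping
artifacts, multi-allelic sites, segregation distortion, polygenic
backgrounds, LD structure beyond the single Markov map, or realistic GO
topology and annotation bias. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the stated model,
not performance on real sequencing data.

## Numerical and design notes

- Problem sizes in the test suite: ~500 markers × 39 individuals per
  simulated cross; 20 seeds for the stochastic recovery and
  false-positive suites; 10,000 replicates for each Δ-CI table;
  a 100-gene fuzz for the effect classifier; exhaustive hypergeometric
  enumeration up to N = 12.
- All stochastic functions take explicit seeds; the simulator restores
  the caller's RNG state, and a fixed seed reproduces the VCF
  byte-for-byte and a pipeline run checksum-for-checksum.
- G is clamped at 0 against roundoff; tied p-values receive identical
  adjusted values; empirical CI quantiles use the type-7 estimator.
- Known limitations: no depletion tests; no UTR/regulatory effect
  classes; one transcript per gene; the pathway stage substitutes
  BY/BH for the proprietary multiple-testing scheme of the web tool
  that inspired it, so adjusted pathway p-values are not comparable to
  that tool's output.
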