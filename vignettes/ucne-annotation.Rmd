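---
title: "Annotating ultraconserved non-coding elements as candidate cis-regulatory elements"
author: "ucre package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating ultraconserved non-coding elements as candidate cis-regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ucre))
```

## The problem

Ultraconserved non-coding elements (UCNEs) are genomic regions longer than
200 bp with at least 95% sequence identity between distant vertebrates
(human--chicken). Many act as tissue-specific enhancers of developmental
genes, and rare variants inside them are candidate drivers of Mendelian
disease that routine exome-centric analysis misses. `ucre` implements, as a
reusable and fully tested pipeline, the annotation of UCNEs as candidate
cis-regulatory elements (cCREs) in a tissue, the assignment of their target
genes, the prioritization of rare non-coding variants within them, and the
statistical comparison of their variation and constraint profile against a
random genomic background.

The pipeline has four stages:

1. **Annotation.** UCNEs are intersected with open-chromatin evidence —
   DNase peak sets per developmental stage and single-cell accessibility
   signal per cell cluster, peak-called at cutoff 0.4 — and, within a
   ±250 bp window, with histone-mark signal peak-called at cutoff 20. An
   element overlapping accessibility evidence from either source is
   *putatively active*; support from both sources defines a high-confidence
   subset. Evidence tiers are ordered
   `none < open_only < marked < active_enhancer < sustained_adult`, where
   `active_enhancer` requires H3K27ac at a developmental stage and
   `sustained_adult` additionally requires it at adult stage.
2. **Target assignment.** Each gene owns a basal regulatory domain (5 kb
   upstream, 1 kb downstream of its TSS, strand-aware) extended on each side
   up to 1 Mb or to the nearest other gene's basal domain, whichever is
   closer. An active element is assigned to every gene whose extended domain
   it overlaps. Targets are filtered by retinal expression (TPM ≥ 0.5 in at
   least one stage; 0.5 exactly counts as expressed because non-expression
   is defined strictly as TPM < 0.5), checked for TAD co-containment of
   element and TSS, and compared for cell-type concordance: the clusters in
   which the element is open must intersect the union of its targets'
   expression signatures (clusters strictly above the gene's own 80th
   expression percentile). Domain-derived targets are also compared against
   correlation-based peak-to-gene linkages kept strictly above 0.4.
3. **Variant prioritization.** Cohort variants are binned by reference
   population frequency — ultrarare (absent from the reference database),
   very rare (MAF < 0.1%), rare (0.1–0.5%), low-frequency (0.5–5%), common
   (≥ 5%) — and filtered to MAF < 0.5% with no observed homozygotes. Variants
   overlapping (≥ 1 bp, including structural-variant spans) active UCNEs are
   annotated with element state and target genes; the *search space* keeps
   hits on histone-marked elements whose targets include a disease gene.
4. **Constraint statistics.** Per-base constraint scores (lower = more
   intolerant) over the elements, their 200 bp flanks and a background of
   200 random 350 bp fragments are compared with a Kruskal–Wallis test and
   Dunn's post-hoc pairwise z tests under Bonferroni correction; allele
   frequency spectra are contrasted between elements and background.

## Statistical machinery

Kruskal–Wallis uses mid-ranks with the tie correction
$H_c = H / (1 - \sum(t^3 - t)/(N^3 - N))$ and a $\chi^2_{k-1}$ reference;
Dunn's statistic is
$z_{ij} = (\bar R_i - \bar R_j) \big/ \sqrt{\left(\tfrac{N(N+1)}{12} -
\tfrac{\sum(t^3-t)}{12(N-1)}\right)\left(\tfrac{1}{n_i}+\tfrac{1}{n_j}\right)}$
with two-sided normal p-values multiplied by the number of pairs (capped at
1). Both are implemented in the package and verified in the tests against a
definitional brute-force rank computation, against `stats::kruskal.test`,
and by Monte-Carlo calibration of the type-I error. Constraint samples are
per-base by default (a region contributes its length in observations,
matching a nucleotide-resolution score); a per-region-mean mode exists for
sensitivity analysis since the sampling unit is a modelling choice.

## Coordinate conventions

All files use 0-based half-open (BED) coordinates; VCF positions are
converted on read (`pos - 1`). In memory the package uses `GRanges`
(1-based closed), the Bioconductor convention, and all readers/writers
convert at the file boundary, so a BED line `chr1 10 20` is the ten bases
`[10, 20)`. Overlap means "at least one shared base" everywhere; half-open
abutment is never an overlap. TSS distances use half-open boundary
arithmetic (an element `[100, 200)` is 60 bp from position 260), writers
emit chromosome-then-start sorted output, and sorting ties are broken by
name so artifacts are diffable.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| accessibility cutoff | 0.4 | signal | peak calling on single-cell tracks |
| mark cutoff | 20 | signal | peak calling on histone-mark tracks |
| peak min length / max gap | 200 / 30 | bp | narrow-peak caller defaults |
| ChIP window | 250 | bp | symmetric mark-overlap window |
| basal domain | 5000 / 1000 | bp | upstream / downstream of the TSS |
| max extension | 1 Mb | bp | regulatory-domain reach |
| expression threshold | 0.5 | TPM | ≥ threshold in ≥ 1 stage = expressed |
| signature percentile | 80 | % | per-gene, strictly above |
| linkage correlation | 0.4 | – | strictly above |
| rare-variant MAF | 0.5% | – | with zero reference homozygotes |
| background | 200 × 350 | bp | random fragments |
| constraint flank | 200 | bp | up- and downstream of each element |

The peak caller's minimum length and gap are not fixed by the cutoff-calling
description; 200 bp and 30 bp are the defaults of the narrow-peak tool
family and are exposed as parameters.

## The synthetic cohort

Real inputs of this kind are protected cohort data and large consortium
datasets, so the package ships a generator (`simulateBundle()`) that
emulates their statistical structure with a planted truth table: elements
placed intergenically, of which 34% are planted open (19% carrying marks,
2.6% the active-enhancer mark, 0.76% sustaining it at adult stage — the
observed proportions of the element catalogue); expressed target genes
(planted TPM high in 1–3 stages) inside randomly tiled TADs; single-cell
signatures realized exactly in the cluster matrix; common-variant rate
multiplied by a depletion factor d (default 0.2) inside elements; and
standard-normal constraint scores shifted by −δ inside elements and −δ/2 in
flanks (default δ = 0.5). The default genome is two 2.5 Mb chromosomes with
60 genes and 150 elements — small enough that oracle checks and 100-run
calibration loops are cheap, large enough that the common-bin density ratio
and the rank tests have tight sampling error.

Choices worth noting:

* **Depletion readout.** With the depletion applied to the common-bin
  *rate*, the quantity that estimates d directly is the per-bp density
  ratio (elements / background) in that bin, not the ratio of the
  renormalized spectrum proportions; `afSpectrum()` emits both views.
* **TAD sharing** is not forced to a quota: TADs tile each chromosome with
  exponential sizes and the truth table records the realized co-containment
  flag per edge, which is what end-to-end recovery compares.
* **Signatures** are planted with 1–2 high clusters per gene on an
  otherwise-zero row, so the 80th-percentile rule recovers them exactly;
  real expression matrices are noisier and signatures correspondingly less
  crisp.
* **Substreams.** The master seed fans out to per-component seeded streams,
  so `simulateBundle(cfg, components = "constraint")` regenerates exactly
  the constraint material of the full bundle — used by the calibration
  loops.
* Every RNG draw flows from the single seed; two runs with the same seed
  and configuration produce byte-identical bundles and reports.

What passing on this cohort does **not** show: robustness to misassigned
cell clusters, batch effects between accessibility sources, expression
noise near the TPM threshold, or incomplete constraint-track coverage
beyond the missing-base accounting that `scoreValues()` performs.

## Numerical and degenerate-input choices

* The ultraconservation scanner counts gap columns (either row) as
  mismatches, requires windows to start and end on reference-base columns,
  and reports, among overlapping qualifying windows, the longest (leftmost
  on ties) — so no reported interval can be extended without dropping below
  the identity threshold. ">200 bp" is read strictly as ≥ 201 bp.
* A constant expression row yields an empty signature (nothing is strictly
  above its own percentile); an all-zero gene likewise, without error.
* A label set overlapping no validated-enhancer element reports 0/0 with an
  explicit `defined = FALSE` flag rather than NaN.
* Frequency-unknown variants (no AF and no absence flag) are carried as
  flagged records and raise an error at classification time; absence from
  the reference database is a distinct state (`observed = FALSE` with
  AF = 0), because the ultrarare bin means absence, not zero frequency.
* `sampleFragments()` rejection-samples against the exclusion set and
  reports the achieved count if placement fails; fragments may overlap each
  other, as in genome-wide uniform sampling.
* All-identical rank inputs give H = 0, p = 1; Bonferroni p-values never
  drop below the raw p nor exceed 1.

## Worked example

`workedExampleBundle()` builds a fixed 100 kb chromosome with three genes
and five elements in which every stage is hand-checkable; its pipeline
outputs are committed under `inst/extdata/worked-example/` and the test
suite requires byte-identical reproduction.

```{r}
report <- runPipeline(workedExampleBundle())
report
```

## Known limitations

The generator does not simulate reads, sequence composition, or doublet- and
integration-related artifacts of single-cell processing (those are upstream
of this pipeline's inputs, which are peak sets, matrices and tracks). The
enhancer-state ladder assigns `marked` to an element with histone marks even
if it lacks accessibility evidence; the search space additionally requires
activity, so prioritized variants always sit on open, marked elements.
Curated regulatory domains are supported as a generic override table rather
than hard-coded locus coordinates. Validated-enhancer tissue distributions
are reported both per element and per element–tissue mention, since the
proportional view can be defined either way.
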