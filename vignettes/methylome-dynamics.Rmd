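---
title: "Tile-based WGBS methylome dynamics during the endothelial-to-haematopoietic transition"
author: "ehtmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based WGBS methylome dynamics during EHT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

Haematopoietic stem and progenitor cells (HSPCs) arise from hemogenic
endothelial cells (HECs), themselves specified from endothelial cells
(ECs), in the endothelial-to-haematopoietic transition (EHT). This package
implements a whole-genome bisulfite sequencing (WGBS) workflow for asking
how DNA methylation changes across those three populations, how it is
disrupted when the maintenance methyltransferase *dnmt1* is lost, and which
genes look transcriptionally controlled by promoter methylation. The design
is 3 cell types x 2 genotypes (wild-type sibling, *dnmt1* mutant) x 3
replicates.

The stages are:

1. **Tiling.** Each chromosome is cut into consecutive 500 bp tiles (the
   final partial tile is kept; dropping it would silently discard
   chromosome ends). A tile's methylation level in a sample is the pooled
   count ratio `sum(methylated reads) / sum(total reads)` over its CpGs --
   pooling counts, not averaging per-CpG levels, so deeply covered CpGs
   weigh more. The genome-wide 5mC level of a sample is the *unweighted
   mean* of its non-missing tile levels.
2. **CpG categories.** Covered CpGs are classified by level as high
   (> 0.8), intermediate (>= 0.2 and < 0.8), low (> 0 and < 0.2) or
   unmethylated (= 0). The boundary 0.8 falls in neither quoted open
   interval and is assigned to intermediate (the half-open convention is
   applied consistently and logged here once).
3. **DMR calling.** For a two-group comparison, counts are first re-pooled
   per tile using only CpG sites covered (total > 0) in *every* sample of
   both groups -- the shared-CpG recovery rule -- and tiles with fewer than
   `min_shared_cpg` (default 3) such sites are left untested. Each tested
   tile gets an unpaired two-tailed equal-variance Student's t-test on the
   per-replicate tile levels (n = 3 per group), and p-values are
   Benjamini-Hochberg adjusted over all tested tiles. A tile is a DMR when
   `|mean difference| > 0.2` **and** `adjusted p < 0.05`, both strict. The
   test runs on replicate-level tile values, not CpG-level counts, because
   the replicate is the experimental unit. Degenerate tiles are resolved
   explicitly: both groups zero-variance with equal means gives p = 1,
   with unequal means p = 0.
4. **Six-pattern clustering.** DMRs from the two consecutive comparisons
   (EC vs HEC, HEC vs HSPC) are pooled; each DMR's (EC, HEC, HSPC) profile
   of sibling mean levels is min-max normalized and assigned to the nearest
   of six canonical centroids: gradual gain towards HSPC (C1),
   HSPC-specific hyper (C2), HEC-specific hypo (C3), HEC-specific hyper
   (C4), EC-specific hypo (C5) and HSPC-specific hypo (C6). Ties resolve to
   the first nearest centroid. A seeded k-means backend (k = 6 on z-scored
   profiles, clusters relabelled by their mean profile's nearest canonical
   centroid) is provided for sensitivity analysis; the rule-based
   assignment is the default because it is deterministic and directly
   interpretable.
5. **Annotation and enrichment.** Promoters are TSS - 1 kb to TSS + 1 kb,
   strand-aware and clipped at chromosome bounds; gene bodies run TSS to
   TES; introns are gene bodies minus exons. A DMR overlapping >= 1 bp of
   a feature is assignable to it, and one label is chosen by the fixed
   precedence promoter > exon > intron > intergenic. Enrichment of a DMR
   set in a feature is a one-sided Fisher exact test on the 2x2
   overlap table against the universe of *tested* tiles (conditioning on
   testability avoids coverage bias), BH-adjusted across feature sets.
6. **Expression.** Counts are normalized by median-of-ratios size factors.
   The differential-expression screen is deliberately transparent: log2
   fold change from pseudocount-1 group means, two-sample t on
   log2(normalized + 1), BH adjustment, and the conjunctive rule
   `adjusted p < 0.05 & |log2FC| >= 1`. It is a substitute for a negative
   binomial engine, chosen so every number in the screen is reproducible
   by hand; shrinkage estimators are out of scope.
7. **Integration.** For each gene, promoter methylation (pooled counts over
   the promoter window) and log2 expression are correlated (Pearson) across
   the nine samples of each genotype separately. A gene is selected as
   candidate methylation-regulated when `r < -0.3` in siblings but not in
   mutants -- the mutant acts as the specificity control: a gene whose
   anticorrelation reflects shared developmental regulation rather than
   methylation keeps a similar correlation in the mutant and is rejected.
   Genes whose sibling promoter methylation is near-constant
   (sd < `min_meth_sd`, default 0.04) are excluded as uninformative before
   the screen: with nine samples the null distribution of r has standard
   deviation ~0.35, so correlations of flat methylation profiles are
   noise and would otherwise pass the -0.3 cut for ~1 gene in 5. This is
   the same independent-filtering logic used before differential tests.
   The stage filter then keeps genes whose mean promoter methylation rises
   while mean expression falls across a transition (EC to HEC, or HEC to
   HSPC) in siblings and not both in mutants.
8. **Clone bisulfite summaries.** For locus validation, a clones x CpG
   binary matrix is summarised as
   `100 * methylated calls / all non-missing calls`, with missing calls
   excluded from numerator and denominator, plus a per-CpG methylated
   fraction for lollipop-style display.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `tile_size` | 500 | bp | analysis unit of the methylome |
| `diff_threshold` | 0.2 | methylation fraction | DMR effect-size filter (strict >) |
| `alpha` | 0.05 | probability | DMR BH-adjusted p cut (strict <) |
| `min_shared_cpg` | 3 | CpGs | minimum shared covered sites per tested tile |
| `promoter_up`, `promoter_down` | 1000, 1000 | bp | promoter window around the TSS |
| `deg_alpha`, `lfc_threshold` | 0.05, 1 | probability, log2 | DEG screen |
| `corr_threshold` | -0.3 | Pearson r | integration screen |
| `min_meth_sd` | 0.04 | methylation fraction | informativeness filter before correlation |

`deg_alpha` is configurable because the looser cut 0.5 appears in some
published screens; 0.05 is the conventional default used here.

## What the generator emulates

The synthetic-data module (`sim_config()`, `simulate_study()`) is
first-class, tested code: it defines the study conditions under which the
whole workflow is validated, and writes bismark-style CpG cytosine
reports, a GTF, a counts table, a sample sheet and ground-truth sidecar
files (the data files themselves carry no truth).

Structure of the latent methylome, per 500 bp tile:

* a **per-tile base level**, beta-distributed around `baseline_meth_mean`
  (0.8 -- vertebrate genomes are globally highly methylated) with
  concentration 30 (sd ~0.07);
* **regional cell-type variation**: each gene's promoter domain gets one
  per-cell-type wobble draw, built as a per-gene monotone trend along
  EC -> HEC -> HSPC (sd `celltype_meth_sd` = 0.08) plus a smaller
  non-monotone deviation (sd 0.02). Methylation varies regionally -- a
  promoter's tiles move together -- so the wobble is coherent across a
  promoter's tiles, and where promoter domains overlap the tile follows
  the promoter whose TSS is nearest. Variation along a differentiation
  axis is modelled as predominantly monotone, with smaller non-monotone
  deviations. Crucially this variation is *shared between genotypes*: it
  is real cell-type biology, not a methylation-regulation signal, and it
  is exactly what the sibling-vs-mutant correlation screen must reject.
* **planted DMR tiles**: `n_planted_dmrs_per_pattern` (40) tiles per
  canonical pattern, shifted by `dmr_delta` (0.4; the threshold is 0.2, so
  planted effects are twice the cut) from a mid-range base level so both
  directions stay inside (0, 1). The gradual pattern's intermediate step
  is `dmr_delta / 2`, which sits exactly at the calling threshold for the
  first transition -- such tiles are genuine borderline cases and are
  treated as planted differences, not false positives, when scoring
  recovery;
* **coupled promoters**: 200 genes (100 per transition) whose promoter
  tiles start low (0.3-0.4) and gain `dmr_delta` at their transition in
  siblings. In mutants the gain fails and the region instead loses
  `mutant_dynamic_loss` (0.15) -- failed de novo establishment plus
  passive loss at regions under active turnover;
* a **genotype-wide mutant shift**: `mutant_hypomethylation_shift` (0.15)
  subtracted everywhere in the mutant, floored at 0. Together with the
  dynamic-region losses this reproduces the qualitative picture of a
  globally hypomethylated mutant whose later stages lose the most.

Counts: per replicate, the tile level gets beta noise of sd
`replicate_noise_sd` (0.03); per CpG, a beta draw with concentration
`cpg_jitter_concentration` (100) around the replicate level; read totals
are Poisson(`coverage_mean` = 30) split over the two strands of the CpG
dyad, and methylated counts are binomial. Stranded counts exercise the
dyad-merging reader.

Expression: gene baselines are log-normal (median 300 counts); uncoupled
genes carry per-cell-type expression effects with the same
trend-plus-deviation structure (sd `celltype_expr_sd` = 0.7 natural log),
shared between genotypes. Coupled genes' sibling log-mean expression is
`baseline + dev + coupling_slope x promoter methylation` with
`coupling_slope` = -3 (so a 0.4 methylation gain silences ~3.3-fold) and a
methylation-independent developmental downregulation `dev` (-0.5 natural
log across the transition) present in both genotypes; in mutants the
coupling term is absent. Counts are negative binomial (dispersion 0.02,
typical of bulk RNA-seq of sorted populations) with log-normal library
size factors (sd 0.15) that the normalization must undo.

Ground truth written alongside: planted tile patterns, the full per-group
latent tile levels, coupled gene labels, and per-group true mean levels
(the mean of the latent tile levels, which is what the tile-mean estimator
targets).

### What it does not emulate

Reads (FASTQ), bisulfite conversion failure, SNP-overlapping CpGs,
non-CpG methylation, CpG islands and repeat classes, chromatin context,
and genes *down*-regulated in the mutant through indirect effects (the
mutant DEG screen therefore finds only derepressed, i.e. upregulated,
genes in synthetic data). Passing tests show the statistics and plumbing
are correct under a realistic noise model; they do not certify behaviour
on real genomes, where methylation is bimodal per CpG-island status and
effect sizes are not planted.

## Numerical conventions

* Coordinates are 0-based half-open everywhere internally; BED on disk;
  1-based only at the cytosine-report and GTF boundaries. CpG dyads are
  merged onto the plus-strand C by summing counts.
* Zero-coverage CpGs are kept in memory but contribute nothing to pooled
  statistics.
* Latent simulation levels are clamped to [0.001, 0.999] before beta/
  binomial sampling.
* `assign_six_clusters()` on a profile with zero range or a missing level
  returns an unassigned record rather than guessing.
* Fisher odds ratios are the sample (cross-product) ratios with explicit
  guards: 0 when the query has no overlap, infinite when only the
  background lacks overlap, undefined when the feature covers the whole
  universe (p = 1 there).
* A single integer seed drives every stochastic stage; generator
  sub-stages derive fixed offsets (+1, +2) from it, and repeated runs are
  byte-identical.

## Problem sizes

Tests and the reproduction script use a reference synthetic scale chosen
to exercise every stage at meaningful granularity while staying quick on a
laptop: 2 chromosomes x 1 Mb, ~100 bp CpG spacing (~20,000 CpGs), 4,000
tiles, 18 samples, 2,000 genes of which 200 are methylation-coupled. At
this scale the full simulate-to-integration run takes well under a minute.

## Known limitations

* The equal-variance t with n = 3 per group is the study's stated test; it
  is anticonservative under strong variance heterogeneity. Beta-binomial
  dispersion modelling (DSS/methylKit-style) is deliberately out of scope.
* The -0.3 correlation screen at n = 9 is a coarse instrument; its value
  comes from the genotype contrast, not the threshold. The
  `min_meth_sd` filter is essential: without it, flat-methylation genes
  pass at the null rate of the correlation estimator.
* Single-label DMR annotation depends on the stated precedence order;
  distributions are reported, per-feature multi-labels are not.
* Adjacent significant tiles are not merged into longer DMRs, so DMR
  counts are tile counts.
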