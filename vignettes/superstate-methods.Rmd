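---
title: "Chromatin classes, transcriptional states and the superstate model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin classes, transcriptional states and the superstate model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superstate)
```

## The question this package addresses

Single-cell multiome assays measure chromatin accessibility (ATAC) and gene
expression (RNA) in the same cells. A recurring observation in such data is
an asymmetry of resolution: clustering cells on accessibility yields fewer,
broader populations ("chromatin classes") than clustering on expression
("transcriptional cell states"). When several transcriptional states share
one accessibility profile, that chromatin class acts as a *superstate*: a
chromatin-level program within which transcription picks out finer
functional states. This package implements the statistical machinery needed
to establish, quantify and probe that relationship, together with a seeded
generative model that emulates it.

The pipeline covers, in order: barcode-aware read deduplication,
summit-centered fixed-width peak consolidation, fragment counting, cell and
feature quality control, TF-IDF/LSI chromatin clustering with a
batch-adjustment contract, cross-modal k-nearest-neighbor label transfer,
the class-by-state Fisher odds-ratio matrix, pairwise linear-discriminant
AUC of state separability in chromatin space, single-cell logistic and
pseudobulk negative-binomial likelihood-ratio tests, signed per-cell
accessibility scores, hypergeometric motif enrichment, and fine-mapped
variant prioritization.

## The generative model behind the synthetic data

`generate_multiome()` draws a multi-sample dataset under an explicit
superstate model. Its defaults are the package's study conditions and are
chosen once, not tuned per analysis:

* **Cells.** `n_samples = 3` samples of `cells_per_sample = 1000` cells;
  each cell gets a chromatin class (3 classes), a transcriptional state
  nested in that class (`states_per_class = c(2, 2, 1)`, five states), and a
  ternary CD4/CD8 lineage code (45% / 45% / 10%). Class, state and lineage
  are drawn independently of sample.
* **Depth.** Per-cell fragment depth is lognormal
  (`depth_mu = log(800)`, `depth_sigma = 0.35`), emulating the several-fold
  depth variation of real libraries at a size that keeps a 3,000-cell
  simulation tractable on one CPU.
* **Openness.** Peak openness is defined on the logit scale. Background
  peaks sit at `p_open_low = 0.03`; 15% of peaks are class-specific and rise
  to `p_open_high = 0.45` in their class only. All states of a class share
  the same openness profile — this is the superstate assumption, and it is
  what the odds-ratio and discriminability analyses later recover.
  A per-(sample, peak) Gaussian logit shift (`batch_sigma = 0.25`) emulates
  sample-level technical variation of the kind mixture-model harmonization
  corrects in real data.
* **Counts on a simplex.** ATAC counts are Poisson with mean
  `depth_i * pi_ij / D_i`, where `D_i` is the cell's *lineage-neutral*
  openness sum (class and batch terms only). Normalizing by a per-cell sum
  decouples depth from composition, which is what makes depth-confounding
  tests meaningful. The denominator deliberately excludes the lineage
  perturbation: if the cell's own total were used, opening the twenty
  lineage-coupled peaks would depress every other peak's relative coverage,
  so *every* peak would carry a (small, compositional) lineage signal and
  the generator's ground truth — that only the planted peaks are
  lineage-coupled — would be false. With the neutral denominator,
  non-planted peaks are conditionally independent of lineage given class
  and sample, which is the null the planted-effect evaluations assume.
* **Lineage.** Two dedicated promoter peaks ("CD4", "CD8A") are open at
  `p_open_high` in the matching lineage and essentially closed
  (`lineage_closed_p = 1e-4`) otherwise, so the accessibility-derived
  ternary code agrees with the simulated truth in ~99.6% of cells; the
  disagreement is pure sampling noise. Twenty further promoter peaks carry
  a `lineage_effect = 1.5` logit shift with a random sign (positive =
  CD4-associated), about 1% of peaks — the same order as the sparse
  lineage coupling reported for T-cell promoter repertoires.
* **Expression.** Gene counts are negative binomial
  (`nb_dispersion = 2`) around lognormal library sizes; each state owns
  `markers_per_state = 20` marker genes whose means are multiplied by
  `expr_fc = 4` in that state's cells. Expression is therefore the only
  channel that distinguishes states within a class.
* **Fixtures.** The generator also emits overlapping sub-peak candidates
  (for consolidation), motif annotations (one motif per class planted at
  0.8 frequency in its class-specific peaks versus 0.1 background), SNPs
  (half inside class-specific peaks, PIP ~ Beta(0.5, 2)), signed peak sets,
  and — when `with_reads = TRUE` — fragment and read tables with
  within-cell PCR duplicates (`k ~ Geometric(dup_rate)`).

What the generator does **not** emulate: genome sequence, fragment-length
periodicity, doublets, TSS enrichment structure, protein channels, and
per-peak GC or accessibility biases. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under a
faithful superstate model — not robustness to every artifact of real
chromatin data.

## Read, peak and cell processing

Reads are deduplicated within cells: one record is kept per (barcode,
chromosome, start, mate start, CIGAR) group when mate information exists,
else per start position; identical coordinates in different cells are
deliberately kept. Records with MAPQ < 60, a missing barcode, or a
blacklist overlap are dropped, with per-filter counts reported.

Sub-peaks are trimmed to summit ± 100 bp and de-overlapped greedily in
ascending q order (ties broken by chromosome and start for determinism), so
the output is a sorted, non-overlapping, width-200 peak set; re-running
consolidation on its own output is the identity. Summits within 100 bp of a
contig start clip to [0, 200) with a warning rather than being dropped.
All coordinates are 0-based half-open (BED convention) and overlap means at
least one shared base pair.

Cell QC reads its thresholds literally: *more than* 10,000 reads (strict),
*at least* 50% of reads in 5x peak neighborhoods and 10% in promoters
(inclusive), *not more than* 10% mitochondrial or blacklisted reads
(inclusive); RNA cells need at least 500 genes and strictly under 20%
mitochondrial reads. Feature selection inside a cell type keeps "peaks with
minimal accessibility" (PMA): a fragment in at least 0.5% of that type's
cells, or an absolute `min_cells` override for rare types.

## Clustering and the resolution choice

The chromatin chain is: binarize, PMA filter, `log(1 + 1e4 * TF * IDF)`
(the dialect is recorded in the output's metadata so alternatives can be
compared), variance-stabilized feature selection, per-feature scaling, PCA
(10 components for fine-grain work, 20 for broad typing), batch adjustment,
then a shared-nearest-neighbor graph (k = 20, Jaccard weights pruned below
1/15) under Louvain modularity. Labels are renumbered by descending cluster
size with the largest cluster named 0.

Batch adjustment is a *contract*, not an algorithm: after adjustment every
sample's mean must equal the global mean in each component. The default
method is per-sample centering — an intentionally simple stand-in — and an
externally harmonized embedding can be injected unchanged, which is how
real-data users would supply a mixture-model-corrected embedding.

The fine-grain pipeline defaults to Louvain resolution 0.1. This is the
package's analog of choosing the resolution at which known marker peaks
respect cluster boundaries: the generator's lineage coupling is genuine
within-class substructure, and at resolutions of 0.3 and above Louvain
resolves class-by-lineage subclusters rather than classes. Resolution is a
per-dataset calibration parameter targeting the class level of granularity;
`snn_louvain()` itself keeps a generic default of 0.8.

## Label transfer and the superstate statistics

`knn_classify()` assumes both modalities are embedded in one coordinate
space (the synthetic data provides this directly; for real data the shared
embedding is an input, not computed here). Each query cell takes the most
common label of its five nearest reference neighbors; ties go to the
nearest neighbor's label; at least 3 of 5 agreeing votes marks a
high-confidence mapping. The direction is reversible, so states can be
pushed onto multiome cells or classes onto reference cells.

The superstate test builds, per (class, state) pair, the 2x2 table of cells
in/out of the class and state. `fisher_exact_or()` computes the exact
two-sided p (minimum-likelihood rule) and the *conditional maximum
likelihood* odds ratio by solving the noncentral hypergeometric mean
equation with a tight root tolerance — implemented in the package because
the stock implementation's root solver stops at ~1e-4 relative precision,
which is too loose to verify against an independent enumeration; the stock
routine remains as a cross-check in the test suite. States with 10 or fewer
cells are excluded; BH FDR is applied across computed pairs; for display
the natural-log OR of an infinite estimate is capped at plus-or-minus one
plus the ceiling of the largest finite |log OR| in the table.

Discriminability is measured by pairwise LDA: for each pair of states with
at least 50 cells each, a two-class LDA of the 10 chromatin hPCs plus
one-hot sample and scaled log10 fragment-count covariates is trained on a
stratified 75% of cells and scored by held-out AUC. Constant design columns
are dropped; if the fit degenerates a small ridge (1e-6 of the mean pooled
variance) is tried before the pair is marked skipped. Stratification of the
split is imposed for stability. Under the superstate model the mean
within-class AUC sits near chance while across-class pairs are nearly
perfectly separable; the package reports both means.

## Differential testing

Three testing families are provided, all using BH FDR within the scope of
each analysis:

* **Single-cell logistic LRT** for lineage
  (`peak ~ lineage + class + sample + scale(log10 nFragments)` vs the
  lineage-free null, df = 1, selection at FDR < 0.20, positive beta =
  CD4-associated) and class one-vs-rest (same structure, class indicator
  tested). The sample term defaults to fixed-effect one-hot dummies —
  deterministic, fast, and present in both models so the tested df is
  unchanged — with an lme4 random intercept available via
  `sample_effect = "random"`. Uniformly open or closed peaks are excluded
  before fitting; non-converged (separated) fits are flagged and excluded
  from the FDR. The class beta is reported raw (natural log-odds), matching
  the labelling convention of the display tables.
* **Pseudobulk negative-binomial LRT.** Counts are summed over
  (sample, state) combinations; combinations are kept when the sample has
  more than 150 cells, the state more than 130, and the combination more
  than 10 (all strict); peaks need at least 5 reads across the retained
  pseudobulks; calls are made at FDR < 0.10. At these sizes (about a dozen
  observations against sample + state + depth parameters) a per-peak
  dispersion MLE collapses toward Poisson and the chi-square LRT rejects
  severalfold too often, while a per-peak deviance-F reference is
  calibrated but powerless at ~4 residual degrees of freedom. The default
  therefore estimates one common dispersion across all tested peaks
  (Cox-Reid adjusted profile likelihood) and shares it between the nested
  fits, restoring both calibration (null rejection ~5% at alpha = 0.05) and
  power; `dispersion = "per_peak"` retains the unmoderated variant for
  designs with many pseudobulks.
* **Rank-sum markers.** Per feature and group (one-vs-rest): tie-corrected
  two-sided Wilcoxon p (exact for small untied groups), AUC = U/(n1 n2),
  and logFC as the difference of group means of log-normalized values.
  Marker-derived signed sets use the standard gene cutoffs
  (FDR < 0.1, logFC > 0.25, AUC > 0.6) and peak cutoffs
  (FDR < 0.1, logFC > 0.1, AUC > 0.58).

Promoter/gene concordance pairs each retained gene (detected in more than
50 of the pair's cells) with one promoter peak — the candidate with the
maximum summed normalized accessibility — and re-applies FDR separately
within modalities over the retained pairs. Under superstate generation the
expected pattern is strong: state markers separate in expression while
their promoter peaks do not.

## Scores, enrichment and variants

A signed score is the mean normalized value over a positive feature set
minus the mean over a negative set; it is linear in the matrix and its
group shifts are tested by rank-sum with a chosen alternative. Motif
enrichment is an upper-tail hypergeometric test of motif counts in
class-specific peaks against the background universe, BH-adjusted within
class; display selection requires an enrichment value (-log10 adjusted p)
of at least 5, within 95% of the class maximum, and minimally expressed TFs
(mean normalized expression at least 0.05), with per-motif scaling to the
percentage of the cross-class maximum. SNPs with PIP strictly above 0.1
are joined to containing peaks; per-peak class means of normalized
accessibility are z-scored across classes (z > 1 calls a class accessible;
a "joint" scaling over the whole class-by-peak grid is available since the
scaling domain is a documented choice), and broad-cell-type specificity
uses the exact one-sided Wilcoxon on the class-level z values, appropriate
at ~24 classes. Coverage tracks are per-base-pair coverage scaled by the
group's total reads per 1e7, making tracks comparable across groups and
invariant to duplicating a group's fragments.

## Numerical and design choices

* One integer seed drives everything; sub-generators derive child seeds
  deterministically per stage, so no stage's randomness depends on another
  stage's draw order.
* PCA uses the eigendecomposition of the feature covariance with component
  signs fixed by the largest-magnitude loading, making embeddings exactly
  reproducible; kNN search is exact (blockwise brute force), appropriate at
  the package's simulation scales.
* The conditional-MLE root is solved to 1e-12 on the log-odds scale;
  two-sided Fisher p uses the minimum-likelihood rule with a 1 + 1e-7
  relative tie tolerance.
* Degenerate inputs are handled explicitly: all-zero cells produce zero
  TF-IDF rows with a warning; zero-total features are an error (they should
  be pre-filtered); single-cell samples pass through batch adjustment
  unadjusted with a warning; disconnected cells after SNN pruning are
  assigned to the nearest cluster centroid; constant score vectors test at
  p = 1.

## Problem sizes used by the checks

The packaged verification suite runs the full pipeline at the default study
conditions (20 seeds of 3 samples x 1000 cells, 2000 peaks, 1000 genes) for
class recovery, the odds-ratio matrix and LDA discriminability; the lineage
analysis at 2000 cells x 500 promoter peaks with 20 planted couplings over
10 seeds; the pseudobulk test at 6 samples x 2 states with 1000 null and
10-in-200 planted peaks over 20 seeds; and exhaustive enumeration oracles
for the exact statistics (all 2x2 tables with margins up to 15; all
hypergeometric tails up to N = 30; all rank-sum splits up to n = 10). These
sizes were chosen as the smallest at which the asymptotic approximations in
play are expected to hold and the planted effects are comfortably inside
the detectable regime.

## Known limitations

* Per-sample centering satisfies the batch contract but cannot undo
  cell-composition-dependent batch effects; real analyses should inject a
  harmonized embedding.
* The fixed-effect sample strategy is asymptotically equivalent to the
  random intercept for the tested term but can differ at very small
  per-sample cell counts; the lme4 path exists for that regime.
* The rank-sum marker test does not select bias-matched background peaks
  (no TSS-enrichment or GC matching); class-specific peak sets from sparse
  classes should be read accordingly.
* The LDA AUC treats the hPCs as given; uncertainty in the embedding is not
  propagated.
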