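---
title: "Quantifying lung-nodule microenvironments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung-nodule microenvironments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleTME)
```

# Scope

Part-solid lung nodules juxtapose a preinvasive, radiographically non-solid
(NS) component and an invasive solid (S) component, with matched adjacent
normal lung (NL) available from the same resection. noduleTME quantifies how
the tumor microenvironment changes across these compartments, starting from
already-segmented data: cell tables from multiplexed imaging (one row per
cell with centroid coordinates in micrometres and a phenotype label),
single-cell RNA count matrices, per-cell copy-number value matrices, and
spot-level spatial transcriptomics tables. Upstream steps — image
segmentation, read alignment, ambient-RNA cleanup, clustering, CNV
inference itself — are out of scope; the package consumes their outputs.

# BET triads

The central spatial statistic is the BET triad: a B cell and a T cell
simultaneously in contact with the same endothelial cell (EC), read as a
proxy for high-endothelial-venule-mediated lymphocyte recruitment into
tertiary lymphoid structures (TLS). Contact is defined geometrically: a
lymphocyte touches an EC when the centroid distance is at most twice that
EC's major-axis length (its longest diameter, supplied by segmentation and
never re-derived here). Choices worth stating explicitly:

* **Inclusive boundary.** A lymphocyte at exactly 2× the axis counts as a
  contact. The alternative (strict inequality) changes results only on a
  measure-zero set for continuous coordinates but matters for constructed
  fixtures, so it is fixed and tested. The multiplier is exposed
  (`boundaryMultiplier`, default 2; 1 gives the tighter single-axis
  variant).
* **EC-centric counting.** One triad per qualifying EC is the primary
  count (`n_triads`); the number of distinct (B, EC, T) combinations is
  reported alongside (`n_triples` = #B contacts × #T contacts summed over
  triad ECs). Counting ECs rather than triples keeps the statistic bounded
  by the EC population and insensitive to lymphocyte multiplicity inside
  one contact zone.
* **Per-ROI, per-area reporting.** `triadRate()` normalizes to triads per
  mm² so ROIs of different sizes compare; raw per-ROI counts remain in the
  result for per-TLS or per-ROI summaries.

Detection is validated two ways: against an exhaustive all-pairs
brute-force oracle on random fixtures (exact equality required), and
against generator truth on ROIs with planted triads and single-contact
distractors (perfect precision and recall required). Both counts and
densities are exactly invariant under rigid motions of the coordinate
system, which the suite also checks.

# Neighborhood densities and TLS ratios

Cell neighborhoods use a proximity graph with edges between centroids
within 100 µm (inclusive), the conventional interaction range for
segmented imaging mass cytometry data. Anchored density
(`densityAround()`) counts target-phenotype cells within the radius of
each anchor cell (the anchor itself excluded) and divides by the disc
area, yielding cells/mm²; per-ROI aggregation is the mean over anchors,
with a pooled count-over-total-area variant reported alongside since
either convention appears in practice.

TLS membership is taken from the `tls_id` column — the package does not
segment TLS boundaries. The TLS area defaults to the convex hull of its
member cells, with a fixed-radius disk override for workflows that define
TLS as circular neighborhoods. The activation/exhaustion ratio divides the
activated T-cell density by the exhausted T-cell density per TLS and
lineage (CD4, CD8); a zero exhausted density yields a flagged missing
value rather than an infinity, so downstream paired tests silently drop
such TLS instead of propagating infinities.

# Gene-module scores and cell-of-origin calls

Module scores follow the bin-matched control-gene scheme: normalize counts
(log1p of counts scaled to 10,000 per cell — configurable, applied
automatically unless a `logcounts` assay or a pre-normalized matrix is
supplied), bin all genes into `nBins = 24` equal-frequency bins of
gene-wise average expression, sample `nCtrl = 100` control genes per
signature gene from its bin under a fixed seed, and score each cell as
mean signature expression minus mean control expression. Two deliberate
departures from the most common implementation:

* Control pools **exclude the signature's own genes**, so a one-gene
  signature against an otherwise empty bin scores exactly the raw
  expression difference (the package's worked arithmetic example relies on
  this, and it removes a small systematic attenuation).
* The bin count is capped at `floor(nGenes / 4)` so tiny matrices retain
  non-signature bin mates as controls; with realistic gene counts the cap
  never binds.

Scores are invariant to adding a per-cell constant across genes (signature
and control means shift equally) and bit-reproducible given the seed.

Tumor cell-of-origin is assigned per cell by the argmax of the AT2 and
club module scores (exact ties labelled `tied`), then aggregated per
patient. A patient call requires at least 20 tumor cells, a winning-label
fraction of at least 0.6, and a non-negative patient-mean winning score;
otherwise the patient is `unassigned`. These three thresholds encode
"predominantly one program, supported by enough cells with positive
enrichment" and are all configurable; an alternative `method = "mean"`
compares patient-level mean AT2 vs club scores instead of the cell
majority — both aggregation conventions are defensible, so both are
implemented, with the cell-majority rule as the default.

# CNV cell scores

Copy-number burden per cell is the arithmetic mean over chromosome arms of
the per-arm mean of squared CNV values, where values are deviations from
neutral (a 1-centred matrix can be recentred at construction). Squaring
makes gains and losses contribute alike; for i.i.d. Normal(0, σ) noise the
expected cell score is exactly σ², which the suite verifies empirically at
10⁴ cells × 100 genes, and a single arm shifted by *a* among *k* arms with
zero noise scores exactly a²/k.

"Elevated" is made operational as a reference-anchored z-threshold: a
cluster is called tumor when its mean score exceeds the normal-reference
mean by more than `kSigma = 2` reference standard deviations, with at
least 10 reference cells required for the baseline. Auxiliary evidence
(nodule-sample enrichment, mixed marker expression) belongs to annotation,
not to the hard call. Per-cell scores are averaged within clusters after
scoring each cell, not the other way round.

# Single-cell QC

Cells are kept when the detected-gene count (genes with count > 0, not
UMIs) lies in [200, 6500] and the mitochondrial read fraction is at most
15%. The removal phrasing is strict ("fewer than", "more than"), so
boundary cells — exactly 200 genes, exactly 15% — are kept; the suite
pins this. Absent mitochondrial flags skip that criterion with a warning
rather than silently. Removal reasons are reported with the priority
low_genes > high_genes > high_mito when a cell violates several.

The doublet rule flags cells expressing markers of two or more distinct
lineages (epithelial: SFTPC, SCGB3A1; T: CD3D; B/plasma: CD79A, JCHAIN,
MZB1; myeloid: MARCO, CD163), where "expressing" means raw count > 0 by
default (configurable). The pan-immune marker PTPRC is excluded from the
rule: its co-expression with any immune lineage is biologically universal
and would flag every immune cell.

# Spot-level analyses

The spatial-significance score of a gene is the unbiased (n−1) standard
deviation of its normalized expression across the spots of one sample —
the plainest reading of "spatial standard deviation". It uses no spot
coordinates; a moving-average-residual variant that would was considered
and deliberately not made the default, since nothing in the method
definition requires coordinates. Candidate genes are the top `nTop` per
sample (default 5000) with lexicographic tie-breaks, intersected across
samples.

The per-spot signature score is a rank-recovery AUC: genes are ranked by
expression within each spot (ties broken by gene id so scores are
bit-stable), and the score is the area under the cumulative
signature-recovery curve over the top 5% of ranks, normalized by the
maximal achievable area — 1 when the signature occupies the top ranks, 0
when it misses the window entirely. Using ranks only makes the score
invariant to any monotone transform of a spot's profile. The 5% window is
the canonical default and is exposed as a parameter.

Cell-type coexistence is the Pearson correlation across spots between
per-spot cell-type counts (as produced by any deconvolution); zero
variance yields flagged missing entries.

# Statistical comparisons

Paired compartment comparisons (NL vs NS vs S from the same patients) use
the Wilcoxon matched-pairs signed-rank test. The implementation computes
the exact, tie-aware null distribution by dynamic programming over doubled
midranks for n ≤ 25 pairs and the normal approximation with continuity
and tie correction above; zero differences are dropped (classical
convention) and all-zero input returns p = 1. The exact branch is verified
against exhaustive 2ⁿ sign enumeration, and its type-I error at nominal
α = 0.05 is checked to land in [0.03, 0.07] over 10⁴ null replicates.

Unpaired two-group comparisons reproduce the stated gate verbatim:
Levene's test first (classical mean-centred), then Mann-Whitney U when
Levene's p < 0.05 and Student's t-test otherwise. Using a
variance-equality test to decide "normality" is internally inconsistent —
it routes heteroscedastic normal data to the rank test and heavy-tailed
equal-variance data to the t-test — but it is the procedure as defined,
so it is implemented as such, both branch results are always retained in
the result object, and a Shapiro-Wilk gate is available behind a flag (off
by default). Multi-group comparisons use Kruskal-Wallis with tie
correction. No multiplicity correction is applied by default (per-
comparison p-values are the reporting convention here); Benjamini-Hochberg
can be applied downstream via `p.adjust`.

# The synthetic-data generator

Every input has a generator with recorded ground truth, so all detectors
can be scored without external data. What it emulates, and what it does
not:

* **ROIs** (`simulateROI()`): homogeneous Poisson background per phenotype
  over a 1 mm² ROI at densities typical of dense nodule tissue, planted
  triad ECs (lognormal major axes, median 10 µm, sdlog 0.25) each given
  one B and one T contact at uniform angle and radius in (0, 2a], planted
  distractor ECs with one contact plus one near-miss at radius in
  (2a, 4a] so the boundary is exercised, and TLS disks (radius 120 µm,
  ~3000 cells/mm²) with a B-cell core inside 0.6 R and a T-cell ring
  outside it. One deliberate departure from pure Poisson: unplanted
  lymphocytes are resampled until they are more than 2a from every EC.
  This makes the planted triad set *exactly* the true triad set — the
  property perfect-precision/recall tests rely on — at the cost of a
  slight local thinning of lymphocytes around ECs. Under unconstrained
  spatial randomness at these densities, chance EC-lymphocyte
  coincidences alone would produce several "triads" per mm², which is a
  property of dense tissue, not a detector failure; the permutation-null
  test therefore uses a sparse background where the planted excess is
  identifiable.
* **Expression** (`simulateExpression()`): negative-binomial counts
  (size 10) with lognormal library sizes (median 5000), two planted
  programs of 10 genes each (AT2 and club) at a baseline of 20
  counts-per-10k, shifted multiplicatively by exp(δ) in their program's
  cells. Both programs are planted symmetrically, so the small library-
  size inflation they cause cancels between groups and a planted δ is
  recovered as a score difference within a few percent (log1p curvature
  accounts for the remainder; the recovery criterion allows 10%). Marker
  genes for the doublet rule and Beta-distributed mitochondrial fractions
  (mean 5%) are included. Not emulated: batch effects, ambient RNA,
  dropout beyond NB sampling, realistic gene-gene correlation — so
  passing tests demonstrate correctness of the scoring arithmetic and
  recovery under the stated noise model, not robustness to real-data
  artifacts.
* **CNV** (`simulateCNV()`): Normal(0, σ = 0.05) noise, additive arm
  shifts in tumor cells. Real inferred-CNV output is smoothed and
  autocorrelated along the genome; this generator is not, which is
  irrelevant for score arithmetic but means segmentation-related biases
  are untested.
* **Spots** (`simulateSpots()`): 15×15 grid, flat genes plus linear
  gradients of amplitude 2 (in normalized-expression units) for planted
  spatially variable genes, Poisson cell-type counts with a shared latent
  Gamma field linking the first two types. Expression is emitted directly
  on the normalized scale. Spot mixing profiles and platform-specific
  noise are not modelled.

All generators are bit-reproducible from the config seed and restore the
caller's RNG state.

# Problem sizes and runtime choices

The test and acceptance workloads were sized to be statistically
meaningful while staying comfortably interactive: triad brute-force
equivalence on 100 random fixtures of up to 200 cells; planted-triad
recovery over 50 (tests) / 20 (acceptance script) seeded ROIs of ~1500
cells; module-score recovery at 1000 cells × 5000 genes (the gene count
matters — expression bins must be large enough that the two anti-
correlated program gene sets dilute in their bin's control pool); CNV
closed-form at 10⁴ cells × 100 genes; signed-rank type-I error over 10⁴
null replicates of 12 pairs; and an end-to-end pipeline of 4 patients × 2
compartments. The full pipeline runs in well under a minute on one CPU.

# Known limitations

* Geometry is 2-D and centroid-based; cell shapes beyond the EC major
  axis are ignored, so "contact" is a centroid-distance proxy.
* The convex-hull TLS area underestimates the area of sparse TLS and is
  undefined below 3 member cells (an error); supply a disk radius there.
* The Levene-gated test inherits the conceptual inconsistency discussed
  above by design.
* Patient-level origin calls depend on three thresholds whose values are
  conventions, not fitted quantities; sensitivity to them should be
  reported when the calls matter.
* The spatial-significance score conflates spatial structure with overall
  expression variability; it ranks genes, it does not test them.
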