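---
title: "Methods: building a spatially resolved cortical cell atlas from multiplexed FISH data"
author: "merfishAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a spatially resolved cortical cell atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`merfishAtlas` implements an end-to-end computational pipeline for
multiplexed error-robust FISH (MERFISH) experiments on cortical tissue:
from error-correcting barcode design, through image decoding, quality
control and two-round clustering, to laminar spatial statistics, analysis
of the intratelencephalic (IT) expression gradient, and retrograde-tracer
projection mapping. This vignette records the models, the parameters that
matter, and the design decisions taken where the methods literature leaves
choices open. Every empirical statement here is recomputed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from external runs.

## Error-robust codebooks

Each gene is assigned a binary barcode of length 22 (one bit per imaging
round) with exactly 4 on-bits and pairwise Hamming distance at least 4, so
any single bit error maps uniquely back to its codeword. The primary
generator is a *sum-residue* construction: all weight-4 words whose
0-based on-bit positions sum to 0 modulo the word length. If two such
words shared 3 on-bits, their remaining positions would be congruent
modulo the length and hence equal, so distinct words share at most 2
on-bits and the distance-4 guarantee is structural rather than checked
a posteriori (the class validity still verifies it exhaustively). At 22
bits this yields 335 codewords — comfortably more than the 252 needed for
242 genes plus 10 blanks. Blank barcodes are codewords assigned to no
gene; since no RNA species carries them, their call rate estimates the
false-positive ("misidentification") rate. A greedy lexicographic
construction backs up parameter regimes the residue construction cannot
serve (e.g. minimum distance above 4). Decoding never guesses: a word
within distance 1 of two entries (impossible for distance-4 codes, but
possible for degraded inputs under relaxed parameters) is a no-call.

## Panel selection and probe design

Marker panels are selected from clustered reference expression by three
routes that mirror standard practice: a manually curated marker list;
the top genes by mutual information between zero-thresholded (on/off)
expression and cluster identity, computed separately for excitatory and
inhibitory clusters; and per-cluster-pair differential expression with
four criteria (fold change >= 2, p < 0.05 from a two-group one-way test on
log-transformed values, foreground expressing fraction >= 0.40, and more
than 3-fold enrichment of the expressing fraction). The two-group ANOVA
is algebraically the equal-variance two-sample t test, and we compute it
as such rather than calling a fitting package; a background expressing
fraction of zero counts as infinite enrichment. The log transform uses a
pseudocount of 1 and the natural log — the convention, since nothing
pins it down. A greedy cover then augments the seed panel until every
ordered cluster pair has at least two of its DE candidates included per
direction; pairs that cannot reach the target even with all their
candidates are flagged, never silently dropped.

Encoding probes carry 30-nt targeting sequences. A transcript of length
L accommodates `floor((L - 30) / 10) + 1` targets when adjacent targets
may overlap by up to 20 nt; genes that cannot fit 48 probes even so, or
whose per-cluster mean count reaches 200, are routed to sequential
single-readout imaging rounds instead of the combinatorial run. When a
transcript fits the requested probes without overlap, start positions are
sampled (seeded) from the non-overlapping grid — random placement with a
reproducibility handle; otherwise probes sit on a deterministic evenly
spaced grid whose adjacent overlap never exceeds 20 nt. Combinatorial
probes carry two readout sites drawn from the gene's four on-bits, cycled
so that with four or more probes every on-bit is represented. No
off-target or melting-temperature screening is attempted here.

## Decoding and segmentation

Image stacks are reduced to a single 2-D plane (imaging experiments of this kind
typically acquire several 1.5-um z-planes; all downstream statistics consume the cell
volume as a scalar, which we form as area times a nominal 10-um slice
thickness). Preprocessing per round: high-pass background subtraction,
Lucy–Richardson deconvolution (20 iterations by default) with a Gaussian
PSF, then mild low-pass smoothing. Pixel vectors across rounds are unit
normalized; bits are called by thresholding at the midpoint of the
largest gap in the sorted intensities, and the resulting word is decoded
with single-error correction. Four-connected pixels with the same call
merge into candidate molecules; single-pixel candidates are discarded.

The misidentification rate is the mean call count per blank barcode
divided by the mean count per coding barcode. The adaptive filter orders
candidates by a rank-product quality score (mean on-bit intensity, and
one minus the cosine distance to the unit barcode) and keeps the largest
quality prefix whose blank-derived rate stays at or below the 5% target.
Cell segmentation uses nucleus seeds (Otsu-thresholded, labelled) and
propagates them over the polyA landscape within the polyA foreground,
yielding disjoint masks; molecules take the id of the mask containing
their centroid.

## Quality control

The cascade runs in a fixed order: (1) volume filter — cells below
100 um^3 (segmentation artifacts) or above three times the pre-removal
median volume (merged cells) are flagged, with strict inequalities at
both cut-offs; (2) volume normalization; (3) per-batch scaling of the
mean total counts to 250; (4) the sequential-channel artifact filter —
cells above the 90% quantile in at least 12 of 16 channels (scaled
proportionally when fewer channels are present); (5) per-cell background
subtraction within dye-channel groups; (6) removal of cells outside the
2%–98% total-count quantiles, computed after batch normalization (the
ordering is not dictated by the QC definitions; computing totals on the
batch-normalized matrix keeps the quantiles comparable across
experiments); (7) doublet removal; (8) removal of configured low-quality
genes (none by default — the shipped 254-gene panel already excludes
them).

Doublet scoring synthesizes artificial doublets by summing random
observed cell pairs, embeds observed and simulated cells jointly
(total-normalization to the median, log1p, gene z-scores, 30 PCs), and
scores each observed cell from the fraction `q` of simulated doublets
among its neighbours. With `r` the simulated/observed ratio and `rho` the
expected contamination prior, the reported score is the posterior
`q*rho/r / (q*rho/r + (1-q)*(1-rho))`, so the familiar 0.18 removal threshold
is meaningful as a probability. Two defaults matter and both are deliberate: the
prior equals the anticipated contamination (0.12), and the neighbourhood
is small (k = 6 before ratio adjustment, i.e. 30 joint neighbours).
Doublets between two of ~95 roughly balanced clusters populate their
pair-specific region of expression space only sparsely; a wide
neighbourhood dilutes the local excess of simulated doublets with cells
of the flanking singlet clusters and suppresses sensitivity, which we
verified directly on generated data with planted doublets. Doublets whose
parents share a cluster are invisible to this (and any) total-normalized
detector; with ~95 clusters they are a percent-level minority.

## Two-round clustering

Expression is total-scaled to the median, log-transformed and z-scored
per gene. The number of principal components is set by a shuffle
calibration: each gene column is permuted independently, the first
eigenvalue of the shuffled covariance recorded, and after 20 shuffles all
real components whose eigenvalue exceeds the mean shuffled first
eigenvalue are kept. Round 1 clusters all cells (Louvain on a kNN graph,
k = 10, resolution 1) and routes each cluster by marker expression into
five groups — IT (Slc17a7 with Slc30a3), non-IT excitatory (Slc17a7
without Slc30a3), CGE-derived (Gad1/Gad2 with Lamp5/Sncg/Vip), MGE-derived
(Gad1/Gad2 with Sst/Pvalb) and non-neuronal. Routing operates on
cluster-mean z-scores with a threshold of 0.5: clusters, not single
cells, are routed, and clusters co-expressing incompatible class markers
(the classic Slc17a7 + Sox10 chimera) are flagged as doublet clusters and
removed. Round 2 re-z-scores each group and re-clusters with
group-specific parameters — k = 40, r = 2 for both excitatory groups;
k = 15, r = 2 for both inhibitory groups; k = 20, r = 1 for non-neuronal
cells — then assigns each final cluster a subclass by its best
marker-set score and names it "subclass index". Bootstrap co-clustering
stability (mean within-cluster pair consistency across subsampled
re-clusterings) is available to flag fragile clusters; the merge
threshold default of 0.6 is a package choice; no standard value exists.

Label transfer to new samples uses a multinomial maximum-entropy
classifier on the leading principal components of the z-scored profiles
(a single-hidden-layer network is available by configuration). Train and
test matrices are matched on their gene intersection and the test data
are standardized with the training statistics.

## Spatial statistics

The cortical surface of each slice is a quadratic curve fitted through
the VLMC centroids (the vascular leptomeningeal cells form the outermost
cell layer; the "surface line" concept has no
standard parameterization — a low-order polynomial is the mildest smooth choice).
A cell's soma depth is its shortest distance to that curve, normalized by
the slice's cortical thickness, defined as the median depth of its L6b
cells; slices missing either anchor population are excluded with a
warning. Layer boundaries are medians of designated clusters (most
superficial L2/3 IT cluster for the top of L2/3, most superficial L4/5 IT
cluster for L4, most superficial of the L6 IT/CT clusters for L6), L6b is
centred at 1 with interquartile bounds (how wide the L6b band should be is
not standardised; the IQR is the conservative choice, and it is a config
switch), and the top of L5 is reported as an uncertainty interval between
the deepest L4/5 IT cluster and the most superficial L5 IT cluster.

The marker-overlap statistic bins all cells into 100 equal-count depth
bins and asks what fraction of a cluster's cells fall in bins where the
marker's binned expression exceeds half its maximum; the bin summary is
the mean (mean and median summaries are both
defensible; the mean is the default and the median a switch). Density overlap between two depth
distributions is the integral of the pointwise minimum of their kernel
density estimates (Scott's rule bandwidth by default, fixed-bandwidth
override for reproducibility). Neighbourhood complexity counts the
distinct cluster labels within 100 um of a cell in its slice, including
the cell's own cluster — "clusters present within the neighbourhood
surrounding the cell" is read inclusively, so an isolated cell scores 1.

## The IT gradient

Genes varying with depth are found by splitting IT cells into 50
equal-count depth bins and selecting genes whose binned mean z-profile
spans more than 0.5, ordered by the peak of a 10-bin rolling average.
Inter-cluster connectivity is the observed number of kNN-graph edges
(19 PCs by default, k = 12) between two clusters divided by the count
expected when edge endpoints are placed randomly in proportion to cluster
sizes, `m * 2 * n_a * n_b / (n * (n - 1))` — chance-level mixing scores
1, separation scores 0; a 0.1 display threshold hides weak edges in plots
but never removes them from the data. Diffusion pseudotime builds a
diffusion map from the same kNN graph (eigenvectors of the symmetrically
normalized adjacency, components scaled by `lambda / (1 - lambda)`) and
measures each cell's diffusion distance from a root cell — the member of
the designated root cluster nearest that cluster's PC centroid, a
deterministic reading of "a neuron from the root cluster" with a seeded
tie-break. The well-separated L6 IT Car3-like outgroup can be excluded by
configuration and then never enters the graph. Pseudotime here orders
cells along the expression continuum; it carries no developmental claim.
The PC count for these analyses is re-derived by the shuffle criterion
for each analysis subset by default.

## Projection mapping

Tracer channels are robust-scaled per channel (median/MAD across cells,
dominated by the unlabelled background) and thresholded stringently
(default 5 robust-z units) so weakly labelled cells stay off; there is no
universal threshold value to inherit, so the default is validated
on synthetic data only. Depth enrichment divides, per depth bin, the
fraction of a target's tracer-positive cells by the fraction of the
reference population (all IT and L6b cells) in that bin; bins are 20
equal-count bins of the reference population (the bin count is a
package choice), and empty bins report missing values rather than
zeros. Composition statistics restrict to single-projecting cells and
report per-cluster target fractions and per-target compositions over
subclasses and clusters, with percentile bootstrap-over-cells confidence
intervals.

## The synthetic data generator

The generator is first-class, tested code: it encodes the statistical
structure every stage assumes so the whole pipeline is testable without
any download. Its defaults are the study conditions: a 95-cluster
taxonomy (39 excitatory, 42 inhibitory, 14 non-neuronal clusters in 23
subclasses) with cluster-specific truncated-normal laminar depth
distributions; a 254-gene panel (242 combinatorial, 12 sequential-mode
genes) containing the class, group and subclass markers the router needs;
negative-binomial counts (size 8) around cluster means built from a
log-normal baseline, marker structure, six signature genes per cluster
(10-fold boost) and log-normal per-cluster jitter (sd 0.35); 20
depth-graded genes whose means vary as `exp(slope * (depth - 0.5))` in IT
cells so spatially adjacent IT clusters overlap in expression; a
two-batch design whose raw mean totals differ by 30%; 12% doublets formed
by summing two independently drawn parent profiles (volumes add); 2%
small-volume artifact cells; and three slices with gently curved
quadratic surfaces and varying thickness. Cell class composition defaults
to 50% excitatory / 20% inhibitory / 30% non-neuronal with IT clusters
holding 70% of the excitatory cells; the within-class evenness is
stylized (real data are more skewed) and chosen so every cluster keeps
enough cells to be recoverable at the 30,000-cell scale used throughout.

The tracer generator samples per-channel labels from a per-cluster
probability table whose default is calibrated so IT and L6b cells jointly
account for about 90% of labelled cells, including a small leak rate for
all other clusters, and encodes a disjoint-target scenario for two
molecularly similar deep IT clusters. The image-stack generator renders
each on-bit as a Gaussian spot with amplitude jitter, optional single-bit
dropout, optional dim "false spots" carrying one fewer on-bit than a real
barcode (the quality-separable false-positive population the blank-based
filter is designed against; real molecules never carry blank codes), and
Gaussian background noise; molecule placements keep a minimum separation
so ground-truth evaluation stays well-defined.

What passing tests on these data do **not** show: robustness to ambient
RNA, segmentation errors correlated with cell type, non-linear batch
effects, tissue morphology, or cluster abundance distributions as skewed
as real cortex; the generator's clusters are also more Gaussian in
log-expression space than real ones.

## Numerical choices and problem sizes

All randomness flows through explicit seeds (`withSeed`), including
Louvain, the doublet simulation, probe placement and root-cell
tie-breaks; identical seeds give bit-identical outputs. PCA is computed
from the feature covariance eigendecomposition (features ≪ cells
throughout); zero-variance genes z-score to 0; quantiles use R's default
linear interpolation; the kNN backend is exact. The test suite exercises
the full pipeline at 6,000–30,000 cells and the acceptance script uses
30,000 cells for clustering recovery, 10,000 for doublet calibration,
8,000 for the tracer experiment and a 300-pixel field with ~700 molecules
for decoding — sizes at which every recovery property we assert is
stable across seeds while the whole suite stays desk-scale. Known
limitations: the 2-D single-plane reduction of image analysis; no drift
correction or FOV mosaicking; no atlas registration (a synthetic
coordinate frame replaces it); and the classifier is exercised on
synthetic data only.
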