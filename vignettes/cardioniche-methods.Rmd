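---
title: "Methods: spatially informed niche analysis with cardioniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially informed niche analysis with cardioniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioniche)
```

## Overview

`cardioniche` chains five analysis stages commonly used to map cellular
niches in spatial transcriptomic atlases of developing tissue, such as the
embryonic/fetal human heart between postconceptional weeks (PCW) 5.5 and
14:

1. **Reference profiling** — per-state mean expression and fraction of
   expressing cells from a labeled single-cell count matrix.
2. **Spot deconvolution** — non-negative least squares (NNLS) estimation
   of per-spot cell-state proportions.
3. **Co-detection niche discovery** — pairwise Pearson correlation of
   per-spot proportions, a thresholded niche graph, and stability checks
   across developmental age groups.
4. **ISS decoding** — per-round max-channel decoding of combinatorial
   in situ sequencing barcodes with per-cycle quality scores and a
   minimum-quality filter.
5. **Ligand–receptor surrogate scoring** — a directed sender→receiver
   score built from enzyme/receptor gene pairs (e.g. TH→ADRB1 for
   adrenergic, CHAT→CHRM2 for cholinergic signaling).

Because the atlases these methods target are large and access-controlled,
the package is exercised end to end on a first-class synthetic generator
with full ground truth; every stage is validated against that truth or an
independent oracle.

## The synthetic study conditions

`synthetic_config()` fixes the simulated study design once:

- **States and markers.** Each of `n_states` (default 6) states owns
  `markers_per_state` (10) dedicated marker genes out of `n_genes` (200).
  Per-gene baseline relative expression is uniform on [0.5, 1.5]; a
  state's markers are enriched `marker_fold` (5) times over baseline.
  With baselines bounded by 1.5 and fold > 3, every marker is strictly
  the top gene of its state — an exactly assertable invariant.
- **Sections and niches.** Spots sit on a `grid_side`² lattice split into
  `n_niches` contiguous vertical bands (rectangular blocks guarantee
  spatial contiguity; Voronoi layouts would be an extension, not the
  default). States are dealt round-robin to niches; a niche's Dirichlet
  mean gives its dominant states 75% of the mass. Per-spot compositions
  are Dirichlet with total concentration `dirichlet_concentration` (30 —
  clearly niche-structured but far from degenerate); `fixed_mixture =
  TRUE` is the infinite-concentration limit used in exactness tests.
- **Counts.** Expected spot counts are `spot_depth` (5000, a typical
  spatially barcoded spot depth) times the mixed profile. Noise is
  Poisson by default, negative binomial with one shared dispersion as the
  standard single-cell overdispersion convention, or `none` for the exact
  linear-mixture limit. No public noise model exists for the motivating
  data; these are conventions, not reconstructions.
- **Ages.** Sections carry PCW values in [5.5, 14], defaulting to an even
  spread.
- **ISS.** 150 targets coded over 5 rounds × 5 channels (one-hot per
  round, unique codes sampled from the 5⁵ = 3125 possibilities), uniform
  background plus additive half-normal noise per (round, channel) so
  intensities stay non-negative.

One global seed drives separate deterministic substreams for the
reference, the sections and the ISS tensor, so any module's inputs can be
regenerated independently and byte-identically.

What the generator does *not* emulate: doublets and ambient RNA, batch
and donor effects, spatially varying capture efficiency, segmentation or
optical artifacts upstream of the ISS intensity table. Passing tests
demonstrate correctness of the algorithms under the stated generative
model, not robustness to every artifact of real tissue data.

## Reference profiles

`normalize_counts()` scales each cell to 10⁴ total counts and applies
`log1p` — the de facto standard when the upstream recipe is not
prescribed. `build_profiles()` returns three genes × states matrices:
`mean_expr` (mean log-normalized expression, the display and LR-scoring
substrate), `mean_counts` (mean linear counts-per-10⁴, the deconvolution
reference — log transforms break mixture linearity), and `frac_expr`
(fraction of cells with raw count > 0). Dot-plot (`dotplot_table()`) and
heatmap (`zscale_heatmap_table()`) summaries z-score each gene across the
*selected* states using the population SD; genes constant across the
selection map to 0 rather than NaN so downstream heatmaps stay finite.
Whether to scale within the displayed states or all states is genuinely
open; within-selection scaling matches how such panels are usually read.

## Deconvolution

`fit_proportions()` solves, per spot,

$$\min_{w \ge 0} \; \lVert b - A w \rVert_2^2, \qquad
  \hat p = w / \textstyle\sum_k w_k,$$

where $b$ is the spot's counts-per-10⁴ vector over the genes shared with
the reference and $A$ holds the states' linear mean profiles
(Lawson–Hanson NNLS via `pracma::lsqnonneg`). This deliberately
dependency-light, transparent estimator reproduces the downstream
co-detection logic; the `proportion_map` contract isolates it so a
probabilistic deconvolution model could be swapped in. Design choices:

- Normalization before fitting makes estimates invariant to per-spot
  scaling (solver tolerance ~1e-8).
- Spots under `min_counts` (100) total counts are masked, not fitted —
  standard QC floor; masked spots carry an explicit mask bit and all-zero
  rows.
- Collinear references are fit as-is with a conditioning warning; an
  optional ridge penalty (`ridge`, default 0) is available rather than
  imposed.

Noise-free mixtures are recovered to numerical precision (mean per-spot
L1 error ~1e-16 in the acceptance run); under Poisson noise at depth
5000 with 5 marker-separated states the mean L1 error stays well under
0.10.

## Co-detection and niche graphs

The co-detection score of two states is the Pearson correlation of their
per-spot proportions. Two aggregations are exposed because pooling spots
across sections can manufacture correlation from between-section
composition shifts: `per_section_weighted` (default) correlates within
each section and averages across sections weighted by unmasked spot
count; `pooled` concatenates spots. Zero-variance states propagate as
missing values (never 0) with a warning, and missing entries never create
edges.

`niche_graph()` draws an edge where the score is **strictly** greater
than the threshold (default 0.07); connected components are the
discovered niches. `assign_age_groups()` bins sections into the
three-group scheme 5.5–6, 7–8, 9–14 PCW, with each printed interval
extended to the next interval's start so mid-gap ages (e.g. PCW 6.5) are
covered deterministically. `group_stability()` recomputes the matrix per
group and reports, for every group pair, the Pearson correlation of
upper-triangle scores (missing entries excluded pairwise) and the Jaccard
index of thresholded edge sets; self-comparisons are exactly 1.

On the synthetic conditions (3 planted niches, Poisson noise), every
within-niche pair outscores every cross-niche pair and the graph's
components equal the planted partition; two age groups drawn from one
truth agree with upper-triangle correlation > 0.99 and edge Jaccard 1.

## ISS decoding

`decode_spots()` implements per-round max-channel decoding: the winning
channel of each round is the intensity argmax; the barcode is the winning
sequence; genes are assigned on exact codebook match only (no
nearest-barcode rescue, matching the decoder's semantics). The per-round
quality is

$$q_r = \frac{I_{\max,r}}{\sum_c I_{c,r}},$$

an L1 normalization against the most intense channel. The L1 form makes
the 0.4 minimum-quality cutoff discriminative: uniform intensities give
exactly $1/C = 0.2$ with 5 channels, whereas an L2 rule is bounded below
by $1/\sqrt{5} \approx 0.447$ and would make the cutoff vacuous (the L2
variant is available via `quality_norm = "l2"`). With uniform background
$b$ and signal $s$, $q = (s+b)/(s+Cb)$, strictly decreasing in $b$.
Degenerate cases are defined, not fatal: argmax ties break to the lowest
channel index and are flagged; all-zero rounds score the uniform floor
$1/C$ and are flagged, so dropout spots are filtered rather than
erroring. `filter_calls()` keeps spots with a decoded gene and minimum
per-round quality **strictly** above 0.4, logging removal counts by
reason; `expression_map()` assembles the per-gene coordinate maps.

## Ligand–receptor surrogate score

For a surrogate pair (sender enzyme/ligand $g_s$, receiver receptor
$g_r$) and an ordered state pair $(S, R)$:

$$\mathrm{score}(S \to R) =
  \begin{cases}
    \tfrac12\!\left(\mu_{g_s,S} + \mu_{g_r,R}\right)
      & \text{if } f_{g_s,S} \ge 0.1 \text{ and } f_{g_r,R} \ge 0.1,\\
    0 & \text{otherwise,}
  \end{cases}$$

with $\mu$ the mean log-normalized expression and $f$ the expressing
fraction. The exact "modified" formula behind the motivating analysis is
not published in recoverable form; this mean-of-means with a 10%
expression gate is the convention closest to standard interaction-scoring
frameworks with the enzyme substituted for the ligand, and it sits behind
one function boundary with a multiplicative alternative
(`method = "product"`) exposed so the form is a one-line swap. The score
is directional, monotone in both means when gated on, and exactly 0 for
any gated-off pair. A ready-made pairs table for autonomic innervation
(TH→ADRB1, CHAT→CHRM2) ships in
`system.file("extdata/innervation_pairs.csv", package = "cardioniche")`.

## Pipeline and reproducibility

`run_pipeline(run_config(...), out_dir)` executes
simulate → profiles → deconvolve → codetect / decode / lrscore with
dependency checking, writes every artifact as plain text (MTX triplets,
CSVs, GraphML) plus a JSON manifest echoing all parameters, the seed and
the output list. Defaults carry the field constants: co-detection
threshold 0.07, minimum ISS quality 0.4, LR expression gate 0.1, three
age groups. Identical config + seed reproduces every CSV bit-identically
(the manifest differs only in timestamp/wall-clock). A thin command-line
front end, `exec/cardioniche run --config cfg.yaml --out DIR --seed N`,
wraps the same functions.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the generator at desk
scale — 4–6 states, 80–200 genes, 100–400 spots per section over 1–4
sections, 10,000 ISS spots — sizes chosen so each stage's statistical
behavior (recovery bounds, stability, filter precision) is measurable in
seconds while leaving the algorithms identical at any scale. Tolerances:
simplex sums to 1 ± 1e-9 (truth) / 1e-6 (fitted); co-detection equals the
brute-force Pearson oracle within 1e-10; the NNLS grid-search oracle uses
step 1e-4 on the 1-simplex. Ties in decoding break to the lowest channel
index; ranking ties share dense ranks via a stable sort.

## Known limitations

- NNLS deconvolution ignores spot-level count uncertainty and gene–gene
  covariance; it is a transparent baseline, not a probabilistic model.
- Co-detection is correlation, not a spatially explicit statistic; it
  cannot distinguish co-location within a spot from shared regional
  abundance at the section scale.
- The LR surrogate score carries no specificity p-value; it ranks, it
  does not test.
- The generator's niches are rectangular bands; spatial statistics that
  depend on niche geometry should not be benchmarked against it.
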