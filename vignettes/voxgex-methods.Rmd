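---
title: "voxgex: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxgex: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxgex)
```

## What the package computes

voxgex turns scattered post-mortem brain expression samples — a few hundred
3D locations per donor, each with one value per gene — into dense
voxel-by-voxel expression maps, and then characterises those maps four ways:

1. **Regional enrichment**: which parcellation regions express a gene above
   or below the brain-wide average, with FDR control and effect sizes.
2. **Donor reproducibility**: the *differential stability* (DS) statistic,
   the mean Spearman correlation of a gene's spatial pattern over all donor
   pairs.
3. **Co-expression structure**: donor-averaged Spearman correlation
   matrices, soft-thresholded adjacencies, topological overlap, module
   detection, and hypergeometric gene-set enrichment.
4. **Reverse-inference decoding**: Spearman correlation of a gene's map
   with a library of meta-analytic term association maps, rank specificity
   against the whole gene library, and a permutation contrast between
   "social" and "non-social" terms.

Because the real data sources this kind of analysis runs on (donor brain
atlases, tissue expression databases, fMRI meta-analytic map libraries)
cannot ship with a package, voxgex includes a synthetic-data generator that
emulates their structure with planted, recoverable ground truth. Every
pipeline stage is validated against that truth.

## Dense maps from scattered samples

The mapping procedure is deliberately simple and geometric:

1. **Border labelling.** Every mask voxel with a 6-connected neighbour
   outside the mask (or on the grid edge) becomes a pseudo-point at its
   voxel centre, carrying the expression value of the nearest sample
   (Euclidean distance in voxel space; exact ties go to the lowest sample
   index). This pins the interpolant down at the brain surface so the
   convex hull of the augmented point set covers essentially the whole
   mask.
2. **Delaunay tessellation.** The augmented point set is tessellated into
   tetrahedra (Bowyer–Watson incremental insertion, implemented in C++
   inside the package since no installed R package offers 3D Delaunay).
3. **Barycentric interpolation.** Each mask voxel centre inside the hull
   receives the linear interpolant of its containing tetrahedron's vertex
   values. The rare voxels outside the hull fall back to the
   nearest point's value, so no mask voxel is left undefined.
4. **Averaging.** Donor volumes are averaged voxelwise so each gene is
   represented by a single map.

### Numerical choices

* **Deterministic jitter.** Border pseudo-points sit at integer voxel
  centres, a maximally degenerate configuration for Delaunay
  (many cospherical quadruples). The tessellation therefore works on a
  jittered copy of the points (relative magnitude 1e-6, a pure hash of the
  point index — no RNG state is consumed, so results are bit-reproducible).
  Barycentric weights are computed from the *original* coordinates, which
  keeps the interpolant exact on affine fields: the acceptance suite
  verifies reproduction of random affine fields at every in-hull voxel to
  1e-9, and agreement with an independent Qhull-based implementation to
  1e-8.
* **Degenerate input.** A point set whose affine rank is below 3 (all
  coplanar or collinear) cannot be tessellated and is rejected with an
  error advising jitter.
* **Range clamping.** Linear interpolation of border-labelled data cannot
  legitimately leave the sample value range, so each gene's volume is
  clamped to it; this also absorbs the ~1e-6-scale wobble that the jitter
  can introduce where pseudo-points coincide with samples.
* **Query convention.** Sample coordinates are continuous 0-based voxel
  indices; interpolation queries are the integer voxel centres themselves.
  World coordinates exist only through the atlas affine. Registration
  across donors is out of scope: all donors share the template grid, with
  a sub-voxel coordinate jitter in the generator standing in for residual
  misregistration.

## Regional statistics

Region-by-donor mean expression comes either from the dense maps (mean
over the region's voxels) or directly from the samples falling in the
region. Enrichment per region is a two-tailed one-sample t-test of the
donors' region means against the **grand mean** — the mean of region means,
each region weighted equally, treated as a fixed reference `mu`. The
induced dependence between a region and the reference (the region is part
of the grand mean) is accepted and is slightly conservative. BH adjustment
runs across however many regions the atlas has; Cohen's d is
`|mean − mu| / SD` of the donor region means. Zero donor variance makes t
undefined; such regions are reported with `d = Inf`, `p = 0` and a
degeneracy flag rather than silently dropped.

Group contrasts (e.g. between two sets of substructures) use Welch's
unequal-variance t-test on per-region means averaged over donors — the
region, not the donor, is the unit. Cross-dataset profile validation is
Spearman's rank correlation of matched regional summaries with a
t-approximation p-value on `n − 2` degrees of freedom.

## Differential stability

For each unordered donor pair, the gene's spatial profile (voxel values of
the dense maps by default; region means as a lighter-weight option) is
rank-correlated over the units both donors share; DS is the unweighted
mean over pairs (15 pairs for 6 donors). Because a dense map is built from
a limited number of samples, each pair's p-value is computed at an
effective sample size equal to the *smaller* of the two donors' sample
counts, not the voxel count — using the voxel count would badly overstate
the information content of an interpolated map. Pairs sharing fewer than
3 units are excluded with a flag. Decile ranks place a DS value within a
gene library: decile 1 is the top 10%, ties get the better decile.

## Co-expression networks

Spearman correlation is used throughout (robust to outliers and monotone
distortions). The gene-by-gene matrix is computed per donor across that
donor's samples and averaged cellwise over donors; a gene constant within
one donor drops that donor from the affected cells with a flag.

* **Soft thresholding.** For each candidate power the unsigned adjacency
  `|r|^beta` is formed and the scale-free fit index computed: log10
  frequency vs log10 mean connectivity over 10 log-spaced connectivity
  bins, R² signed negative when the slope is positive. The selected beta
  is the smallest with R² ≥ 0.8. Planted-module libraries are *not*
  scale-free, so the criterion often fails there; the pipeline then falls
  back to the conventional unsigned default beta = 6 rather than chasing
  the argmax of a flat R² curve. Unsigned adjacency is the default since
  the sign convention is a free choice here; a signed variant is a
  one-line change (`((1 + r)/2)^beta`) users can apply before
  `tom_similarity()`.
* **Topological overlap.** `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 −
  a_ij)` with zero diagonal internally and unit diagonal reported. The
  implementation is matrix algebra; the test suite checks it against a
  literal triple-loop oracle to 1e-12.
* **Module detection.** Average-linkage clustering on `1 − TOM` with a
  *static* cut, not a dynamic tree cut: deterministic and directly
  testable. The default cut height 0.95 sits just below 1 because the TOM
  dissimilarity between unrelated genes concentrates at 1 in
  soft-thresholded networks while co-expressed genes merge well below it;
  clusters smaller than 5 genes become background (module 0).
* **Enrichment.** Over-representation p-values are upper-tail
  hypergeometric probabilities; Bonferroni adjustment is used across
  tissue-type sets and BH across gene-set collections, matching the two
  contexts in which such tests are conventionally reported. A filter
  utility builds tissue gene sets from a differential-expression table
  (adjusted p < 0.05 and |log fold change| ≥ 0.58), and a probe-selection
  utility keeps, per gene, the probe with the highest DS.

## Decoding and the social contrast

Decoding correlates (Spearman, over mask voxels) a gene's map with each
term's association Z map; the top-k terms are reported, and a gene's rank
for a term is its position among all library genes' correlations with that
term (ties share the better rank).

The social/non-social contrast scores each labelled term as the **median of
the gene's expression over the term's FDR-suprathreshold voxels**
(association-map FDR p < 0.05, pooled per term without connected-component
segmentation). The phrase "median association Z of each significant
region" would not produce a gene-specific score, so the gene-expression
reading is used — this is the package's key interpretive decision for this
statistic. The observed statistic is Welch's t between social and
non-social term scores; significance comes from randomly reassigning the
category labels to terms (term-level exchangeability; the spatial
structure within each term's map is preserved). The p-value uses add-one
smoothing, `(1 + #{|t*| ≥ |t|}) / (B + 1)`, so it is never 0 and never
below `1/(B+1)`. Terms with no suprathreshold voxel are excluded and
reported.

A practical note from validating this statistic: score medians must be
computed on *continuous* maps. A region-painted volume takes only as many
distinct values as there are regions, which ties the term scores and
piles permutation p-values at 1; interpolated maps do not have this
problem.

## The synthetic generator: what it emulates, what it does not

`make_atlas()` grows an ellipsoidal mask partitioned into contiguous
regions by seeded nearest-centroid growth (ties to the lowest seed).
`simulate_gene_library()` plants co-expression modules: members share a
latent regional profile, mixed so the expected profile correlation equals
`within_module_cor` exactly (`lambda = noise_sd * sqrt(rho/(1−rho))`).
`sample_donor()` draws sample voxels uniformly without replacement and
adds Gaussian measurement noise; `simulate_term_maps()` places each linked
term's active voxels inside its gene's top-expression regions, draws Z
from Normal(z_effect, 1) there and Normal(0, 1) elsewhere, and derives the
FDR p volume by BH over two-sided normal p-values on the mask.

Default study conditions: a 20³ grid with 54 regions (mirroring a
54-region left-hemisphere parcellation), 200 genes with four 10-gene
modules at within-module correlation 0.9, six donors with 363–946 samples
each, measurement noise SD 0.5 on profiles of SD ≈ 2.2, and a 20-term map
library with 10% active fraction at z_effect = 4. Validation studies use
smaller grids (12³) so that replicate counts of 100–500 stay inside a few
seconds; the acceptance script states each problem size alongside the
quantity it reports.

Deliberate simplifications, which bound what passing tests can show about
real data:

* Expression truth is region-constant with i.i.d. Gaussian noise; there is
  no within-region spatial gradient, no spatial autocorrelation beyond the
  parcellation, no probe-level artifacts, batch effects or hemispheric
  asymmetry. One consequence worth knowing: with region-constant truth,
  the effective degrees of freedom of a gene–gene correlation is the
  region count, not the sample count, so null correlations are wider than
  an i.i.d.-sample intuition suggests.
* All donors share one grid; nonlinear registration and its artifacts are
  entirely out of scope.
* Term maps are inputs; nothing about their meta-analytic construction is
  modelled beyond suprathreshold geometry and null calibration.

## Reproducibility

Every generator and every stochastic statistic takes an explicit integer
seed and is a pure function of it; the permutation seed is logged in the
contrast result. Rebuilding a volume from the same inputs is bit-identical.
The acceptance script (`scripts/acceptance.R`) reruns the full pipeline
and the replicate studies from a single command-line seed.
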