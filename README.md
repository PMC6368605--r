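# voxgex

Voxel-level brain gene expression maps, co-expression networks, and
cognitive decoding — an imaging-transcriptomics pipeline in R.

## The problem

Post-mortem brain expression datasets sample each donor at a few hundred
scattered 3D locations, yet most downstream questions — which regions are
enriched, how reproducible a gene's spatial pattern is across donors,
which genes co-express, which cognitive-state maps a gene's distribution
resembles — want a dense, voxel-by-voxel expression map on a common grid.
voxgex implements that workflow end to end for researchers who want a
tested, deterministic, desk-scale implementation of each stage:

1. **Dense maps.** Mask border voxels are labelled with the nearest
   sample's value, the augmented point set is tessellated (3D Delaunay,
   Bowyer–Watson in C++), and each mask voxel receives the barycentric
   linear interpolant of its containing tetrahedron; donor maps are then
   averaged per gene.
2. **Regional enrichment.** Per region, a two-tailed one-sample t-test of
   the donors' region means against the brain-wide average (the mean of
   region means, as a fixed reference μ), Benjamini–Hochberg correction
   across regions, and one-sample Cohen's *d* = |x̄ − μ| / s.
3. **Differential stability.** DS(gene) = mean over all n(n−1)/2 donor
   pairs of Spearman's r between the two donors' maps, with per-pair
   p-values computed at the smaller donor's sample count, and decile ranks
   within the gene library.
4. **Co-expression networks.** Donor-averaged Spearman correlation
   matrices; unsigned adjacency |r|^β with β chosen by the scale-free
   topology criterion (R² ≥ 0.8 on a log–log connectivity fit); the
   topological overlap matrix TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 −
   a_ij); average-linkage module detection with a static cut; and
   hypergeometric gene-set enrichment.
5. **Decoding.** Spearman correlation of a gene map with a library of term
   association Z maps, the gene's rank for each term across the whole
   library, and a permutation contrast (Welch t, term-label permutation,
   add-one smoothed p) of median expression over each term's
   FDR-suprathreshold voxels between "social" and "non-social" terms.

Real inputs of this kind (donor expression atlases, meta-analytic map
libraries) cannot ship with a package, so voxgex includes a first-class
synthetic-data generator with planted regional, modular and term-linkage
structure; every stage is validated against that recoverable ground truth.
See `vignettes/voxgex-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `06_decoding.R`). Stage 1 generates the synthetic study
(20³ grid, 54 regions, 200 genes with four planted 10-gene modules, six
donors at 363–946 samples each, 20 term maps) and caches it; later stages
read the cache. In R, the same thing in one call:

```r
library(voxgex)
pipe <- run_pipeline(seed = 1, n_perm = 5000)
```

Running the workflow prints, among other things:

```
Atlas: 20x20x20 grid, 2440 mask voxels, 54 regions
  donor_1: 910 samples + 656 border pseudo-points -> 9644 simplices
Averaged maps vs planted truth (Spearman): median 0.891, min 0.847
Soft threshold: beta = 6 (criterion met: FALSE)
Detected 4 modules; adjusted Rand index vs planted truth: 1.000
gene_0001-gene_0002 correlation: r = 0.846, rank 4 of 199 (top 2.0%)
Voxel-level DS over 200 genes: median 0.744 (IQR 0.723-0.764)
gene_0001: DS = 0.713 over 15 pairs, library decile 9
gene_0001: top decoded terms: term_01, term_03, term_02, term_05, term_04
Planted term term_01 decoded at rank 1 (r = 0.260)
Social vs non-social contrast: t = 8.65, mean social 8.534 vs non-social 4.487, p_perm = 0.006799 (5000 permutations, seed 6)
```

Reading those numbers: the six donors' scattered samples reconstruct the
planted regional truth well (median map–truth rank correlation 0.89); the
four planted co-expression modules are recovered exactly (ARI 1.0); a
within-module gene pair ranks in the top 2% of one gene's library-wide
correlations; differential stability across the 15 donor pairs is ≈ 0.74
under the default measurement noise (identical donors would give 1); the
term map planted on the target gene's high-expression regions is its top
decoded term; and median expression over the social terms' suprathreshold
voxels exceeds the non-social terms' with permutation p ≈ 0.007. The
scale-free criterion is honestly *not* met — planted-module libraries are
not scale-free — so the network stage falls back to the conventional
unsigned power β = 6 and says so.

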