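# SmoothFPCA

Smooth functional principal component analysis for scalar fields on 3D
tetrahedral meshes, with the seed-based functional-connectivity (FC)
pipeline and two-group score statistics built around it.

## What problem this solves, and for whom

Seed-based FC mapping turns each subject's fMRI into a spatial map: the
Fisher z-transformed Pearson correlation between every grey-matter
location and the mean BOLD signal of a seed region. Given *n* subjects'
maps at the *m* nodes of a tetrahedral mesh of the grey-matter volume
(an *n* × *m* matrix **Z**), neuroimagers want the dominant modes of
variation of these maps and whether subjects' expressions of them (the
PC scores) separate clinical groups.

Standard multivariate PCA ignores that the maps live on an anatomical
domain. SmoothFPCA estimates each component as a smooth function *f* on
the meshed volume *D* by the penalized rank-1 criterion

```
minimize over (f, s):   Σ_ij { z_ij − s_i f(p_j) }²  +  λ sᵀs ∫_D (Δf)²
```

solved by alternating exact minimizations (scores given *f*, then a
penalized smoothing solve for *f* given *s*), with the squared-Laplacian
penalty discretized by linear finite elements in a mixed formulation
with mass lumping. Because the penalty integrates over the domain,
smoothing follows the anatomy: locations close in space but far apart
within the volume (opposite banks of a sulcus) are not smoothed
together. Components are extracted sequentially by deflation; λ = 0
reproduces multivariate PCA exactly. The group layer provides
Mann–Whitney rank-sum tests (exact by enumeration for small untied
samples), leave-one-out LDA with ROC AUC, covariate checks, and median
expression maps.

The package is self-validating: synthetic mesh/data generators plant
known smooth modes, group score shifts and prescribed seed-correlation
fields, so the whole chain is testable without any imaging data.

## Worked example

A synthetic two-group study on a 10³-cell cube mesh: three planted
smooth modes, a group shift of 1.5 sd on mode 2, i.i.d. node noise.

```r
library(SmoothFPCA)

mesh <- makeCubeMesh(10)
mesh
#> TetMesh: 1331 nodes, 6000 tetrahedra, 8 labelled regions
#>   bounding box [0, 1] x [0, 1] x [0, 1] mm

ops  <- femOperators(mesh)
sim  <- simulateMaps(mesh, seed = 1)   # defaults: 30 + 30 subjects, K = 3 modes
comps <- sfpca(sim$Z, ops, lambda = 0.1, K = 4)
comps[[2]]
#> SmoothPC: m = 1331 nodes, n = 60 subjects, lambda = 0.1
#>   roughness 0.2319; 11 iteration(s), converged; cumulative EV 15.56%

res <- groupComparison(comps, sim$labels, alpha = 0.01)
print(res$perComponent, digits = 3)
#>   component median1 median2   U        p significant
#> 1         1  0.3494 -0.5107 470 7.75e-01       FALSE
#> 2         2  1.3057 -0.7373 795 3.52e-07        TRUE
#> 3         3  0.1338  0.1431 523 2.86e-01       FALSE
#> 4         4  0.0513 -0.0641 521 3.00e-01       FALSE
res$auc
#> [1] 0.844
```

Reading the output: each fitted component carries its node field
(`componentField()`, unit norm), subject scores (`componentScores()`),
roughness and cumulative explained variance. Here only component 2 —
the one carrying the planted group shift — separates the groups at
α = 0.01 (rank-sum p = 3.5e-07), the unshifted components do not, and
the leave-one-out LDA on all four score columns discriminates diagnosis
with AUC 0.844. The recovered fields match the planted modes with
|cos| ≥ 0.99 in this run. Components export to legacy VTK
(`writeVTK()`) for volume rendering.

Connectivity maps from BOLD data follow the same grammar:

```r
seed <- selectSeed(nodeLabels(mesh), 1)      # atlas label -> SeedRegion
z    <- connectivityMap(bold, seed)          # highpass -> seed mean -> Pearson -> Fisher z
Z    <- buildZ(listOfMaps)                   # n x m ConnectivityMatrix
```

A thin command-line wrapper (`inst/cli/sfpca-cli.R`) exposes the stages
as `simulate | fcmap | pca | compare` subcommands over plain-text
artifacts (.node/.ele meshes, TSV matrices, NIfTI volumes, JSON
manifests).

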