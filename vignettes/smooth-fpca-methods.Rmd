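---
title: "Smooth functional PCA on tetrahedral meshes: model, algorithm and design choices"
author: "SmoothFPCA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth functional PCA on tetrahedral meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SmoothFPCA)
```

## The problem

Seed-based functional connectivity summarizes each subject's resting or
task fMRI as a spatial map: the Fisher z-transformed Pearson correlation
between every grey-matter location and the mean BOLD signal of a seed
region. Stacking $n$ subjects' maps evaluated at the $m$ nodes of a
tetrahedral mesh of the grey-matter volume gives an $n \times m$ matrix
$Z$. The scientific question is what the dominant *modes of variation*
of these maps are, and whether subjects' expressions of those modes
(their scores) differ between clinical groups.

Ordinary multivariate PCA (MV-PCA) treats the $m$ nodes as exchangeable
coordinates: its loadings are noisy and ignore that the maps are
functions on a 3D anatomical domain. SmoothFPCA instead estimates each
component as a *smooth function* $f$ on the meshed volume $D$, by
minimizing the penalized rank-1 criterion

$$
\sum_{j=1}^m \sum_{i=1}^n \{ z_{ij} - s_i f(p_j) \}^2
  \;+\; \lambda\, s^\top s \int_D (\Delta f)^2,
$$

over node fields $f$ and score vectors $s = (s_1, \dots, s_n)^\top$.
The penalty integrates the squared Laplacian of $f$ over the *domain*,
not over the Euclidean bounding box: smoothing borrows strength only
along paths inside the mesh. Locations that are close in space but far
apart within the domain — the two banks of a sulcus, or the two arms of
the C-shaped test geometry shipped with the package — are not smoothed
together. This domain compliance is the method's reason to exist, and
the C-shape test (`makeCShapeMesh()`) demonstrates it directly: a
planted contrast of opposite sign on the two arms of the C survives the
fit with essentially no leakage across the slit.

## Finite-element discretization

$f$ is represented as a piecewise-linear (P1) finite-element function on
the tetrahedral mesh, identified with its vector of node values. The
package assembles:

* the **consistent mass matrix** $M$, element blocks
  $(V_e/20)(1+\delta_{ij})$;
* the **lumped mass** $M_L = \mathrm{diag}(\text{row sums of } M)$,
  whose entries sum to the domain volume;
* the **stiffness matrix** $A$, element blocks
  $V_e \nabla\phi_i \cdot \nabla\phi_j$ with constant per-element basis
  gradients, so $A$ is symmetric positive semidefinite and $A\mathbf{1} = 0$.

Because $\Delta f$ of a piecewise-linear function is not directly
defined, the biharmonic penalty is discretized by a **mixed
formulation**: introduce the auxiliary variable $g \approx -\Delta f$
through $M g = A f$, giving the penalty matrix
$P = A^\top M_L^{-1} A$ after mass lumping. Lumping keeps $P$ sparse
(the stencil of $A^2$), so the inner smoothing solve
$(I + \lambda P) f = u$ factorizes once per $\lambda$ and is reused
across all iterations and components. The equivalent $2\times 2$ block
system $\{f + \lambda A g = u;\ M g = A f\}$ is also implemented
(`smoothField(..., method = "mixed")`): with $M = M_L$ it agrees with
the normal-equation route to solver tolerance (asserted in tests), and
with the consistent $M$ it provides a slightly different quadrature of
the same penalty, used as a cross-check on smooth fields.

**Boundary conditions** are homogeneous natural (Neumann) ones — nothing
is imposed on the boundary, which is what the weak form gives when no
constraint is added. Consequently constants are exactly in the penalty's
null space ($P\mathbf{1} = 0$) and `roughness()` vanishes iff the field
is constant on the (connected) mesh.

The discretization is validated against closed forms: on the reference
tetrahedron, mass entries $1/60$ and $1/120$ and stiffness entries
$1/2, -1/6, 1/6, 0$; on refined unit-cube meshes the roughness of
$\cos(\pi x)$ converges monotonically to the analytic
$\int_D (\Delta f)^2 = \pi^4/2 \approx 48.70$ (observed: $45.26$,
$47.83$, $48.49$ at $4^3$, $8^3$, $16^3$ cells), and
$\cos(\pi x) + \cos(\pi y)$ to $\pi^4$; both fields are
Neumann-compatible on the cube, which is why the analytic values apply.

**Data fidelity** is the plain nodal sum of squares, not a mass-weighted
norm: the criterion above is written as a sum over nodes, with one
observation per node, so the evaluation operator is the identity.
Off-node observation locations are out of scope.

## The alternating algorithm

Setting the gradients of the criterion to zero gives the two exact
update steps the implementation alternates:

* **score step** ($f$ fixed):
  $s_i = (Z f)_i / (f^\top f + \lambda f^\top P f)$;
* **component step** ($s$ fixed): $f$ solves
  $(I + \lambda P) f = Z^\top s / (s^\top s)$ — a penalized smoothing
  of the score-weighted mean map.

Both were re-derived by differentiating the criterion and are verified
in the test suite against a numerical optimizer (BFGS over the joint
$(f, s)$ vector) on a tiny 8-node instance: the alternation's fixed
point attains the optimizer's minimum.

After each sweep $f$ is renormalized to $\lVert f\rVert_2 = 1$ with the
magnitude folded into $s$. The criterion is invariant under
$(f, s) \mapsto (f/c,\, c\,s)$, so this costs nothing and pins down the
scale. Remaining conventions:

* **Normalization** is the Euclidean node norm, not $f^\top M f = 1$,
  so that the $\lambda = 0$ fit coincides *exactly* with the first
  multivariate PC — the property the test suite exploits as an oracle
  (agreement with truncated SVD to $|\cos| \ge 1 - 10^{-8}$).
* **Sign**: $(f, s)$ is flipped so the largest-magnitude entry of $f$
  is positive; ties break at the lowest node index.
* **Initialization**: the first multivariate PC of the current data
  matrix (the leading right singular vector), for the first and every
  deflated component alike.
* **Convergence**: stop when the relative change of both $f$ and $s$
  falls below $10^{-6}$, or at 50 sweeps with a warning. The objective
  is recorded every sweep and is non-increasing by construction
  (each step is an exact coordinate minimization); tests assert this on
  every fitted component.

**Subsequent components** are obtained by sequential deflation: after
fitting $(f_k, s_k)$ the rank-1 term $s_k f_k^\top$ is subtracted and
the same algorithm runs on the residual. No orthogonality is enforced
across components (the criterion does not imply it); for $\lambda = 0$
the sequence nevertheless reproduces the SVD exactly.

**Explained variance** is reported as the residual Frobenius fraction
$EV_k = 1 - \lVert Z_c - \sum_{j \le k} s_j f_j^\top \rVert_F^2 /
\lVert Z_c \rVert_F^2$, cumulative and non-decreasing in $k$. This
definition reduces to the usual singular-value identity for MV-PCA (a
tested equivalence). Scores are *not* re-estimated jointly after all
$K$ components; deflation is sequential, exactly as fitted.

**Smoothing parameter.** $\lambda$ trades data fidelity against
roughness: $\lambda \to 0$ recovers the multivariate PC, large
$\lambda$ drives the component toward the constant null space. The
package default is $\lambda = 10^{-1}$, the value used throughout the
validation suite; fitted roughness is non-increasing in $\lambda$
(tested over $\lambda \in \{10^{-3}, 10^{-1}, 10\}$). No automatic
selection (GCV or similar) is provided — $\lambda$ is a user parameter.

## Connectivity-map construction

`connectivityMap()` chains the four steps applied per subject: (1)
node-wise zero-phase highpass — mean removal followed by a 4th-order
Butterworth applied forward and backward (`signal::filtfilt`), cutoff
0.01 Hz by default, which removes linear drift and slow noise with no
phase distortion (measured amplitude gain at TR = 2 s: $\ge 0.999$ at
0.1 Hz, $\le 0.01$ at 0.002 Hz); (2) unweighted mean over the seed
nodes; (3) Pearson correlation of every node with the seed mean —
nodes with zero temporal variance get $\rho = 0$ and a QC flag rather
than being dropped, so $Z$ stays $n \times m$; (4) Fisher
$z = \mathrm{atanh}(\rho)$ with $\rho$ clipped to
$\pm(1 - 10^{-7})$ so exact $\pm 1$ maps to a large finite value.
The Butterworth realization is one deliberate choice among several
defensible fMRI highpass filters, and it is isolated behind
`highpassFilter()` so it can be swapped without touching anything else.

Volumes are read from NIfTI; mesh nodes are associated to voxels by
applying the inverse header affine and rounding to the nearest voxel
(no interpolation — each node corresponds to one BOLD series); any
node falling outside the volume is an error, not a silent drop.

## Group comparison

Scores are compared between the two diagnostic groups with a two-sided
Mann–Whitney rank-sum test (the groups are independent samples) at
$\alpha = 0.01$, with **no multiple-testing correction** — raw
p-values are compared to the threshold, and the report flags each
component. For $n_1 + n_2 \le 12$ without ties the p-value is exact by
full enumeration of rank assignments; otherwise a normal approximation
with tie-corrected variance, continuity correction and an Edgeworth
excess-kurtosis term is used. The Edgeworth term matters: without it
the approximation can differ from the exact enumeration by 0.015
around the distribution's shoulders, while with it the two routes agree
within 0.01 for all untied configurations with at least 3 per group and
9 or more in total (asserted exhaustively in the tests). Simulated
type-I error at $\alpha = 0.01$ over 1000 null replicates of 30 vs 30
falls within $[0.004, 0.02]$.

Discrimination is assessed by two-class LDA with pooled within-group
covariance and empirical priors, in leave-one-out cross-validation;
each subject's held-out linear discriminant value (signed toward the
second group level) is fed threshold-free to the rank-based AUC (ties
counted $\tfrac12$). Under label permutations the mean LOO AUC sits
slightly *below* 0.5 (typically 0.42–0.46 here): leave-one-out
cross-validation is pessimistically biased under the null, a known
property of LOO error estimates, not a defect of the AUC computation.
Covariate checks mirror the score tests: rank-sum p per component for
sex, Pearson correlation with age. Per-group "typical expression" maps
are $\mathrm{median}(s_{\text{group}}) \cdot f$, exportable as VTK
point data. QDA, SVMs and random forests are not implemented.

## The synthetic generator and what it does (not) show

`simulateMaps()` emulates the structure the decomposition assumes:
$K = 3$ orthonormal smooth modes (low-order Neumann-compatible cosine
products, Gram–Schmidt-orthonormalized on node values), per-subject
Gaussian scores, a between-group mean shift on mode 2 of $1.5$ times
that mode's score sd (groups at $\mp\delta/2$), and i.i.d. node noise
with $\sigma = 0.2$. The per-mode score sds default to $(3, 1.5, 1)$:
they must be strictly ordered for components to be identifiable by
variance, *including after* the group shift inflates mode 2's total
spread to $\sqrt{1.5^2 + (2.25/2)^2} \approx 1.87$ — hence the gap to
both neighbors. The placement of the effect on mode 2 mirrors the
common situation where the discriminating mode is not the largest one,
without claiming equivalence to any particular dataset.

`simulateBold()` synthesizes node series with a prescribed
seed-correlation field $\rho^*$: a standardized latent signal
$\sigma(t)$ and independent per-node noise $\eta_j(t)$ are drawn as
band-limited Fourier noise (random cosine/sine coefficients on
0.02 Hz to just below Nyquist — so the analysis highpass passes them
essentially unchanged and there are no filter transients), and node $j$
receives $\rho^*_j \sigma + \sqrt{1 - \rho^{*2}_j}\,\eta_j$; seed nodes
carry $\sigma$ plus small jitter. The population correlation with the
latent signal is exactly $\rho^*_j$, so the whole
highpass-correlate-Fisher chain can be scored against truth (RMSE
$\approx 0.044$ at $T = 300$, TR = 2 s, versus the 0.08 test bound).

What passing these tests shows: the estimator recovers smooth planted
structure at realistic noise, respects the domain geometry, and the
statistical layer has correct size and reasonable power. What it does
**not** show: robustness to realistic fMRI noise (physiological
rhythms, motion residue, spatially correlated scanner noise, drift
families), to registration error, or to atlas mis-labeling — the
generator deliberately models none of these, and upstream preprocessing
(motion correction, registration, nuisance regression) is out of scope
entirely.

## Validation problem sizes

The shipped validation uses unit-cube meshes of $4^3$–$16^3$ cells
(125–4913 nodes), the default study condition being a $10^3$-cell cube
($m = 1331$) with $n = 30 + 30$ subjects and 20 generator seeds;
connectivity-map checks use an $8^3$ mesh with $T = 300$ volumes and 10
seeds. These sizes keep every mode of variation and failure mode
visible while the full suite runs in well under a minute; the estimator
itself is sparse end-to-end (one Cholesky factorization of
$I + \lambda P$ per $\lambda$, reused across components and
iterations) and scales to meshes with tens of thousands of nodes, the
regime of a full grey-matter discretization.

## Known limitations

* One value per node: no off-node observation locations, no
  mass-weighted fidelity.
* P1 elements only; no surface (2D manifold) FEM; meshes are consumed,
  never generated from images.
* No smoothing-parameter selection; no orthogonality across components;
  no sparse or robust PCA variants.
* Connectivity is plain Pearson to a seed mean; partial correlation and
  nonlinear dependence measures are not implemented.
* The rank-sum normal route's Edgeworth constant assumes untied data;
  with heavy ties the tie-corrected variance is used but the kurtosis
  term remains the untied one (the exact route never applies to tied
  data either).
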