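---
title: "Dense surface landmarking and twin heritability maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense surface landmarking and twin heritability maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

facetwin implements an automated phenotyping stack for ensembles of similar
3D surfaces — the motivating application is frontal facial scans of twins —
and the statistical machinery to turn dense surface phenotypes into
per-landmark heritability maps:

1. mesh handling and rigid alignment (fiducial Kabsch + ICP),
2. discrete geodesic geometry (distances, exponential and logarithmic maps),
3. an entropy-based ensemble correspondence optimizer that places `M`
   landmarks per surface, uniformly within each surface and in point-wise
   correspondence across surfaces,
4. curvature phenotypes at the landmarks (mean curvature MC, Gaussian
   curvature GC, curvedness CU, shape index SI),
5. classical distance traits between named fiducial landmarks (straight-line
   and geodesic), and sparse-PCA regional traits,
6. twin variance-components estimation (ACE/AE/E) by maximum likelihood with
   AIC model selection and a saturated-model goodness-of-fit test.

Real twin facial scans are restricted; the package therefore ships a
synthetic twin-face generator with a fully known genetic architecture, used
by every test.

# Mesh model and alignment

A surface is a `triangle_mesh`: vertex coordinates (mm) and counterclockwise
triangular faces. Invariants enforced on construction: indices in range, no
zero-area faces, edge-manifold with boundary. Vertex normals are
area-weighted means of incident face normals. Orientation is global: the
mean face normal must point along a configured axis (default `+z`, the
camera axis of a frontal scan); for closed surfaces, where the mean normal
vanishes, the signed volume decides. All curvature signs inherit this
convention, so convex-outward structures (nose tip, chin) are positive.

Pose normalization mirrors the usual scan-processing protocol: a proper
rigid Kabsch fit on three labelled fiducials (e.g. outer eye corners and
nasion) gives a rough orientation, then point-to-point ICP
(vertex-to-nearest-vertex matching, least-squares rigid update, stop when
the matched RMSD improves by less than `1e-6` of the bounding-box diagonal)
refines it. Accepted ICP iterations never increase the matched RMSD. The
reference surface is an explicit argument — there is no canonical choice.

Landmarks are continuous surface points (face index + barycentric weights),
not mesh vertices.

# Discrete geodesics

All on-surface distances go through a Steiner-augmented graph: every mesh
edge receives `n_steiner` evenly spaced extra nodes and all node pairs
sharing a face are joined by their in-face chord (which lies on the
surface). Dijkstra on this graph overestimates the true geodesic by an
amount that falls quickly with `n_steiner`; with the default 3 points per
edge the pole-to-pole distance on a subdivision-4 icosphere is within 0.05%
of $\pi$, comfortably inside the package's 0.5% accuracy contract. Query
points in face interiors connect to their face's nodes by exact chords.

Two refinements matter in practice:

* **Straight-chord certificate.** Euclidean distance is a lower bound on
  geodesic distance. If the straightest-geodesic trace shot from `a` along
  the (tangent) chord direction for exactly the chord length lands on `b`,
  the lower bound is attained and the distance is exact. This makes flat and
  developable configurations exact to machine precision, which the
  distance-trait contract (EDT = GDT on flat surfaces) relies on.
* **Unfolded log map.** `log_map(a, b)` recovers the Dijkstra node path,
  unfolds the visited face strip isometrically into the plane of `a`'s face
  (hinge rotations about shared edges), and takes the direction to the
  unfolded image of `b`, with the norm set to the geodesic distance. On the
  sphere the initial direction is within 2 degrees of the analytic
  great-circle tangent at test resolution.

`exp_map` shoots a straightest geodesic: straight inside each face,
continuing straight in the unfolding across interior edges (rotation of the
direction about the shared edge by the dihedral angle). At an open boundary
the path is clipped and flagged. Paths through vertices are disambiguated by
nudging the running point toward the face centroid by a relative `1e-9` —
geometrically negligible, numerically decisive for corner starts.

# The ensemble correspondence optimizer

Surfaces `j = 1..N` carry landmark sets `x_i^j`, `i = 1..M`. Concatenating a
surface's landmarks gives its shape vector `z_j` in `R^{3M}`. The optimizer
descends the combined cost

$$Q = H(Z) \;-\; \sum_{j=1}^N H(P_j),$$

where `H(Z)` is the Gaussian-model entropy of the shape-vector sample (low =
compact shape distribution = good correspondence) and `H(P_j)` is the sample
entropy of the landmark distribution on surface `j` (high = uniform
coverage). Both weights default to 1 and are exposed in the configuration.

**Shape term.** With centered data matrix `Y` (`3M x N`) and sample
covariance eigenvalues $\lambda_k$,
$H(Z) = \tfrac12 \sum_k \log(\lambda_k + \alpha)$, computed through the
`N x N` dual Gram matrix; the `3M - N` eigenvalues beyond the sample rank
contribute $\log\alpha$ each. The gradient with the mean held fixed is
$G = Y\,(Y^\top Y/(N{-}1) + \alpha I)^{-1}/(N{-}1)$ — exactly the
derivative of the log-determinant entropy by the Woodbury identity, which
the test suite verifies against central finite differences. Each landmark's
3-vector of `G` is projected onto its face plane before use.

**Uniformity term.** Per-surface densities are geodesic Gaussian kernel
estimates
$\hat p(x_i) = \frac{1}{M-1}\sum_{k\neq i}
\frac{1}{2\pi\sigma^2}\exp(-d_g(x_i,x_k)^2/2\sigma^2)$, and the
per-landmark gradient is the weighted mean of log maps toward the
neighbors, scaled by $1/\sigma^2$; the uniformity move is its negation
(repulsion). Kernels are truncated at `4 sigma` (contribution below
`e^-8`), which permits a Euclidean prefilter because chords never exceed
geodesics.

**Numerical design choices.** Several choices were genuinely open and are
worth recording:

* *Bandwidth schedule.* `sigma = sqrt(mean surface area / (pi * M))` — the
  mean inter-landmark spacing — recomputed at each splitting level.
* *Adaptive per-landmark bandwidth inside the optimizer.* Right after a
  split, twins sit at `0.1 sigma` from their parents; with a fixed kernel
  their mutual repulsion is diluted by every neighbor within `4 sigma` and
  pair separation stalls. The optimizer therefore clamps each landmark's
  bandwidth to its nearest-neighbor distance (bounded to
  `[sigma/100, sigma]`), making separation proceed at a scale-free rate.
  The exported `surface_density()` and `uniformity_gradient()` keep the
  fixed-bandwidth definitions; the adaptation is an internal numerical
  device of `gessa_step()`.
* *Preconditioning.* The two terms have incompatible natural scales. The
  uniformity move is taken as $\sigma_i^2$ times the entropy gradient (a
  length). The correspondence update is scaled by $\alpha (N-1)$, which
  turns plain gradient descent into a per-eigendirection contraction of the
  shape covariance by $\gamma\,\alpha/(\lambda+\alpha)$: bounded by
  $\gamma$, strong on sub-noise directions, gentle on genuine shape
  variance.
* *Regularizer floor.* The automatic $\alpha$ is
  `max(1e-4 * trace/(3M), 0.1 sigma^2)`. The floor declares cross-surface
  variation below about a third of the landmark spacing to be sampling
  noise. It also bounds the log-determinant gradient, which otherwise grows
  without limit as the shape variance shrinks and drives the ensemble into
  the degenerate solution where all landmarks collapse onto one
  anatomical point.
* *Step size and backtracking.* `gamma = 0.1` by default. A step that fails
  to decrease `Q` is retried with halved `gamma` (5 times) and then
  rejected, so the cost is non-increasing across accepted steps; the step
  size recovers by a factor 1.5 per successful iteration so one noisy
  evaluation cannot permanently stall the descent.
* *Splitting.* Each parent stays in place; its child is offset by an
  exponential-map step of length `0.1 sigma` in a direction drawn once per
  landmark index **in world coordinates** and projected onto each
  landmark's face plane. Because corresponding faces are nearly parallel
  across pre-aligned surfaces, the offsets are nearly parallel too and the
  split adds no spurious cross-surface variance (an early implementation
  that drew directions in per-face local frames was quietly destroying the
  correspondence at every split). Children `2k-1, 2k` descend from parent
  `k`.
* *Schedule.* One random seed landmark per surface (area-weighted, seeded),
  then alternate optimization and splitting until `M_target = 2^L`. Only
  powers of two are accepted: arbitrary targets would require a partial
  split rule with no principled ordering. A level ends after
  `iters_per_level` iterations or when `|dQ| < 1e-6 |Q|` five times in a
  row. `iters_per_level` may be a per-level vector; coarse levels are cheap
  and are where the correspondence anchor is established, so front-loading
  iterations there is the efficient configuration.
* *Distance fidelity inside the optimizer.* Landmark-pair distances come
  from a once-per-mesh vertex-to-vertex Steiner-graph matrix with
  per-endpoint chord corrections; sub-edge-length separations use the chord
  itself, with a linear blend over `[h, 2h]` (`h` = mean edge length) so
  the estimator is continuous — a discontinuity there puts spurious noise
  into the backtracking cost. Log maps in the kernel sums use the
  tangent-plane chord rescaled to geodesic length, exact on the planar
  configurations where the gradient oracles run and first-order accurate at
  kernel range on smooth surfaces.

# Curvature phenotypes

At each landmark the symmetric 2x2 shape operator `S` is fitted by least
squares from finite differences of unit vertex normals against tangent-plane
displacements (`dN ~ S dX`) over the mesh vertices within a radius of twice
the landmark spacing (`2 sqrt(mean area/(pi M))`); neighborhoods starved of
vertices near an open boundary grow by factors of 1.5 until at least five
vertices are found. Eigenvalues give `k_max >= k_min`, with the
outward-normal sign convention (sphere of radius `r`: both `+1/r`).

The four indices are the standard combinations: `MC = (k_max + k_min)/2`,
`GC = k_max k_min`, `CU = sqrt((k_max^2 + k_min^2)/2)`, and the shape index
`SI = (2/pi) atan((k_max + k_min)/(k_max - k_min))` in `[-1, 1]` (dome +1,
convex cylinder +0.5, saddle 0, cup -1). At umbilic points, where SI is
formally undefined, it is set to `sign(MC)`. MC and CU scale as 1/length, GC
as 1/length^2 and SI is scale-free, which the suite checks as an
equivariance property.

# Distance and regional traits

Seventeen standard fiducials (glabella, nasion, pronasale, subnasale,
gnathion, and the bilateral alare, exo/endocanthion, zygion, cheilion,
gonion) are located once on the average face — each labelled pick maps to
its nearest average-face landmark, ties to the lowest index — and then
transfer to every subject through the index correspondence. Ten classical
traits (face heights, nasal protrusion, and the nose, intercanthal,
biocular, zygomatic, mandible and mouth widths) are measured both as
straight-line distances (EDT) and as on-surface geodesic lengths (GDT);
EDT <= GDT always, with equality on flat geometry.

Age enters in one of two equivalent ways: as a covariate in the mean model
of the univariate twin fits, or regressed out of the trait matrix (OLS per
column) before multivariate analysis.

Regional traits are sparse principal components: sequential rank-one
maximization of explained variance subject to unit L2 norm and an L1-ball
bound (soft-thresholded power iteration, threshold found by binary search),
followed by rank-one deflation. With the bound at its maximum `sqrt(M)` the
first component reproduces dense PCA; at 1 it degenerates to a single
landmark. Explained variance of component `k` is `var(scores_k)` over the
total variance of the original matrix; orthogonality between sparse
components is not enforced (no sparse PCA guarantees it). Loadings are
visualized as landmark maps by absolute value — a component and its negation
are the same trait.

# Twin variance-components estimation

Complete pairs are bivariate-normal observations with common variance
`a^2 + c^2 + e^2` and twin covariance `a^2 + c^2` (MZ) or `a^2/2 + c^2`
(DZ); the mean is `mu + beta * age` per twin. Heritability is
`h2 = a^2/(a^2 + c^2 + e^2)` (`= a^2/(a^2 + e^2)` in the AE model, 0 in E).

Implementation notes:

* Variance components are log-parameterized (path coefficients nonnegative
  by construction) and the data are standardized internally, making `h2`
  exactly invariant to affine trait rescaling. Optimization is Nelder-Mead
  from a moment start (`a2 = 2(cov_MZ - cov_DZ)` etc.), with the
  closed-form E fit as a second start and as a nesting anchor; jittered
  restarts fire only if the optimum falls below the anchor. This replaces a
  blind multi-start scheme: the moment start makes random restarts almost
  always redundant and the mass-univariate loop several times faster.
* The E model and the saturated model (per zygosity: two free means, two
  free variances, one free covariance; 10 parameters, +1 for a shared age
  slope) have closed-form ML when age is absent; with age the slope is
  profiled by one-dimensional optimization over closed-form inner moments.
* Model selection fits ACE, AE and E and takes the minimum AIC
  (`-2 loglik + 2 k`), ties to fewer parameters; E is always retained in
  the ladder as the error-only floor. Goodness of fit is the
  likelihood-ratio test of the winner against the saturated model.
* Zero-heritability testing uses the AE-vs-E likelihood ratio with the
  boundary correction (a variance component tested on its boundary has a
  50:50 mixture of a point mass at zero and a 1-df chi-square as its null);
  the uncorrected 1-df p-values are reported alongside, since either
  convention appears in practice.
* Standard errors come from the inverse numerical Hessian at the optimum,
  with the delta method for `h2`.
* No multiple-testing correction is applied across landmarks; heritability
  maps report raw per-landmark estimates, with the goodness-of-fit p-value
  available as a reporting mask.

The suite calibrates the machinery: type-I error of the boundary-corrected
test within three binomial standard errors of 5%; mean recovered `h2`
within 0.05 of truth at 500+500 pairs for `h2` in {0.2, 0.5, 0.8};
goodness-of-fit pass rate 95 +/- 2% under a true AE model; and simulated
power at the cohort composition used throughout (197 MZ + 279 DZ pairs)
of at least 95% for `h2 = 0.3`, and for `h2 = 0.8` already at ~75 pairs.

# The synthetic twin-face generator

`make_face_mesh()` builds a subdivided icosphere, removes the back
hemisphere (leaving an open surface with boundary, like a frontal scan),
scales to ellipsoid semi-axes (default 70 x 90 x 80 mm, adult-face scale)
and displaces radially by Gaussian bumps (default: a nose, a chin and two
brow ridges). `simulate_twin_ensemble()` makes each bump amplitude a
standardized ACE score: `A = a G + c C + e U` with `G` shared within MZ
pairs and built as `(G_shared + G_own)/sqrt(2)` for DZ pairs (genetic
correlation exactly 0.5), `C` shared, `U` independent; the amplitude
standard deviation defaults to 30% of the bump mean, which makes bump
variation clearly visible against discretization noise without deforming
the face implausibly. Pair ages follow the adult female twin cohort that
motivates the defaults (normal, mean 59.3 y, sd 9.85 y, truncated at 18),
and `simulate_twin_traits()` provides the same ACE structure for scalar
traits. All generators are bit-reproducible under a fixed seed.

What the generator does **not** emulate: texture, facial expression,
asymmetry, scanning artifacts and manual cropping variability, non-Gaussian
trait distributions, assortative mating or gene-environment interplay.
Passing tests therefore demonstrate that the algorithms are internally
correct and calibrated under the stated model — not that real facial scans
satisfy that model.

# Problem sizes used by the test suite

The tests run the full stack at reduced scale, chosen as the smallest sizes
at which each property is meaningful: geometry oracles on subdivision-2..4
icospheres and small grids; the doubling schedule to the full 4,096
landmarks on a 3-mesh ensemble with one optimization pass per level (the
landmark-count contract does not depend on convergence); estimator
calibration with 1,000 replicates; and the end-to-end discrimination
experiment (one bump with `h2 = 0.8`, one with `h2 = 0`) on 30 MZ + 30 DZ
pairs, 64 landmarks and subdivision-2 meshes across 10 seeds, where the
per-landmark heritability map must rank the heritable bump above the null
bump in at least 9 of 10 seeds.

# Known limitations

* Geodesic distances are graph approximations (with exact-chord and
  endpoint corrections), not exact window-propagation geodesics; accuracy
  is controlled by `n_steiner` and validated at 0.5% on smooth surfaces.
* The correspondence optimizer is a local descent grown from a single seed
  landmark; at aggressive iteration budgets the landmark distribution can
  retain coverage gaps far from the seed. Budget iterations generously at
  coarse levels where they are cheap.
* `exp_map` clips at open boundaries rather than reflecting or sliding;
  clipped updates simply leave a landmark on the rim for the next iteration
  to move.
* The twin models assume bivariate normality and equal environments across
  zygosity; dominance (ADE), multivariate genetic-correlation models and
  extended pedigrees are out of scope.
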