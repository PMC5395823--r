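# facetwin

Dense 3D surface landmarking, curvature phenotyping and twin heritability
maps, in R.

## The problem

Classical heritability studies of face shape relied on a handful of manually
placed landmarks and caliper-style distances, which limits both the spatial
resolution of the phenotypes and the reproducibility of the estimates. With
3D surface scans, a landmarking algorithm can instead place *thousands* of
corresponding points automatically across a cohort, attach a local geometry
phenotype to every point, and estimate the genetic contribution to each one —
yielding a heritability map of the whole surface. facetwin implements that
stack for researchers working with ensembles of similar triangle-mesh
surfaces (the motivating case is frontal facial scans of monozygotic and
dizygotic twin pairs), plus a synthetic twin-face simulator so the entire
pipeline can be exercised, calibrated and tested without access to restricted
scan data.

## What is inside

**Ensemble correspondence by entropy optimization.** Each of the `N`
surfaces is sampled at `M` landmarks; concatenating a surface's landmarks
gives a shape vector `z_j ∈ R^{3M}`. The optimizer descends

```
Q = H(Z) − Σ_j H(P_j)
```

where `H(Z) = ½ Σ_k log(λ_k + α)` is the Gaussian entropy of the shape
sample (minimized → compact shape distribution → good correspondence) and
`H(P_j)` is the entropy of the landmark distribution on surface `j`,
estimated with geodesic Gaussian kernels
`p̂(x_i) = (M−1)⁻¹ Σ_{k≠i} exp(−d_g(x_i,x_k)²/2σ²)/(2πσ²)`
(maximized → uniform coverage). Gradients live in the tangent planes of the
mesh and positions are updated with the exponential map, so landmarks never
leave their surfaces. Landmarks grow by doubling: 1 → 2 → … → `M = 2^L`,
each split offsetting a child by `0.1 σ` in a direction shared across
surfaces.

**Geodesic engine.** Distances come from Dijkstra on a Steiner-augmented
edge graph (within 0.5% on smooth validation surfaces, exact on flat
geometry via a straight-chord certificate); log maps unfold the shortest
path's face strip, and exp maps trace straightest geodesics across edge
unfoldings.

**Phenotypes.** Per-landmark principal curvatures from a least-squares shape
operator on finite normal differences, combined into mean curvature (MC),
Gaussian curvature (GC), curvedness (CU) and shape index (SI); the ten
classical fiducial distance traits in both Euclidean (EDT) and geodesic
(GDT) flavors; sparse-PCA regional traits (L1-constrained rank-one
decomposition) with landmark-map visualization.

**Twin models.** Complete pairs are bivariate normal with variance
`a² + c² + e²` and covariance `a² + c²` (MZ) or `a²/2 + c²` (DZ). ACE, AE
and E are fitted by maximum likelihood (optional age covariate), compared by
AIC, and checked against a saturated model by likelihood-ratio test;
heritability is `h² = a²/(a² + c² + e²)`. Zero-heritability testing uses the
boundary-corrected (50:50 mixture) likelihood-ratio test, and
`power_simulation()` estimates design power by Monte Carlo.

## Worked example

Simulate 15 MZ + 15 DZ twin pairs of synthetic faces in which the nose
bump's amplitude is 80% heritable and the chin bump is pure environment,
place 32 corresponding landmarks per face, phenotype them with mean
curvature, and fit a twin model per landmark:

```r
library(facetwin)

base <- face_params()
arch <- data.frame(a2 = c(0.8, 0, 0, 0), c2 = 0, e2 = c(0.2, 1, 1, 1))
sim <- simulate_twin_ensemble(base, arch, n_mz = 15, n_dz = 15,
                              resolution = 2, noise_sd = 0.1, seed = 1)

res <- run_gessa(sim$meshes, M_target = 32,
                 iters_per_level = c(50, 40, 30, 25, 20, 15), seed = 1)

cm <- curvature_maps(sim$meshes, res$landmarks, subjects = sim$subjects)
her <- mass_univariate(cm$traits$MC, sim$subjects, use_age = FALSE)
head(her[order(-her$h2), c("trait", "model", "h2", "gof_p")], 5)
#>       trait model        h2        gof_p
#> 6   trait_6    AE 0.9196214 3.466672e-08
#> 5   trait_5    AE 0.7716658 4.902211e-01
#> 8   trait_8    AE 0.6232909 8.216759e-01
#> 7   trait_7    AE 0.5422424 2.414491e-01
#> 17 trait_17    AE 0.4911725 4.085816e-01
```

Every landmark gets a selected model, an `h²` estimate and a saturated-model
goodness-of-fit p-value (fits with `gof_p < 0.05`, like the top row above,
are usually masked when mapping). The heritable bump stands out spatially:

```r
avg <- average_landmark_positions(sim$meshes, res$landmarks)
apex <- base$axes * base$bumps[[1]]$center * 1.1
nose <- order(colSums((t(avg) - apex)^2))[1:5]
round(mean(her$h2[nose]), 2)    # mean h2 at the 5 landmarks on the nose bump
#> [1] 0.56
round(mean(her$h2[-nose]), 2)   # mean h2 everywhere else
#> [1] 0.13
```

`heritability_map(her$h2, avg, "map.ply", gof_p = her$gof_p)` writes the
estimates as a colored point cloud plus a CSV. A design power check for a
cohort of 197 MZ + 279 DZ pairs:

```r
power_simulation(n_mz = 197, n_dz = 279, h2_true = 0.3,
                 n_replicates = 200, seed = 1)$rate
#> [1] 1
```

i.e. at that sample size the zero-heritability hypothesis is rejected in
essentially every replicate even for a moderate `h² = 0.3`.

A YAML-driven pipeline (`run_pipeline()`) chains
simulate → align → landmark → curvature → heritability → maps with
provenance records per stage; `inst/scripts/facetwin` wraps it for the
shell. The methods vignette (`vignettes/facetwin-methods.Rmd`) documents the
models, parameter defaults and numerical choices.

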