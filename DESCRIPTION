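Package: facetwin
Title: Dense 3D Surface Landmarking, Curvature Phenotyping and Twin Heritability Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated phenotyping of facial-like 3D triangle-mesh surfaces and
    twin-based heritability mapping. Implements an entropy-based ensemble
    surface sampling algorithm that places dense, point-wise corresponding
    landmarks across a set of similar surfaces using geodesic geometry
    (discrete geodesic distances, exponential and logarithmic maps), derives
    per-landmark curvature phenotypes (mean and Gaussian curvature, curvedness,
    shape index) and classical Euclidean/geodesic distance traits, reduces
    landmark phenotypes to sparse regional components, and estimates additive
    genetic, common and unique environmental variance components (ACE/AE/E
    structural models) from monozygotic and dizygotic twin pairs by maximum
    likelihood, producing per-landmark heritability maps. Includes a synthetic
    twin-face simulator with known variance structure so the whole pipeline can
    be exercised and calibrated without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
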