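# Synthetic twin-face ensembles with known variance structure.
#
# Real twin facial scans are restricted data, so the package ships a
# parametric generator: an ellipsoidal half-shell (open surface, like a
# frontal facial scan) decorated with Gaussian bumps whose amplitudes are
# shared between co-twins according to the classical additive-genetic /
# common-environment / unique-environment (ACE) decomposition: genetic
# correlation 1 for monozygotic pairs and 0.5 for dizygotic pairs.

#' Subdivided icosahedral sphere
#'
#' Unit sphere obtained by repeated midpoint subdivision of an icosahedron and
#' reprojection onto the sphere. Subdivision level `k` yields
#' `10 * 4^k + 2` vertices (level 4: 2562).
#'
#' @param subdivisions number of subdivision rounds.
#' @param radius sphere radius.
#' @return a [triangle_mesh()].
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    ne <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!exists(key, envir = ne, inherits = FALSE)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        assign(key, nrow(v), envir = ne)
      }
      get(key, envir = ne, inherits = FALSE)
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  triangle_mesh(v * radius, f, validate = FALSE)
}

#' Parameters of a synthetic face-like surface
#'
#' @param axes three positive semi-axes (mm) of the base half-ellipsoid: the
#'   defaults (70, 90, 80) give an adult-face-scale shell about 140 mm wide
#'   and 180 mm tall, facing +z.
#' @param bumps list of bump specs, each a list with `center` (location on the
#'   unit sphere, normalized internally), `width` (angular s.d. in radians)
#'   and `amplitude` (fractional radial displacement; 0.1 = 10% outward). The
#'   defaults sketch a nose, chin and two brow ridges.
#' @param noise_sd per-coordinate Gaussian vertex jitter (mm).
#' @return a `face_params` list.
#' @export
face_params <- function(axes = c(70, 90, 80),
                        bumps = list(
                          list(center = c(0, -0.15, 1), width = 0.22,
                               amplitude = 0.10),
                          list(center = c(0, -0.85, 0.55), width = 0.28,
                               amplitude = 0.06),
                          list(center = c(-0.38, 0.45, 0.85), width = 0.22,
                               amplitude = 0.04),
                          list(center = c(0.38, 0.45, 0.85), width = 0.22,
                               amplitude = 0.04)),
                        noise_sd = 0) {
  stopifnot(length(axes) == 3, all(axes > 0), noise_sd >= 0)
  bumps <- lapply(bumps, function(b) {
    stopifnot(b$width > 0)
    b$center <- b$center / sqrt(sum(b$center^2))
    b
  })
  structure(list(axes = as.numeric(axes), bumps = bumps,
                 noise_sd = noise_sd), class = "face_params")
}

#' Generate a synthetic face-like mesh
#'
#' Builds a subdivided icosphere, removes the back hemisphere (z < 0) to
#' create an open surface with boundary, scales to the ellipsoid semi-axes,
#' displaces radially by Gaussian bumps, and optionally jitters vertices.
#' Deterministic for a fixed seed.
#'
#' @param params a [face_params()].
#' @param resolution icosphere subdivision level (4 gives ~1300 vertices on
#'   the half-shell, similar to a decimated facial scan).
#' @param seed RNG seed for the jitter (ignored when `noise_sd = 0`).
#' @return a [triangle_mesh()].
#' @export
make_face_mesh <- function(params, resolution = 4, seed = NULL) {
  stopifnot(inherits(params, "face_params"))
  sph <- icosphere(resolution)
  u <- sph$vertices
  keep_v <- u[, 3] >= -1e-9
  keep_f <- keep_v[sph$faces[, 1]] & keep_v[sph$faces[, 2]] &
    keep_v[sph$faces[, 3]]
  remap <- cumsum(keep_v)
  faces <- matrix(remap[sph$faces[keep_f, ]], ncol = 3)
  u <- u[keep_v, , drop = FALSE]
  r <- rep(1, nrow(u))
  for (b in params$bumps) {
    ct <- pmin(pmax(u %*% b$center, -1), 1)
    theta <- acos(ct)
    r <- r + b$amplitude * exp(-theta^2 / (2 * b$width^2))
  }
  v <- sweep(u, 2, params$axes, "*") * as.numeric(r)
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + matrix(stats::rnorm(length(v), sd = params$noise_sd), ncol = 3)
  }
  triangle_mesh(v, faces, orient_axis = c(0, 0, 1), validate = FALSE)
}

# standardized ACE scores for all pairs: one row per pair, columns twin1/twin2
ace_scores <- function(n_mz, n_dz, a2, c2, e2) {
  a <- sqrt(a2); c_ <- sqrt(c2); e <- sqrt(e2)
  n <- n_mz + n_dz
  g_sh <- stats::rnorm(n); g1 <- stats::rnorm(n); g2 <- stats::rnorm(n)
  cc <- stats::rnorm(n)
  u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
  mz <- seq_len(n) <= n_mz
  # MZ: identical genomes; DZ: G = (shared + own)/sqrt(2) => corr 0.5
  gg1 <- ifelse(mz, g_sh, (g_sh + g1) / sqrt(2))
  gg2 <- ifelse(mz, g_sh, (g_sh + g2) / sqrt(2))
  cbind(twin1 = a * gg1 + c_ * cc + e * u1,
        twin2 = a * gg2 + c_ * cc + e * u2)
}

#' Simulate scalar twin traits under the ACE structure
#'
#' Draws pair trait vectors from the bivariate normal implied by the ACE
#' decomposition (unit total variance before the age effect): MZ covariance
#' `a2 + c2`, DZ covariance `a2/2 + c2`. Ages are shared within a pair and
#' drawn to mimic an adult female twin cohort (normal, mean 59.3, s.d. 9.85,
#' truncated at 18).
#'
#' @param n_mz,n_dz numbers of complete MZ and DZ pairs.
#' @param a2,c2,e2 variance shares; must sum to 1.
#' @param age_beta linear age effect added to both twins (trait units/year).
#' @param mu trait intercept.
#' @param seed RNG seed (optional).
#' @return a twin pair table: data.frame with columns `pair_id`, `zygosity`,
#'   `value_twin1`, `value_twin2`, `age_twin1`, `age_twin2`.
#' @export
simulate_twin_traits <- function(n_mz, n_dz, a2, c2 = 0, e2 = 1 - a2 - c2,
                                 age_beta = 0, mu = 0, seed = NULL) {
  if (abs(a2 + c2 + e2 - 1) > 1e-8)
    stop("variance shares a2 + c2 + e2 must sum to 1")
  if (any(c(a2, c2, e2) < 0)) stop("variance shares must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- n_mz + n_dz
  sc <- ace_scores(n_mz, n_dz, a2, c2, e2)
  age <- pmax(stats::rnorm(n, 59.31, 9.85), 18)
  data.frame(
    pair_id = seq_len(n),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    value_twin1 = mu + sc[, 1] + age_beta * age,
    value_twin2 = mu + sc[, 2] + age_beta * age,
    age_twin1 = age,
    age_twin2 = age)
}

#' Simulate a twin ensemble of synthetic face meshes
#'
#' Per pair, each bump's amplitude is `amplitude + amp_sd * s`, where `s` is a
#' standardized ACE score with the bump's variance shares (`a2 + c2 + e2 = 1`,
#' genetic correlation 1 for MZ and 0.5 for DZ pairs). An optional linear age
#' effect can act on selected bumps. Returns all meshes plus a truth table of
#' realized amplitudes.
#'
#' @param base a [face_params()]; its bump amplitudes are the population
#'   means.
#' @param heritable_spec data.frame with one row per bump and columns `a2`,
#'   `c2`, `e2` (rows must sum to 1) and optionally `amp_sd` (default 30% of
#'   the mean amplitude) and `age_beta` (amplitude units/year, default 0).
#' @param n_mz,n_dz pair counts.
#' @param ages optional vector of pair ages (recycled); drawn from the cohort
#'   age model when `NULL`.
#' @param resolution icosphere subdivision level for each mesh.
#' @param noise_sd vertex jitter per mesh (mm); defaults to `base$noise_sd`.
#' @param seed RNG seed.
#' @return list with `meshes` (list of 2*(n_mz+n_dz) meshes, pair-major:
#'   twin 1 then twin 2), `subjects` (data.frame subject_id, pair_id,
#'   zygosity, twin, age) and `truth` (per pair/twin/bump realized
#'   amplitudes).
#' @export
simulate_twin_ensemble <- function(base, heritable_spec, n_mz, n_dz,
                                   ages = NULL, resolution = 4,
                                   noise_sd = NULL, seed = NULL) {
  stopifnot(inherits(base, "face_params"))
  nb <- length(base$bumps)
  hs <- as.data.frame(heritable_spec)
  if (nrow(hs) != nb) stop("heritable_spec needs one row per bump")
  if (any(abs(hs$a2 + hs$c2 + hs$e2 - 1) > 1e-8))
    stop("per-bump variance shares must sum to 1")
  if (is.null(hs$amp_sd))
    hs$amp_sd <- 0.3 * vapply(base$bumps, `[[`, 0, "amplitude")
  if (is.null(hs$age_beta)) hs$age_beta <- 0
  if (is.null(noise_sd)) noise_sd <- base$noise_sd
  if (!is.null(seed)) set.seed(seed)
  n <- n_mz + n_dz
  if (is.null(ages)) ages <- pmax(stats::rnorm(n, 59.31, 9.85), 18)
  ages <- rep_len(ages, n)
  scores <- lapply(seq_len(nb), function(k)
    ace_scores(n_mz, n_dz, hs$a2[k], hs$c2[k], hs$e2[k]))
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  meshes <- vector("list", 2 * n)
  truth <- list()
  subj <- list()
  for (p in seq_len(n)) {
    for (tw in 1:2) {
      amps <- vapply(seq_len(nb), function(k) {
        base$bumps[[k]]$amplitude +
          hs$amp_sd[k] * scores[[k]][p, tw] +
          hs$age_beta[k] * (ages[p] - 59.31)
      }, numeric(1))
      pars <- base
      for (k in seq_len(nb)) pars$bumps[[k]]$amplitude <- amps[k]
      pars$noise_sd <- 0
      m <- make_face_mesh(pars, resolution = resolution)
      if (noise_sd > 0) {
        m$vertices <- m$vertices +
          matrix(stats::rnorm(length(m$vertices), sd = noise_sd), ncol = 3)
        m <- triangle_mesh(m$vertices, m$faces, orient_axis = m$orient_axis,
                           validate = FALSE)
      }
      id <- (p - 1) * 2 + tw
      meshes[[id]] <- m
      subj[[id]] <- data.frame(subject_id = id, pair_id = p,
                               zygosity = zyg[p], twin = tw, age = ages[p])
      truth[[id]] <- data.frame(pair_id = p, twin = tw, bump = seq_len(nb),
                                amplitude = amps)
    }
  }
  list(meshes = meshes,
       subjects = do.call(rbind, subj),
       truth = do.call(rbind, truth))
}
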