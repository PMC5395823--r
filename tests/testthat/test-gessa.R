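test_that("geodesic kernel density matches its closed form", {
  m <- grid_mesh(4, 4)
  sigma <- 0.2
  two <- nearest_surface_point(m, rbind(c(0.3, 0.5, 0), c(0.3 + sigma, 0.5, 0)))
  expect_equal(surface_density(m, two, 1, sigma),
               exp(-0.5) / (2 * pi * sigma^2), tolerance = 1e-9)
  # coincident pair: kernel at zero distance
  co <- landmark_set(c(2L, 2L), rbind(c(0.3, 0.3, 0.4), c(0.3, 0.3, 0.4)))
  expect_equal(surface_density(m, co, 1, sigma), 1 / (2 * pi * sigma^2),
               tolerance = 1e-12)
  # everything far beyond 8 sigma: density numerically zero
  far <- nearest_surface_point(m, rbind(c(0.05, 0.05, 0), c(0.95, 0.95, 0)))
  expect_lt(surface_density(m, far, 1, sigma = 0.05),
            1e-10 / (2 * pi * 0.05^2))
  expect_error(surface_density(m, nearest_surface_point(m, c(0.5, 0.5, 0)),
                               1, sigma), "at least 2")
})

test_that("uniformity gradient points away from neighbors and cancels by symmetry", {
  m <- grid_mesh(12, 12)
  sigma <- 0.2
  pair <- nearest_surface_point(m, rbind(c(0.4, 0.5, 0), c(0.6, 0.5, 0)))
  g <- uniformity_gradient(m, pair, 1, sigma)$vec
  # -g points from x2 away past x1, i.e. along -x
  mv <- -g / sqrt(sum(g^2))
  expect_lt(max(abs(mv - c(-1, 0, 0))), 1e-9)

  # hexagonal ring around a central landmark: gradient cancels
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- rbind(c(0.5, 0.5, 0),
                cbind(0.5 + 0.15 * cos(th), 0.5 + 0.15 * sin(th), 0))
  hex <- nearest_surface_point(m, ring)
  hex$bary <- facetwin:::as_landmark_set(hex)$bary
  ghex <- uniformity_gradient(m, hex, 1, sigma)$vec
  expect_lt(sqrt(sum(ghex^2)), 1e-8 / sigma)
})

test_that("uniformity gradient matches the finite-difference entropy oracle", {
  m <- grid_mesh(10, 10)
  set.seed(42)
  ls <- random_surface_points(m, 6)
  sigma <- 0.2
  i <- 3
  g <- uniformity_gradient(m, ls, i, sigma)$vec
  # oracle: numeric gradient of the landmark's log kernel density (its
  # contribution to the sampled entropy) with respect to its own position
  xyz <- sp_position(m, ls)
  h <- 1e-5
  fd <- c(0, 0, 0)
  for (dim in 1:2) for (s in c(1, -1)) {
    lsp <- ls
    x2 <- xyz[i, ]; x2[dim] <- x2[dim] + s * h
    pt <- nearest_surface_point(m, x2)
    lsp$face[i] <- pt$face[1]; lsp$bary[i, ] <- pt$bary[1, ]
    fd[dim] <- fd[dim] + s * log(surface_density(m, lsp, i, sigma)) / (2 * h)
  }
  expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 0.05)
  # fast chord variant is exact on a planar mesh
  expect_equal(uniformity_gradient(m, ls, i, sigma, method = "chord")$vec, g,
               tolerance = 1e-12)
})

test_that("shape entropy matches a dense eigendecomposition and its limits", {
  set.seed(7)
  z <- matrix(rnorm(18), 3, 6)               # N=3 surfaces, M=2 landmarks
  alpha <- 0.05
  y <- sweep(z, 2, colMeans(z))
  dense <- 0.5 * sum(log(eigen(crossprod(y) / 2, symmetric = TRUE,
                               only.values = TRUE)$values + alpha))
  expect_equal(shape_entropy(z, alpha), dense, tolerance = 1e-9)
  # identical vectors: all 3M eigenvalues zero
  zsame <- matrix(rep(rnorm(6), each = 4), 4, 6)
  expect_equal(shape_entropy(zsame, alpha), (6 / 2) * log(alpha),
               tolerance = 1e-9)
  # strictly increasing in alpha
  expect_gt(shape_entropy(z, 0.1), shape_entropy(z, 0.05))
  # dual (wide) and direct (tall) paths agree
  zw <- matrix(rnorm(8 * 6), 8, 6)
  yw <- sweep(zw, 2, colMeans(zw))
  densew <- 0.5 * sum(log(pmax(eigen(crossprod(yw) / 7, symmetric = TRUE,
                                     only.values = TRUE)$values, 0) + alpha))
  expect_equal(shape_entropy(zw, alpha), densew, tolerance = 1e-9)
})

test_that("correspondence gradient matches finite differences and projects", {
  set.seed(8)
  z <- matrix(rnorm(4 * 18), 4, 18)          # N=4, M=6
  alpha <- 0.05
  g <- correspondence_gradient(z, alpha)$raw
  h <- 1e-6
  fd <- matrix(0, nrow(z), ncol(z))
  for (a in seq_len(nrow(z))) for (b in seq_len(ncol(z))) {
    zp <- z; zp[a, b] <- z[a, b] + h
    zm <- z; zm[a, b] <- z[a, b] - h
    fd[a, b] <- (shape_entropy(zp, alpha) - shape_entropy(zm, alpha)) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 0.05)

  # identical shape vectors: zero gradient
  zsame <- matrix(rep(rnorm(6), each = 3), 3, 6)
  expect_lt(max(abs(correspondence_gradient(zsame, alpha)$raw)), 1e-12)

  # projected updates are orthogonal to the face normals
  m <- icosphere(2)
  set.seed(3)
  lms <- list(random_surface_points(m, 4), random_surface_points(m, 4))
  zz <- do.call(rbind, lapply(lms, function(l) as.vector(t(sp_position(m, l)))))
  normals <- lapply(lms, function(l) face_normals(m)[l$face, , drop = FALSE])
  cg <- correspondence_gradient(zz, alpha, normals = normals)
  for (j in 1:2) {
    dots <- rowSums(cg$projected[[j]] * normals[[j]])
    expect_true(all(abs(dots) <= 1e-8 *
                      pmax(sqrt(rowSums(cg$projected[[j]]^2)), 1e-12)))
  }
})

test_that("gessa_step repels clustered landmarks and never increases the cost", {
  m <- make_face_mesh(face_params(noise_sd = 0), resolution = 2)
  # single surface, two clustered landmarks: separation must grow
  two <- nearest_surface_point(m, rbind(c(1, 0, 80), c(2.5, 0.5, 80)))
  st <- gessa_state(list(m), list(two), weight_shape = 0, n_steiner = 1)
  d0 <- geodesic_distance(m, surface_point(two$face[1], two$bary[1, ]),
                          surface_point(two$face[2], two$bary[2, ]))
  s1 <- gessa_step(st)
  ls2 <- s1$state$landmarks[[1]]
  d1 <- geodesic_distance(m, surface_point(ls2$face[1], ls2$bary[1, ]),
                          surface_point(ls2$face[2], ls2$bary[2, ]))
  expect_gt(d1, d0)

  # identical surfaces + identical landmarks, uniformity off: fixed point
  m2 <- triangle_mesh(m$vertices, m$faces)
  set.seed(2)
  lsX <- random_surface_points(m, 8)
  stz <- gessa_state(list(m, m2), list(lsX, lsX), weight_uniform = 0,
                     n_steiner = 1)
  sz <- gessa_step(stz)
  expect_identical(sz$state$landmarks[[1]]$bary, lsX$bary)
  expect_identical(sz$state$landmarks[[2]]$bary, lsX$bary)

  # descent with backtracking on a random small ensemble
  meshes <- face_ensemble(3)
  set.seed(9)
  lms <- lapply(meshes, random_surface_points, n = 8)
  std <- gessa_state(meshes, lms, n_steiner = 1)
  q <- facetwin:::gessa_cost(std)
  for (i in 1:8) {
    s <- gessa_step(std)
    expect_lte(s$cost, q + 1e-9 * max(abs(q), 1))
    std <- s$state
    q <- s$cost
  }
})

test_that("splitting doubles landmarks, preserves correspondence and offsets", {
  meshes <- face_ensemble(2)
  set.seed(4)
  # interior landmarks (away from the open boundary, where offsets may clip)
  anchors <- rbind(c(0, -20, 75), c(15, 30, 70), c(-25, 0, 72), c(5, 55, 55))
  lms <- lapply(meshes, nearest_surface_point, xyz = anchors)
  st <- gessa_state(meshes, lms, n_steiner = 1)
  st2 <- split_landmarks(st, epsilon = 0.1)
  expect_equal(vapply(st2$landmarks, function(l) length(l$face), 0L),
               c(8L, 8L))
  for (j in 1:2) {
    old <- sp_position(meshes[[j]], lms[[j]])
    new <- sp_position(meshes[[j]], st2$landmarks[[j]])
    for (k in 1:4) {
      # child 2k-1 is the parent in place
      expect_equal(new[2 * k - 1, ], old[k, ], tolerance = 1e-12)
      # child 2k sits one offset away along the surface
      d <- geodesic_distance(meshes[[j]],
                             surface_point(st2$landmarks[[j]]$face[2 * k - 1],
                                           st2$landmarks[[j]]$bary[2 * k - 1, ]),
                             surface_point(st2$landmarks[[j]]$face[2 * k],
                                           st2$landmarks[[j]]$bary[2 * k, ]))
      expect_lt(abs(d - 0.1 * st$sigma), 0.02 * st$sigma)
    }
  }
  # M = 1 -> M = 2
  st1 <- gessa_state(meshes, lapply(meshes, random_surface_points, n = 1),
                     n_steiner = 1)
  expect_equal(length(split_landmarks(st1)$landmarks[[1]]$face), 2L)
})

test_that("run_gessa follows the doubling schedule deterministically", {
  meshes <- face_ensemble(2)
  expect_error(run_gessa(meshes, M_target = 20), "power of two")
  expect_error(run_gessa(meshes[1], M_target = 4), "at least 2")
  res <- run_gessa(meshes, M_target = 32, iters_per_level = 2, seed = 7,
                   n_steiner = 1)
  expect_equal(vapply(res$landmarks, function(l) length(l$face), 0L),
               c(32L, 32L))
  expect_equal(sort(unique(res$log$M)), 2L^(0:5))
  expect_equal(max(res$log$level), 5)       # 2^5 = 32
  res2 <- run_gessa(meshes, M_target = 32, iters_per_level = 2, seed = 7,
                    n_steiner = 1)
  expect_identical(res$landmarks, res2$landmarks)
})

test_that("identical meshes converge to coincident correspondences", {
  m <- make_face_mesh(face_params(noise_sd = 0), resolution = 2)
  m2 <- triangle_mesh(m$vertices, m$faces)
  res <- run_gessa(list(m, m2), M_target = 16, iters_per_level = 60,
                   seed = 3, n_steiner = 1)
  p1 <- sp_position(m, res$landmarks[[1]])
  p2 <- sp_position(m2, res$landmarks[[2]])
  expect_lt(max(sqrt(rowSums((p1 - p2)^2))), 1e-3 * bbox_diagonal(m))
})

test_that("optimization lowers shape entropy below random initializations", {
  meshes <- face_ensemble(3, amp0 = 0.08, damp = 0.01)
  res <- run_gessa(meshes, M_target = 8, iters_per_level = 30, seed = 5,
                   n_steiner = 1)
  z_opt <- do.call(rbind, lapply(seq_along(meshes), function(j)
    as.vector(t(sp_position(meshes[[j]], res$landmarks[[j]])))))
  alpha <- 1
  h_opt <- shape_entropy(z_opt, alpha)
  for (s in 1:3) {
    set.seed(100 + s)
    z_rnd <- do.call(rbind, lapply(meshes, function(m)
      as.vector(t(sp_position(m, random_surface_points(m, 8))))))
    expect_lt(h_opt, shape_entropy(z_rnd, alpha))
  }
})

test_that("optimized landmark densities are more uniform than random ones", {
  sph <- icosphere(3, radius = 10)
  cv <- function(x) stats::sd(x) / mean(x)
  wins <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    lsr <- random_surface_points(sph, 48)
    st <- gessa_state(list(sph), list(lsr), weight_shape = 0, n_steiner = 1)
    for (i in 1:20) {
      stp <- gessa_step(st)
      st <- stp$state
      st$gamma <- min(0.1, st$gamma * 1.5)
    }
    dens_of <- function(l) vapply(seq_len(48), function(i)
      surface_density(sph, l, i, st$sigma), numeric(1))
    wins <- wins + (cv(dens_of(st$landmarks[[1]])) < cv(dens_of(lsr)))
  }
  expect_gte(wins, 4)                        # median over seeds improves
})

test_that("fiducial validation reports zero for exact hits and scales right", {
  meshes <- face_ensemble(2)
  set.seed(6)
  lms <- lapply(meshes, random_surface_points, n = 12)
  gt <- lapply(seq_along(meshes), function(j) {
    xyz <- sp_position(meshes[[j]], lms[[j]])[c(1, 4, 7), ]
    rownames(xyz) <- c("a", "zy1", "zy2")
    xyz
  })
  rep1 <- validate_against_fiducials(lms, meshes, gt, c("zy1", "zy2"))
  expect_equal(rep1$mean_distance, rep(0, 3))
  expect_equal(rep1$sd_distance, rep(0, 3))
  # scale invariance of the normalized metrics
  gt2 <- lapply(seq_along(meshes), function(j) {
    xyz <- sp_position(meshes[[j]], lms[[j]])[c(1, 4, 7), ] + 1.5
    rownames(xyz) <- c("a", "zy1", "zy2")
    xyz
  })
  rep_a <- validate_against_fiducials(lms, meshes, gt2, c("zy1", "zy2"))
  meshes2x <- lapply(meshes, function(m) triangle_mesh(2 * m$vertices, m$faces))
  gt2x <- lapply(gt2, function(g) 2 * g)
  rep_b <- validate_against_fiducials(lms, meshes2x, gt2x, c("zy1", "zy2"))
  expect_equal(rep_a$norm_mean, rep_b$norm_mean, tolerance = 1e-9)
  expect_equal(rep_a$norm_sd, rep_b$norm_sd, tolerance = 1e-9)
  # missing label errors
  gt_bad <- gt
  rownames(gt_bad[[2]]) <- c("a", "zy1", "other")
  expect_error(validate_against_fiducials(lms, meshes, gt_bad,
                                          c("zy1", "zy2")), "missing")
})
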