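test_that("fiducial picking maps labels to nearest landmarks with tie-breaks", {
  avg <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  picks <- rbind(g = c(1.02, 0, 0), n = c(0, 0.9, 0))
  fid <- pick_fiducials(avg, picks)
  expect_equal(unname(fid), c(2L, 4L))
  expect_named(fid, c("g", "n"))
  # equidistant pick: lowest index wins
  tie <- pick_fiducials(avg, rbind(x = c(0.5, 0, 0)))
  expect_equal(unname(tie), 1L)
  # duplicate assignment warns
  expect_warning(pick_fiducials(avg, rbind(a = c(1, 0, 0), b = c(1.01, 0, 0))),
                 "same landmark")
  # a full 17-label pick set yields a 17-entry map
  set.seed(1)
  avg2 <- matrix(rnorm(60), 20, 3)
  picks17 <- avg2[1:17, ]
  rownames(picks17) <- FIDUCIAL_LABELS
  expect_length(pick_fiducials(avg2, picks17), 17L)
})

test_that("distance traits: ten pairs, chord bound, planar equality, rigid invariance", {
  meshes <- face_ensemble(3)
  res <- run_gessa(meshes, M_target = 32, iters_per_level = c(40, 25, 15, 10, 8, 5),
                   seed = 11, n_steiner = 1)
  avg <- average_landmark_positions(meshes, res$landmarks)
  set.seed(2)
  sel <- sample.int(32, 17)
  picks <- avg[sel, ]
  rownames(picks) <- FIDUCIAL_LABELS
  fid <- pick_fiducials(avg, picks)
  edt <- distance_traits(meshes, res$landmarks, fid, mode = "euclidean")
  gdt <- distance_traits(meshes, res$landmarks, fid, mode = "geodesic")
  expect_equal(ncol(edt), 10L)               # the ten standard trait pairs
  expect_identical(colnames(edt), names(DISTANCE_TRAIT_PAIRS))
  expect_true(all(edt <= gdt + 1e-9))        # chord bound everywhere

  # rigid invariance and scale equivariance
  th <- 0.4
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  meshes_rot <- lapply(meshes, transform_mesh, rotation = rot,
                       translation = c(5, -3, 2))
  edt_rot <- distance_traits(meshes_rot, res$landmarks, fid)
  expect_equal(edt_rot, edt, tolerance = 1e-9)
  meshes_2x <- lapply(meshes, function(m) triangle_mesh(2 * m$vertices, m$faces))
  expect_equal(distance_traits(meshes_2x, res$landmarks, fid), 2 * edt,
               tolerance = 1e-9)

  expect_error(distance_traits(meshes, res$landmarks, fid[1:5]),
               "missing fiducial")
})

test_that("distance traits coincide between modes on a flat surface", {
  m <- grid_mesh(10, 10)
  set.seed(3)
  ls <- random_surface_points(m, 20)
  avg <- sp_position(m, ls)
  picks <- avg[1:17, ]
  rownames(picks) <- FIDUCIAL_LABELS
  fid <- pick_fiducials(avg, picks)
  edt <- distance_traits(list(m), list(ls), fid, mode = "euclidean")
  gdt <- distance_traits(list(m), list(ls), fid, mode = "geodesic")
  expect_equal(edt, gdt, tolerance = 1e-6)
})

test_that("age residualization removes the age signal exactly", {
  set.seed(21)
  n <- 40
  ages <- runif(n, 40, 80)
  traits <- cbind(t1 = 2 * ages + rnorm(n),
                  t2 = rnorm(n))              # age-independent column
  res <- regress_out_age(traits, ages)
  expect_lt(abs(cor(res[, "t1"], ages)), 1e-9)
  expect_lt(abs(sum(res[, "t1"] * (ages - mean(ages)))), 1e-8)
  expect_equal(res[, "t2"],
               residuals(lm(traits[, "t2"] ~ ages)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # hand-computed 4-subject closed form
  a4 <- c(1, 2, 3, 4); y4 <- c(2, 3, 5, 9)
  b <- cov(a4, y4) / var(a4)
  expect_equal(as.numeric(regress_out_age(matrix(y4), a4)),
               y4 - mean(y4) - b * (a4 - mean(a4)), tolerance = 1e-12)
  expect_error(regress_out_age(traits, rep(50, n)), "constant age")
})

test_that("sparse PCA spans dense PCA at loose bounds and sparsifies at tight ones", {
  set.seed(31)
  n <- 40; M <- 30
  # planted two-cluster covariance: first 6 variables co-vary strongly
  base <- rnorm(n)
  x <- matrix(rnorm(n * M, sd = 0.5), n, M)
  x[, 1:6] <- x[, 1:6] + 2 * base
  x <- sweep(x, 2, colMeans(x))

  loose <- sparse_pca(x, n_components = 2, sparsity_bound = sqrt(M))
  dense <- prcomp(x, center = FALSE)$rotation[, 1]
  cosine <- abs(sum(loose[[1]]$loadings * dense))
  expect_gt(cosine, 0.999)
  expect_equal(sqrt(sum(loose[[1]]$loadings^2)), 1, tolerance = 1e-9)

  tight <- sparse_pca(x, n_components = 1, sparsity_bound = 1)
  expect_equal(sum(tight[[1]]$loadings != 0), 1L)

  # nonzero count is non-increasing as the bound decreases
  nz <- vapply(c(sqrt(M), 4, 2.5, 1.5, 1), function(b)
    sum(sparse_pca(x, 1, b)[[1]]$loadings != 0), integer(1))
  expect_true(all(diff(nz) <= 0))

  # planted-cluster loadings concentrate on the planted block
  mid <- sparse_pca(x, 1, sparsity_bound = 2.2)[[1]]$loadings
  expect_gt(sum(abs(mid[1:6])), 0.9 * sum(abs(mid)))

  # cumulative explained variance is monotone, <= 1, and -> 1 at full rank
  full <- sparse_pca(x, n_components = min(n, M), sparsity_bound = sqrt(M))
  ev <- cumsum(vapply(full, `[[`, 0, "explained_variance"))
  expect_true(all(diff(ev) >= -1e-12))
  expect_lte(max(ev), 1 + 1e-9)
  expect_equal(ev[length(ev)], 1, tolerance = 1e-6)

  expect_error(sparse_pca(x, 1, 0.5), "sparsity_bound")
})

test_that("eigenface maps color only nonzero loadings, ignoring sign", {
  avg <- matrix(rnorm(30), 10, 3)
  w <- rep(0, 10); w[4] <- 1
  trait <- list(loadings = w, scores = rnorm(5), explained_variance = 0.5)
  p1 <- tempfile(fileext = ".ply")
  eigenface_map(trait, avg, p1)
  lines <- readLines(p1)
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  cols <- t(vapply(strsplit(body, " "), function(x) as.integer(x[4:6]),
                   integer(3)))
  expect_equal(sum(!apply(cols, 1, function(r) all(r == 190))), 1L)
  # sign flip produces the identical map
  p2 <- tempfile(fileext = ".ply")
  trait$loadings <- -w
  eigenface_map(trait, avg, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(eigenface_map(list(loadings = w[1:3]), avg, p1), "length")
})
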