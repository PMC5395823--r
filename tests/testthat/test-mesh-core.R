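test_that("OBJ files parse, reject bad indices, and triangulate quads", {
  obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3", "f 1 3 4"), obj)
  m <- read_mesh(obj)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 2L)

  bad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 9"), bad)
  expect_error(read_mesh(bad), "out of range")

  quad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), quad)
  expect_equal(nrow(read_mesh(quad)$faces), 2L)
  expect_error(read_mesh(quad, triangulate_quads = FALSE), "triangula")
})

test_that("write/read round-trips are lossless for all formats", {
  m <- grid_mesh(5, 4)
  for (spec in list(c("obj", FALSE), c("ply", FALSE), c("ply", TRUE))) {
    path <- tempfile(fileext = paste0(".", spec[1]))
    write_mesh(m, path, binary = as.logical(spec[2]))
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_identical(m2$faces, m$faces)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  }
})

test_that("per-vertex scalar export writes colors and a raw-value sidecar", {
  m <- grid_mesh(4, 4)
  path <- tempfile(fileext = ".ply")
  write_mesh(m, path, vertex_scalars = rep(2.5, n_vertices(m)))
  lines <- readLines(path)
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  vert_lines <- body[seq_len(n_vertices(m))]
  cols <- unique(vapply(strsplit(vert_lines, " "), function(x)
    paste(x[4:6], collapse = ","), ""))
  expect_length(cols, 1)                    # constant scalars -> one color
  sidecar <- read.csv(paste0(path, ".values.csv"))
  expect_equal(sidecar$value, rep(2.5, n_vertices(m)))
  expect_error(write_mesh(m, path, vertex_scalars = 1:3), "one value per")
})

test_that("mesh validation catches degenerate and non-manifold input", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "zero-area")
  # one edge shared by three faces
  v5 <- rbind(v, c(0.5, 0.5, 1))
  f3 <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(triangle_mesh(v5, f3), "manifold")
  expect_silent(validate_mesh(grid_mesh(4, 4)))
})

test_that("vertex normals are unit length and outward-oriented", {
  m <- make_face_mesh(face_params(bumps = list()), resolution = 2)
  vn <- vertex_normals(m)
  expect_true(all(abs(sqrt(rowSums(vn^2)) - 1) < 1e-8))
  # half-ellipsoid faces +z: most normals point away from the center
  outward <- rowSums(vn * m$vertices)
  expect_gt(mean(outward > 0), 0.95)
})

test_that("fiducial alignment recovers rigid transforms and stays proper", {
  pts <- rbind(c(1, 0, 0), c(0, 1.5, 0), c(0, 0, 2), c(1, 1, 1))
  th <- 30 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pts %*% t(rot) + rep(1, 4) %o% c(3, -2, 0.5)
  m <- triangle_mesh(pts, rbind(c(1, 2, 3), c(1, 2, 4)))
  fit <- align_from_fiducials(m, fixed_points = moved, moving_points = pts)
  expect_lt(max(abs(fit$rotation - rot)), 1e-6)
  expect_lt(fit$rmsd, 1e-9)

  ident <- align_from_fiducials(m, pts, pts)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)

  mirrored <- pts %*% diag(c(-1, 1, 1))
  mir <- align_from_fiducials(m, mirrored, pts)
  expect_equal(det(mir$rotation), 1, tolerance = 1e-9)
  expect_gt(mir$rmsd, 1e-3)

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(align_from_fiducials(m, collinear, collinear), "collinear")

  # property: proper rotation for random non-degenerate fiducials
  set.seed(42)
  for (i in 1:5) {
    p0 <- matrix(rnorm(12), 4, 3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    fit <- align_from_fiducials(m, p0 %*% t(R), p0)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_lt(fit$rmsd, 1e-8)
  }
})

test_that("ICP refines a small misalignment and respects its contracts", {
  ref <- make_face_mesh(face_params(noise_sd = 0), resolution = 2)
  th <- 5 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moving <- transform_mesh(ref, rot, c(1, -0.5, 0.3))
  fit <- icp_align(moving, ref, max_iters = 50)
  expect_lt(fit$rmsd, 1e-3 * bbox_diagonal(ref))

  same <- icp_align(ref, ref)
  expect_equal(same$iterations, 1L)
  expect_lt(max(abs(same$rotation - diag(3))), 1e-8)

  frozen <- icp_align(moving, ref, max_iters = 0)
  expect_identical(frozen$mesh$vertices, moving$vertices)
  expect_lt(max(abs(frozen$rotation - diag(3))), 1e-12)
})

test_that("surface points obey barycentric invariants", {
  m <- grid_mesh(4, 4)
  sp <- surface_point(2, c(2, 1, 1))
  expect_equal(sum(sp$bary), 1)
  expect_error(surface_point(1, c(-0.5, 1, 0.5)), "nonnegative")
  ls <- random_surface_points(m, 20)
  expect_equal(rowSums(ls$bary), rep(1, 20))
  xyz <- sp_position(m, ls)
  expect_true(all(xyz[, 1] >= 0 & xyz[, 1] <= 1))
  back <- nearest_surface_point(m, xyz)
  expect_lt(max(abs(sp_position(m, back) - xyz)), 1e-9)
})
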