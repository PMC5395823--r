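# programmatic mesh fixtures shared across test files

# flat rectangular grid in the z = 0 plane
grid_mesh <- function(nx = 8, ny = 8, w = 1, h = 1) {
  xs <- seq(0, w, length.out = nx)
  ys <- seq(0, h, length.out = ny)
  v <- cbind(as.matrix(expand.grid(x = xs, y = ys)), 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- vector("list", 2 * (nx - 1) * (ny - 1))
  k <- 0
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    f[[k + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    f[[k + 2]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
    k <- k + 2
  }
  triangle_mesh(v, do.call(rbind, f))
}

# open half-cylinder of given radius around the y axis, bulging toward +z
cylinder_mesh <- function(radius = 5, height = 10, n_theta = 24, n_y = 15) {
  th <- seq(-pi / 2, pi / 2, length.out = n_theta)
  ys <- seq(0, height, length.out = n_y)
  v <- do.call(rbind, lapply(ys, function(y)
    cbind(radius * sin(th), y, radius * cos(th))))
  id <- function(i, j) (j - 1) * n_theta + i
  f <- vector("list", 2 * (n_theta - 1) * (n_y - 1))
  k <- 0
  for (j in 1:(n_y - 1)) for (i in 1:(n_theta - 1)) {
    f[[k + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    f[[k + 2]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
    k <- k + 2
  }
  triangle_mesh(v, do.call(rbind, f))
}

# small ensemble of face-like meshes differing in nose-bump amplitude
face_ensemble <- function(n = 3, resolution = 2, amp0 = 0.06, damp = 0.03) {
  fp <- face_params(noise_sd = 0)
  lapply(seq_len(n), function(i) {
    p <- fp
    p$bumps[[1]]$amplitude <- amp0 + damp * i
    make_face_mesh(p, resolution = resolution)
  })
}

# surface point at/near given world coordinates
sp_at <- function(mesh, xyz) {
  ls <- nearest_surface_point(mesh, matrix(xyz, 1))
  surface_point(ls$face[1], ls$bary[1, ])
}
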