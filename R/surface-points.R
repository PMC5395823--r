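#' Continuous point on a mesh surface
#'
#' A `surface_point` is a location on a triangle mesh given by a face index
#' and three nonnegative barycentric weights summing to one; its Cartesian
#' position is the barycentric combination of the face's vertices. Landmarks
#' live on the continuous surface, not only at mesh vertices.
#'
#' @param face 1-based face index.
#' @param bary numeric length-3, nonnegative; renormalized to sum to one.
#' @return object of class `surface_point`.
#' @export
surface_point <- function(face, bary) {
  bary <- as.numeric(bary)
  if (length(bary) != 3 || any(bary < -1e-12))
    stop("bary must be 3 nonnegative weights")
  bary <- pmax(bary, 0)
  s <- sum(bary)
  if (s <= 0) stop("degenerate barycentric weights")
  structure(list(face = as.integer(face), bary = bary / s),
            class = "surface_point")
}

#' A set of surface points (landmarks) on one mesh
#'
#' Column-bound representation of `M` surface points: an integer vector of
#' face indices plus an `M x 3` matrix of barycentric weights. This is the
#' landmark container used throughout the correspondence optimizer.
#'
#' @param face integer vector of face indices.
#' @param bary `M x 3` matrix of barycentric weights (rows renormalized).
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(face, bary) {
  bary <- matrix(as.numeric(bary), ncol = 3)
  bary <- pmax(bary, 0)
  bary <- bary / rowSums(bary)
  structure(list(face = as.integer(face), bary = bary), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points\n", length(x$face)))
  invisible(x)
}

n_landmarks <- function(ls) length(ls$face)

as_landmark_set <- function(p) {
  if (inherits(p, "landmark_set")) return(p)
  if (inherits(p, "surface_point"))
    return(landmark_set(p$face, matrix(p$bary, 1)))
  stop("expected a surface_point or landmark_set")
}

#' Cartesian positions of surface points
#' @param mesh a [triangle_mesh()].
#' @param points a [surface_point()] or [landmark_set()].
#' @return `M x 3` coordinate matrix.
#' @export
sp_position <- function(mesh, points) {
  ls <- as_landmark_set(points)
  f <- mesh$faces[ls$face, , drop = FALSE]
  v <- mesh$vertices
  ls$bary[, 1] * v[f[, 1], , drop = FALSE] +
    ls$bary[, 2] * v[f[, 2], , drop = FALSE] +
    ls$bary[, 3] * v[f[, 3], , drop = FALSE]
}

# subset of a landmark set
ls_subset <- function(ls, i) landmark_set(ls$face[i], ls$bary[i, , drop = FALSE])

#' Project Cartesian points to the nearest surface location
#'
#' For each query point, finds the closest point on the mesh surface
#' (searching faces incident to the nearest vertices) and returns it as a
#' landmark set.
#'
#' @param mesh a [triangle_mesh()].
#' @param xyz `k x 3` matrix of query coordinates.
#' @return a [landmark_set()] of length `k`.
#' @export
nearest_surface_point <- function(mesh, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  v <- mesh$vertices; f <- mesh$faces
  nn <- nearest_rows(xyz, v)
  # faces incident to each vertex
  vf <- vertex_face_index(mesh)
  faces_out <- integer(nrow(xyz)); bary_out <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) {
    cand <- vf[[nn$index[i]]]
    best <- Inf; bf <- cand[1]; bb <- c(1, 0, 0)
    for (fc in cand) {
      tri <- v[f[fc, ], , drop = FALSE]
      cp <- closest_point_triangle(xyz[i, ], tri)
      d2 <- sum((cp$point - xyz[i, ])^2)
      if (d2 < best) { best <- d2; bf <- fc; bb <- cp$bary }
    }
    faces_out[i] <- bf; bary_out[i, ] <- bb
  }
  landmark_set(faces_out, bary_out)
}

vertex_face_index <- function(mesh) {
  cached(mesh, "vertex_face_index", function() {
    f <- mesh$faces
    idx <- c(f[, 1], f[, 2], f[, 3])
    fid <- rep(seq_len(nrow(f)), 3)
    unname(split(fid, factor(idx, levels = seq_len(n_vertices(mesh)))))
  })
}

# closest point on a triangle (Ericson's barycentric region method)
closest_point_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(point = a, bary = c(1, 0, 0)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(point = b, bary = c(0, 1, 0)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(list(point = a + t * ab, bary = c(1 - t, t, 0)))
  }
  cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(point = c, bary = c(0, 0, 1)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(list(point = a + t * ac, bary = c(1 - t, 0, t)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(list(point = b + t * (c - b), bary = c(0, 1 - t, t)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  list(point = a + ab * v + ac * w, bary = c(1 - v - w, v, w))
}

#' Sample random points uniformly from a mesh surface
#'
#' Faces are drawn with probability proportional to area and barycentric
#' coordinates uniformly within each face, giving an exactly uniform sample of
#' the surface measure. Uses the current RNG state (set a seed upstream for
#' reproducibility).
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points.
#' @return a [landmark_set()].
#' @export
random_surface_points <- function(mesh, n) {
  a <- face_areas(mesh)
  fc <- sample.int(length(a), n, replace = TRUE, prob = a)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  bary <- cbind(1 - r1, r1 * (1 - r2), r1 * r2)
  landmark_set(fc, bary)
}

#' Tangent vector anchored at a surface point
#'
#' A vector lying in the plane of the anchor point's face; tangent vectors are
#' what the exponential map shoots along and what the logarithmic map returns.
#' The vector is projected onto the face plane on construction.
#'
#' @param anchor a [surface_point()].
#' @param vec numeric length-3.
#' @param mesh the mesh the anchor lives on (used to project onto the face).
#' @return object of class `tangent_vector`.
#' @export
tangent_vector <- function(anchor, vec, mesh) {
  nrm <- face_normals(mesh)[anchor$face, ]
  vec <- as.numeric(vec)
  vec <- vec - sum(vec * nrm) * nrm
  structure(list(anchor = anchor, vec = vec), class = "tangent_vector")
}
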