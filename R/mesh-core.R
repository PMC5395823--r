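#' Construct a triangle mesh
#'
#' A `triangle_mesh` is the basic surface container of the package: an
#' `n x 3` matrix of vertex coordinates (any length unit, typically mm) and an
#' `F x 3` integer matrix of 1-based vertex indices per triangular face, with
#' consistent counterclockwise winding viewed from outside the surface.
#'
#' Vertex normals are derived quantities (see [vertex_normals()]); they are
#' oriented so that the mean normal over the mesh points into the half-space
#' of `orient_axis` (default `+z`), the usual "camera-facing" convention for
#' frontal facial scans. All curvature signs downstream inherit this
#' convention, so convex-outward regions (e.g. a nose tip) get positive
#' curvature.
#'
#' @param vertices numeric matrix `n x 3`.
#' @param faces integer matrix `F x 3`, 1-based vertex indices.
#' @param orient_axis length-3 vector giving the outward viewing direction.
#' @param validate check mesh invariants (index range, no zero-area faces,
#'   edge-manifoldness). Internal callers that build meshes programmatically
#'   may skip this.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, orient_axis = c(0, 0, 1),
                          validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         orient_axis = as.numeric(orient_axis),
         .cache = new.env(parent = emptyenv())),
    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

#' Validate triangle-mesh invariants
#'
#' Checks that all face indices are in range, that no face has (near-)zero
#' area, and that the mesh is edge-manifold with boundary (every undirected
#' edge belongs to at most two faces).
#'
#' @param mesh a [triangle_mesh()].
#' @return the mesh, invisibly; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop(sprintf("face vertex index out of range [1, %d]", nrow(v)))
    a <- face_areas(mesh)
    scale2 <- max(apply(v, 2, function(x) diff(range(x))))^2
    if (any(a <= 1e-14 * max(scale2, 1)))
      stop("mesh contains zero-area faces")
    ek <- edge_keys(f)
    tab <- tabulate(match(ek, unique(ek)))
    if (any(tab > 2L))
      stop("mesh is not edge-manifold: an edge is shared by more than 2 faces")
  }
  invisible(mesh)
}

# canonical undirected edge keys for all 3F face edges
edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

cached <- function(mesh, key, fn) {
  env <- mesh$.cache
  if (!exists(key, envir = env, inherits = FALSE)) assign(key, fn(), envir = env)
  get(key, envir = env, inherits = FALSE)
}

# cross products of the two edge vectors per face (un-normalized normals)
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas of a mesh
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  cached(mesh, "face_areas", function() {
    cr <- face_cross(mesh)
    0.5 * sqrt(rowSums(cr^2))
  })
}

#' Total surface area
#' @param mesh a [triangle_mesh()].
#' @return scalar area.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# +1 or -1: sign making the mean winding normal point along orient_axis.
# For (near-)closed surfaces the mean normal vanishes, so the sign of the
# signed volume decides instead (positive = outward winding).
orientation_sign <- function(mesh) {
  cached(mesh, "orient_sign", function() {
    cr <- face_cross(mesh)
    s <- sum(colSums(cr) * mesh$orient_axis)
    total <- sum(sqrt(rowSums(cr^2)))
    if (abs(s) < 1e-3 * total) {
      v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
      f <- mesh$faces
      vol <- sum(rowSums(v[f[, 1], , drop = FALSE] * cr)) / 6
      return(if (vol >= 0) 1 else -1)
    }
    if (s >= 0) 1 else -1
  })
}

#' Outward unit face normals
#' @param mesh a [triangle_mesh()].
#' @return `F x 3` matrix of unit normals, globally oriented along the mesh's
#'   `orient_axis` convention.
#' @export
face_normals <- function(mesh) {
  cached(mesh, "face_normals", function() {
    cr <- face_cross(mesh)
    n <- cr / sqrt(rowSums(cr^2))
    n * orientation_sign(mesh)
  })
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalized to unit length,
#' with the global outward orientation of [face_normals()].
#'
#' @param mesh a [triangle_mesh()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cached(mesh, "vertex_normals", function() {
    cr <- face_cross(mesh) * orientation_sign(mesh)  # area-weighted normals
    f <- mesh$faces
    # accumulate incident face normals at each corner vertex
    n <- matrix(0, n_vertices(mesh), 3)
    for (k in 1:3) {
      idx <- f[, k]
      for (d in 1:3) {
        acc <- rowsum(cr[, d], idx)
        n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
      }
    }
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n / len
  })
}

#' Bounding-box diagonal of a mesh
#' @param mesh a [triangle_mesh()].
#' @return scalar length.
#' @export
bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Apply a rigid transform to a mesh
#' @param mesh a [triangle_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation, translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  triangle_mesh(v, mesh$faces, orient_axis = mesh$orient_axis, validate = FALSE)
}

# ---------------------------------------------------------------------------
# Rigid alignment

#' Least-squares rigid transform from labelled fiducial points
#'
#' Computes the proper rigid transform (rotation with determinant +1 and
#' translation, no scaling) minimizing the RMSD between three or more labelled
#' point pairs (Kabsch algorithm), and applies it to the moving mesh. Typical
#' use: rough pose normalization from manually placed outer eye corners and
#' nasion before ICP refinement.
#'
#' @param moving the mesh to transform.
#' @param fixed_points `k x 3` matrix of target points (k >= 3, non-collinear).
#' @param moving_points `k x 3` matrix of the same fiducials on `moving`.
#' @return list with `rotation`, `translation`, `mesh` (transformed moving
#'   mesh) and `rmsd` (post-fit fiducial RMSD).
#' @export
align_from_fiducials <- function(moving, fixed_points, moving_points) {
  fp <- as.matrix(fixed_points); mp <- as.matrix(moving_points)
  stopifnot(nrow(fp) == nrow(mp), nrow(fp) >= 3, ncol(fp) == 3, ncol(mp) == 3)
  fit <- kabsch(mp, fp)
  if (is.null(fit)) stop("fiducials are collinear: rotation is degenerate")
  aligned <- sweep(mp %*% t(fit$rotation), 2, fit$translation, "+")
  rmsd <- sqrt(mean(rowSums((aligned - fp)^2)))
  list(rotation = fit$rotation, translation = fit$translation,
       mesh = transform_mesh(moving, fit$rotation, fit$translation),
       rmsd = rmsd)
}

# proper rigid transform mapping points a onto points b (least squares)
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  aa <- sweep(a, 2, ca); bb <- sweep(b, 2, cb)
  # collinearity check: centered points must span a plane
  s <- svd(aa)
  if (nrow(a) < 3 || s$d[2] < 1e-12 * max(s$d[1], 1)) return(NULL)
  h <- t(aa) %*% bb
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = as.numeric(cb - rot %*% ca))
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP with vertex-to-nearest-vertex matching: at each
#' iteration every vertex of the moving mesh is matched to its nearest
#' reference vertex, a proper rigid update is estimated by least squares and
#' applied, and iteration stops when the matched-point RMSD improves by less
#' than `tol` times the reference bounding-box diagonal (or after
#' `max_iters`). Accepted iterations never increase the matched RMSD. Meshes
#' should be roughly pre-oriented (e.g. with [align_from_fiducials()]).
#'
#' @param moving,reference triangle meshes.
#' @param max_iters maximum iterations; `0` returns the input unchanged with
#'   an identity transform.
#' @param tol relative RMSD-improvement stopping tolerance.
#' @return list with `rotation`, `translation` (cumulative), `mesh`, `rmsd`
#'   and `iterations`.
#' @export
icp_align <- function(moving, reference, max_iters = 50, tol = 1e-6) {
  if (n_vertices(moving) == 0 || n_vertices(reference) == 0)
    stop("empty mesh")
  diag_len <- bbox_diagonal(reference)
  rot <- diag(3); tr <- c(0, 0, 0)
  cur <- moving$vertices
  ref <- reference$vertices
  rmsd_prev <- Inf; it <- 0
  while (it < max_iters) {
    nn <- nearest_rows(cur, ref)
    matched <- ref[nn$index, , drop = FALSE]
    rmsd <- sqrt(mean(nn$dist2))
    if (rmsd > rmsd_prev) break           # never accept a worsening update
    if (rmsd_prev - rmsd < tol * diag_len && it > 0) { rmsd_prev <- rmsd; break }
    rmsd_prev <- rmsd
    fit <- kabsch(cur, matched)
    if (is.null(fit)) break
    cur <- sweep(cur %*% t(fit$rotation), 2, fit$translation, "+")
    rot <- fit$rotation %*% rot
    tr <- as.numeric(fit$rotation %*% tr + fit$translation)
    it <- it + 1
  }
  if (is.infinite(rmsd_prev)) {           # max_iters = 0
    nn <- nearest_rows(cur, ref)
    rmsd_prev <- sqrt(mean(nn$dist2))
  }
  out_mesh <- triangle_mesh(cur, moving$faces, orient_axis = moving$orient_axis,
                            validate = FALSE)
  list(rotation = rot, translation = tr, mesh = out_mesh,
       rmsd = rmsd_prev, iterations = it)
}

# nearest row of `ref` for each row of `x` (chunked brute force)
nearest_rows <- function(x, ref, chunk = 512L) {
  n <- nrow(x)
  idx <- integer(n); d2 <- numeric(n)
  ref2 <- rowSums(ref^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xs <- x[s:e, , drop = FALSE]
    cross <- xs %*% t(ref)                      # chunk x nref
    dd <- outer(rowSums(xs^2), ref2, "+") - 2 * cross
    j <- max.col(-dd, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- pmax(dd[cbind(seq_len(nrow(dd)), j)], 0)
  }
  list(index = idx, dist2 = d2)
}
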