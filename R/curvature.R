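# Principal-curvature phenotypes at landmarks.
#
# The local shape operator is estimated from finite differences of the unit
# vertex normals against tangent-plane displacements over a geodesically small
# neighborhood; its eigenvalues are the principal curvatures. The sign
# convention follows the mesh's outward normal orientation: convex-outward
# regions (nose tip, chin) have positive curvature.

#' Estimate principal curvatures at a surface point
#'
#' Least-squares fit of the symmetric 2x2 shape operator `S` from finite
#' normal differences over the mesh vertices within `radius` of the point:
#' `dN ~ S dX` in the tangent basis at the point (outward normals). The
#' eigenvalues of `S`, sorted, are `k_max >= k_min`; the eigenvectors give the
#' principal directions (returned in 3D world coordinates).
#'
#' @param mesh a [triangle_mesh()].
#' @param point a [surface_point()].
#' @param radius neighborhood radius (length units); must contain at least 5
#'   vertices.
#' @return list with `k_max`, `k_min`, `directions` (2 x 3 matrix: rows are
#'   the max- and min-curvature directions).
#' @export
estimate_principal_curvatures <- function(mesh, point, radius) {
  p <- as.numeric(sp_position(mesh, point))
  nrm <- face_normals(mesh)[point$face, ]
  fit <- shape_operator_fit(mesh, p, nrm, radius)
  ev <- eigen(fit$S, symmetric = TRUE)
  dirs <- t(fit$basis) %*% ev$vectors      # 3 x 2, columns in world coords
  list(k_max = ev$values[1], k_min = ev$values[2],
       directions = t(dirs)[, , drop = FALSE])
}

# core fit shared by the scalar and batch paths; grow = TRUE enlarges the
# stencil (x1.5, up to 5 times) when a neighborhood is vertex-starved, e.g.
# at landmarks close to an open-surface boundary
shape_operator_fit <- function(mesh, p, nrm, radius, vn = NULL, grow = FALSE) {
  if (is.null(vn)) vn <- vertex_normals(mesh)
  v <- mesh$vertices
  d2 <- colSums((t(v) - p)^2)
  sel <- which(d2 <= radius^2 & d2 > 1e-24)
  if (grow) {
    tries <- 0
    while (length(sel) < 5 && tries < 5) {
      radius <- radius * 1.5
      sel <- which(d2 <= radius^2 & d2 > 1e-24)
      tries <- tries + 1
    }
  }
  if (length(sel) < 5)
    stop("fewer than 5 vertices inside the curvature neighborhood")
  # tangent basis at the point
  e1 <- c(1, 0, 0)
  if (abs(sum(e1 * nrm)) > 0.9) e1 <- c(0, 1, 0)
  e1 <- e1 - sum(e1 * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(nrm, e1)
  dx3 <- sweep(v[sel, , drop = FALSE], 2, p)
  dn3 <- sweep(vn[sel, , drop = FALSE], 2, nrm)
  dx <- cbind(dx3 %*% e1, dx3 %*% e2)        # k x 2 tangent displacements
  dn <- cbind(dn3 %*% e1, dn3 %*% e2)        # k x 2 normal differences
  # least squares for symmetric S = [s1 s2; s2 s3]: dn ~ S dx
  a11 <- sum(dx[, 1]^2); a22 <- sum(dx[, 2]^2); a12 <- sum(dx[, 1] * dx[, 2])
  A <- rbind(c(a11, a12, 0),
             c(a12, a11 + a22, a12),
             c(0, a12, a22))
  b <- c(sum(dn[, 1] * dx[, 1]),
         sum(dn[, 1] * dx[, 2]) + sum(dn[, 2] * dx[, 1]),
         sum(dn[, 2] * dx[, 2]))
  s <- tryCatch(solve(A, b), error = function(e)
    stop("degenerate curvature fit (rank-deficient neighborhood)"))
  list(S = matrix(c(s[1], s[2], s[2], s[3]), 2, 2), basis = rbind(e1, e2))
}

#' Curvature indices from principal curvatures
#'
#' Computes the four standard univariate curvature descriptors from
#' `k_max >= k_min`: mean curvature `MC = (k_max + k_min)/2` (units 1/length),
#' Gaussian curvature `GC = k_max * k_min` (1/length^2), curvedness
#' `CU = sqrt((k_max^2 + k_min^2)/2)` (1/length; magnitude irrespective of
#' shape), and shape index
#' `SI = (2/pi) atan((k_max + k_min)/(k_max - k_min))` (dimensionless in
#' `[-1, 1]`; +1 dome, +0.5 convex cylinder, 0 saddle, -1 cup). At umbilic
#' points (`k_max = k_min`), where the shape index is formally undefined, SI
#' is set to `sign(MC)` (0 for flat points).
#'
#' @param k_max,k_min principal curvatures (vectors allowed), `k_max >= k_min`.
#' @param umbilic_tol relative tolerance declaring an umbilic.
#' @return data.frame with columns `k_max`, `k_min`, `MC`, `GC`, `CU`, `SI`.
#' @export
curvature_indices <- function(k_max, k_min, umbilic_tol = 1e-9) {
  if (any(k_max < k_min)) stop("k_max must be >= k_min")
  mc <- (k_max + k_min) / 2
  gc_ <- k_max * k_min
  cu <- sqrt((k_max^2 + k_min^2) / 2)
  scale <- pmax(abs(k_max), abs(k_min), 1e-12)
  umb <- (k_max - k_min) < umbilic_tol * scale
  si <- numeric(length(mc))
  si[!umb] <- (2 / pi) * atan((k_max[!umb] + k_min[!umb]) /
                                (k_max[!umb] - k_min[!umb]))
  si[umb] <- sign(mc[umb])
  data.frame(k_max = k_max, k_min = k_min, MC = mc, GC = gc_, CU = cu, SI = si)
}

#' Curvature trait matrices over an ensemble
#'
#' Evaluates the four curvature indices at every landmark of every subject,
#' returning one `subjects x landmarks` matrix per index plus landmark-wise
#' summaries. When a pair table is supplied, also reports the MZ and DZ means
#' and variances of the absolute within-pair trait differences, the raw
#' material of a twin analysis.
#'
#' @param meshes list of meshes (subjects).
#' @param landmark_sets matching list of index-aligned [landmark_set()]s.
#' @param radius curvature neighborhood radius; `NULL` = twice the mean
#'   inter-landmark spacing `sqrt(mean area / (pi * M))`.
#' @param subjects optional data.frame with columns `subject_id`, `pair_id`,
#'   `zygosity` (rows in mesh order) enabling the pair-difference summaries.
#' @return list with `traits` (named list of four `subjects x landmarks`
#'   matrices), `radius`, `summary` (landmark-wise mean/variance per index)
#'   and, with `subjects`, `pair_differences`.
#' @export
curvature_maps <- function(meshes, landmark_sets, radius = NULL,
                           subjects = NULL) {
  n <- length(meshes)
  stopifnot(length(landmark_sets) == n)
  M <- n_landmarks(landmark_sets[[1]])
  if (is.null(radius)) {
    mean_area <- mean(vapply(meshes, mesh_area, 0))
    radius <- 2 * sqrt(mean_area / (pi * M))
  }
  idx <- c("MC", "GC", "CU", "SI")
  traits <- lapply(idx, function(x) matrix(NA_real_, n, M))
  names(traits) <- idx
  for (s in seq_len(n)) {
    ci <- landmark_curvatures(meshes[[s]], landmark_sets[[s]], radius)
    for (x in idx) traits[[x]][s, ] <- ci[[x]]
  }
  summary <- do.call(rbind, lapply(idx, function(x)
    data.frame(index = x, landmark = seq_len(M),
               mean = colMeans(traits[[x]]),
               variance = apply(traits[[x]], 2, stats::var))))
  out <- list(traits = traits, radius = radius, summary = summary)
  if (!is.null(subjects)) {
    stopifnot(nrow(subjects) == n)
    out$pair_differences <- pair_difference_summary(traits, subjects)
  }
  out
}

# vectorized per-subject curvature evaluation at all landmarks
landmark_curvatures <- function(mesh, ls, radius) {
  vn <- vertex_normals(mesh)
  xyz <- sp_position(mesh, ls)
  nrm <- face_normals(mesh)[ls$face, , drop = FALSE]
  M <- n_landmarks(ls)
  kmax <- numeric(M); kmin <- numeric(M)
  for (i in seq_len(M)) {
    fit <- shape_operator_fit(mesh, xyz[i, ], nrm[i, ], radius, vn = vn,
                              grow = TRUE)
    ev <- eigen(fit$S, symmetric = TRUE, only.values = TRUE)$values
    kmax[i] <- ev[1]; kmin[i] <- ev[2]
  }
  curvature_indices(kmax, kmin)
}

pair_difference_summary <- function(traits, subjects) {
  pairs <- split(seq_len(nrow(subjects)), subjects$pair_id)
  complete <- pairs[vapply(pairs, length, 0L) == 2]
  zyg <- vapply(complete, function(ii) subjects$zygosity[ii[1]], "")
  rows <- list()
  for (x in names(traits)) {
    tm <- traits[[x]]
    adiff <- do.call(rbind, lapply(complete, function(ii)
      abs(tm[ii[1], ] - tm[ii[2], ])))
    for (z in c("MZ", "DZ")) {
      sel <- adiff[zyg == z, , drop = FALSE]
      if (nrow(sel) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        index = x, zygosity = z, landmark = seq_len(ncol(tm)),
        mean_abs_diff = colMeans(sel),
        var_abs_diff = apply(sel, 2, stats::var))
    }
  }
  do.call(rbind, rows)
}
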