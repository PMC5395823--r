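# Scalar phenotypes built on the dense landmarks: classical fiducial distance
# traits (Euclidean and geodesic) and sparse-PCA regional traits.

#' The 17 standard facial fiducial labels
#'
#' Glabella (g), nasion (n), pronasale (prn), subnasale (sn), gnathion (gn),
#' left/right alare (alL/alR), exocanthion (exL/exR), endocanthion (enL/enR),
#' zygion (zyL/zyR), cheilion (chL/chR) and gonion (goL/goR).
#' @export
FIDUCIAL_LABELS <- c("g", "n", "prn", "sn", "gn", "alL", "alR", "exL", "exR",
                     "enL", "enR", "zyL", "zyR", "chL", "chR", "goL", "goR")

#' The ten standard fiducial distance traits
#'
#' Named label pairs: lower/middle face heights, nose height and protrusion,
#' and the nose, intercanthal, biocular, zygomatic, mandible and mouth widths.
#' @export
DISTANCE_TRAIT_PAIRS <- list(
  lower_face_height = c("sn", "gn"),
  middle_face_height = c("g", "sn"),
  nose_height = c("n", "sn"),
  nasal_protrusion = c("sn", "prn"),
  nose_width = c("alL", "alR"),
  intercanthal_width = c("exL", "exR"),
  biocular_width = c("enL", "enR"),
  zygomatic_width = c("zyL", "zyR"),
  mandible_width = c("goL", "goR"),
  mouth_width = c("chL", "chR"))

#' Map labelled picks to landmark indices on the average face
#'
#' Each labelled 3D pick (typically placed by visual inspection of the
#' average-face landmark cloud) is assigned the index of its nearest
#' average-face landmark; ties break to the lowest index. Through the
#' ensemble-wide index correspondence the same fiducials are then located on
#' every subject automatically.
#'
#' @param average_landmarks `M x 3` matrix of average-face landmark positions.
#' @param picks named list (or `k x 3` matrix with rownames) of 3D points.
#' @return named integer vector: label -> landmark index. Duplicate
#'   assignments trigger a warning.
#' @export
pick_fiducials <- function(average_landmarks, picks) {
  if (is.list(picks)) picks <- do.call(rbind, picks)
  labels <- rownames(picks)
  if (is.null(labels) || anyDuplicated(labels))
    stop("picks must carry unique labels")
  avg <- as.matrix(average_landmarks)
  idx <- vapply(seq_len(nrow(picks)), function(i) {
    d2 <- colSums((t(avg) - as.numeric(picks[i, ]))^2)
    which.min(d2)  # which.min returns the first (lowest) index on ties
  }, integer(1))
  names(idx) <- labels
  if (anyDuplicated(idx))
    warning("two labels were assigned to the same landmark")
  idx
}

#' Fiducial distance traits across an ensemble
#'
#' Computes, for every subject, the distance between the two fiducial
#' landmarks of each pair: straight-line 3D distance (`mode = "euclidean"`,
#' the classical caliper trait) or on-surface geodesic length
#' (`mode = "geodesic"`, only possible with 3D surface data; always >= the
#' Euclidean value).
#'
#' @param meshes list of meshes.
#' @param landmark_sets matching index-aligned [landmark_set()]s.
#' @param fiducials named index vector from [pick_fiducials()].
#' @param pairs list of label pairs; defaults to the ten standard traits of
#'   [DISTANCE_TRAIT_PAIRS].
#' @param mode `"euclidean"` or `"geodesic"`.
#' @return `subjects x traits` numeric matrix with trait names as columns.
#' @export
distance_traits <- function(meshes, landmark_sets, fiducials,
                            pairs = DISTANCE_TRAIT_PAIRS,
                            mode = c("euclidean", "geodesic")) {
  mode <- match.arg(mode)
  labs <- unique(unlist(pairs))
  if (!all(labs %in% names(fiducials)))
    stop("missing fiducial labels: ",
         paste(setdiff(labs, names(fiducials)), collapse = ", "))
  n <- length(meshes)
  out <- matrix(NA_real_, n, length(pairs),
                dimnames = list(NULL, names(pairs)))
  for (s in seq_len(n)) {
    ls <- landmark_sets[[s]]
    fl <- ls_subset(ls, fiducials[labs])
    if (mode == "euclidean") {
      xyz <- sp_position(meshes[[s]], fl)
      rownames(xyz) <- labs
      for (t in seq_along(pairs))
        out[s, t] <- sqrt(sum((xyz[pairs[[t]][1], ] - xyz[pairs[[t]][2], ])^2))
    } else {
      D <- geodesic_distance_matrix(meshes[[s]], fl)
      dimnames(D) <- list(labs, labs)
      for (t in seq_along(pairs)) {
        d <- D[pairs[[t]][1], pairs[[t]][2]]
        if (!is.finite(d)) stop("fiducials disconnected on subject ", s)
        out[s, t] <- d
      }
    }
  }
  out
}

#' Remove a linear age effect from trait columns
#'
#' Ordinary least-squares residualization of each trait on (intercept, age):
#' the residuals are exactly uncorrelated with age. This is the pre-processing
#' route used before multivariate decompositions; univariate twin fits instead
#' carry age as a covariate in the mean model.
#'
#' @param trait_matrix `subjects x traits` numeric matrix.
#' @param ages numeric vector, one age per subject (non-constant).
#' @return residual matrix of the same shape (column means are zero).
#' @export
regress_out_age <- function(trait_matrix, ages) {
  x <- as.matrix(trait_matrix)
  ages <- as.numeric(ages)
  if (length(ages) != nrow(x)) stop("one age per subject required")
  if (any(!is.finite(ages))) stop("ages must be finite")
  if (stats::var(ages) == 0) stop("constant age vector")
  fit <- stats::lm.fit(cbind(1, ages), x)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(x)
  res
}

#' Sparse principal components of landmark phenotypes (regional traits)
#'
#' Sequential rank-one sparse decomposition: each component maximizes
#' explained variance subject to a unit L2 norm and an L1-ball constraint
#' `||w||_1 <= sparsity_bound` (soft-thresholded power iteration), followed by
#' rank-one deflation. With the bound at its maximum `sqrt(M)` the first
#' component equals the dense PCA component; bound 1 forces a single nonzero
#' loading. Sparsity concentrates each component's loadings on a spatially
#' coherent region of the face, which is what makes the components
#' interpretable regional traits.
#'
#' @param data column-centered `subjects x M` matrix (e.g. age-residualized
#'   curvature traits).
#' @param n_components number of components.
#' @param sparsity_bound L1 bound, in `[1, sqrt(M)]`.
#' @param max_iter,tol power-iteration controls.
#' @return list of regional traits, each with `loadings` (unit L2, sparse),
#'   `scores` (per subject), `explained_variance` (fraction of the original
#'   total variance).
#' @export
sparse_pca <- function(data, n_components, sparsity_bound,
                       max_iter = 200, tol = 1e-7) {
  x <- as.matrix(data)
  M <- ncol(x)
  if (sparsity_bound < 1 || sparsity_bound > sqrt(M) + 1e-9)
    stop("sparsity_bound must lie in [1, sqrt(M)]")
  x <- sweep(x, 2, colMeans(x))
  total_var <- sum(x^2)
  out <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    w <- sparse_rank_one(x, sparsity_bound, max_iter, tol)
    scores <- as.numeric(x %*% w)
    ev <- sum(scores^2) / total_var
    out[[comp]] <- list(loadings = w, scores = scores,
                        explained_variance = ev)
    x <- x - tcrossprod(scores, w)          # deflate the rank-one fit
  }
  out
}

# L1-constrained leading singular vector by alternating power iteration
sparse_rank_one <- function(x, c1, max_iter, tol) {
  sv <- svd(x, nu = 1, nv = 1)
  w <- abs(sv$v[, 1]); w <- w / sqrt(sum(w^2))
  w_old <- w
  for (it in seq_len(max_iter)) {
    u <- as.numeric(x %*% w)
    un <- sqrt(sum(u^2))
    if (un == 0) break
    u <- u / un
    a <- as.numeric(crossprod(x, u))
    w <- l1_projected_unit(a, c1)
    if (sqrt(sum((w - w_old)^2)) < tol) break
    w_old <- w
  }
  w
}

# argmax w'a s.t. ||w||_2 = 1, ||w||_1 <= c: soft threshold + renormalize,
# with the threshold found by binary search
l1_projected_unit <- function(a, c1) {
  soft <- function(a, delta) sign(a) * pmax(abs(a) - delta, 0)
  unitize <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) { v[which.max(abs(v))] <- 1; v } else v / n
  }
  w <- unitize(soft(a, 0))
  if (sum(abs(w)) <= c1 + 1e-12) return(w)
  lo <- 0; hi <- max(abs(a))
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    w <- soft(a, mid)
    if (all(w == 0)) { hi <- mid; next }
    w <- unitize(w)
    if (sum(abs(w)) > c1) lo <- mid else hi <- mid
  }
  w <- soft(a, hi)
  unitize(w)
}

#' Export a regional trait's loadings as a colored landmark map
#'
#' Writes the absolute loadings of one regional trait onto the average-face
#' landmark cloud: a point-cloud PLY colored by |loading| (viridis; exact
#' zeros rendered neutral grey) plus a CSV of the raw loadings. Sign is not
#' displayed: a component and its negation define the same regional trait.
#'
#' @param trait one element of [sparse_pca()]'s output.
#' @param average_landmarks `M x 3` matrix of average-face landmark positions.
#' @param path output PLY path (CSV written alongside as `<path>.csv`).
#' @return `path`, invisibly.
#' @export
eigenface_map <- function(trait, average_landmarks, path) {
  avg <- as.matrix(average_landmarks)
  w <- trait$loadings
  if (length(w) != nrow(avg)) stop("loadings length must match landmark count")
  av <- abs(w)
  cols <- scalar_colors(av)
  cols[av == 0, ] <- 190                    # neutral grey for exact zeros
  write_point_ply(avg, cols, path)
  utils::write.csv(data.frame(landmark_id = seq_along(w), weight = w),
                   paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

# minimal colored point-cloud PLY writer
write_point_ply <- function(xyz, cols, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(xyz)),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g %d %d %d", xyz[, 1], xyz[, 2], xyz[, 3],
                     cols[, 1], cols[, 2], cols[, 3]), con)
  invisible(path)
}
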