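# Ensemble surface sampling by entropy optimization.
#
# Landmarks are optimized under a two-term cost Q = H(Z) - sum_j H(P_j):
# the sample entropy of the surfaces' shape-space distribution (N surfaces,
# each summarized by the 3M-vector of its landmark coordinates) is minimized
# to tighten cross-surface correspondence, while the per-surface entropies of
# the landmark point distributions (geodesic Gaussian kernel density
# estimates) are maximized to spread landmarks uniformly. Both gradients live
# in the tangent planes of the landmarks' faces and positions are updated with
# the exponential map, so landmarks never leave their surfaces. Landmark
# count grows by iterative splitting: 1 -> 2 -> 4 -> ... -> M_target.

# --- densities and the uniformity gradient ----------------------------------

#' Geodesic kernel density estimate at one landmark
#'
#' Parzen density of the landmark distribution on a single surface, using a
#' Gaussian kernel in geodesic distance:
#' `p(x_i) = 1/(M-1) * sum_{k != i} exp(-d_g(x_i,x_k)^2 / (2 sigma^2)) / (2 pi sigma^2)`.
#'
#' @param mesh a [triangle_mesh()].
#' @param landmarks a [landmark_set()] with at least 2 points.
#' @param i landmark index at which to evaluate.
#' @param sigma kernel bandwidth (length units).
#' @param distances optional precomputed length-M vector of geodesic distances
#'   from landmark `i` to all landmarks (entry `i` ignored).
#' @return the density value (strictly positive).
#' @export
surface_density <- function(mesh, landmarks, i, sigma, distances = NULL) {
  M <- n_landmarks(landmarks)
  if (M < 2) stop("need at least 2 landmarks for a density estimate")
  stopifnot(sigma > 0)
  if (is.null(distances))
    distances <- geodesic_distance_matrix(mesh, ls_subset(landmarks, i),
                                          landmarks)[1, ]
  d <- distances[-i]
  sum(exp(-d^2 / (2 * sigma^2))) / ((M - 1) * 2 * pi * sigma^2)
}

#' Uniformity (entropy) gradient at one landmark
#'
#' Gradient of the log kernel density at landmark `i` with respect to its own
#' position, expressed in the tangent plane of its face:
#' `g_i = (1/sigma^2) * sum_k w_ik log_map(x_i, x_k) / sum_k w_ik`, with
#' Gaussian weights `w_ik = exp(-d_g^2 / (2 sigma^2))`. The entropy-ascent
#' (uniformity) move is `-g_i`: away from the weighted mass of the neighbors.
#' If all weights underflow (isolated landmark) the zero vector is returned.
#'
#' @param mesh a [triangle_mesh()].
#' @param landmarks a [landmark_set()].
#' @param i landmark index.
#' @param sigma kernel bandwidth.
#' @param method `"exact"` uses the full logarithmic map (small landmark
#'   sets); `"chord"` projects the Euclidean chord onto the tangent plane and
#'   rescales it to geodesic length, the fast approximation used inside the
#'   optimizer where neighbors are within a few bandwidths.
#' @return a [tangent_vector()] at landmark `i`.
#' @export
uniformity_gradient <- function(mesh, landmarks, i, sigma,
                                method = c("exact", "chord")) {
  method <- match.arg(method)
  M <- n_landmarks(landmarks)
  if (M < 2) stop("need at least 2 landmarks")
  a <- surface_point(landmarks$face[i], landmarks$bary[i, ])
  d <- geodesic_distance_matrix(mesh, ls_subset(landmarks, i), landmarks)[1, ]
  w <- exp(-d^2 / (2 * sigma^2)); w[i] <- 0
  sw <- sum(w)
  if (sw < 1e-300)
    return(structure(list(anchor = a, vec = c(0, 0, 0)),
                     class = "tangent_vector"))
  nrm <- face_normals(mesh)[a$face, ]
  xyz <- sp_position(mesh, landmarks)
  acc <- c(0, 0, 0)
  for (k in seq_len(M)) {
    if (k == i || w[k] == 0) next
    if (method == "exact") {
      lv <- log_map(mesh, a, surface_point(landmarks$face[k],
                                           landmarks$bary[k, ]))$vec
    } else {
      ch <- xyz[k, ] - xyz[i, ]
      pr <- ch - sum(ch * nrm) * nrm
      pl <- sqrt(sum(pr^2))
      lv <- if (pl > 0) pr * (d[k] / pl) else c(0, 0, 0)
    }
    acc <- acc + w[k] * lv
  }
  structure(list(anchor = a, vec = unname(acc / (sigma^2 * sw))),
            class = "tangent_vector")
}

# --- shape-space entropy and the correspondence gradient --------------------

#' Shape-space sample entropy of an ensemble
#'
#' Gaussian-model entropy `H = 1/2 * sum_k log(lambda_k + alpha)` over the 3M
#' eigenvalues of the sample covariance of the shape vectors (additive
#' constants dropped), computed through the N x N dual Gram matrix so the cost
#' is independent of M; the `3M - N` eigenvalues beyond the sample rank
#' contribute `log alpha` each.
#'
#' @param shape_vectors numeric `N x 3M` matrix, one row per surface.
#' @param alpha positive covariance regularizer (squared length units).
#' @return scalar entropy.
#' @export
shape_entropy <- function(shape_vectors, alpha) {
  z <- as.matrix(shape_vectors)
  n <- nrow(z); p <- ncol(z)
  if (n < 2) stop("need at least 2 shape vectors")
  stopifnot(alpha > 0)
  y <- sweep(z, 2, colMeans(z))
  if (p <= n) {
    lam <- eigen(crossprod(y) / (n - 1), symmetric = TRUE,
                 only.values = TRUE)$values
    return(0.5 * sum(log(pmax(lam, 0) + alpha)))
  }
  gram <- tcrossprod(y) / (n - 1)           # N x N dual
  lam <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  0.5 * (sum(log(pmax(lam, 0) + alpha)) + (p - n) * log(alpha))
}

#' Correspondence (shape-entropy) gradient
#'
#' Raw gradient of [shape_entropy()] with respect to the landmark coordinates,
#' with the ensemble mean held fixed:
#' `G = Y (Y'Y/(N-1) + alpha I)^-1 / (N-1)` where `Y` is the `3M x N` centered
#' data matrix (regularization guarantees invertibility for rank-deficient
#' ensembles). When per-landmark face normals are supplied, each 3-vector is
#' also projected onto its landmark's face plane, which is the form consumed
#' by [gessa_step()].
#'
#' @param shape_vectors numeric `N x 3M` matrix.
#' @param alpha positive regularizer.
#' @param normals optional list of N `M x 3` face-normal matrices.
#' @return list with `raw` (`N x 3M` gradient matrix) and, when normals are
#'   given, `projected` (list of N `M x 3` tangent update matrices).
#' @export
correspondence_gradient <- function(shape_vectors, alpha, normals = NULL) {
  z <- as.matrix(shape_vectors)
  n <- nrow(z)
  if (n < 2) stop("need at least 2 shape vectors")
  stopifnot(alpha > 0)
  yc <- sweep(z, 2, colMeans(z))            # N x 3M; Y = t(yc)
  gram <- tcrossprod(yc) / (n - 1)          # Y'Y/(N-1), N x N
  ginv <- solve(gram + alpha * diag(n))
  raw <- (ginv %*% yc) / (n - 1)            # t(Y %*% ginv)/(N-1), N x 3M
  out <- list(raw = raw)
  if (!is.null(normals)) {
    out$projected <- lapply(seq_len(n), function(j) {
      gj <- matrix(raw[j, ], ncol = 3, byrow = TRUE)   # M x 3
      nj <- normals[[j]]
      gj - rowSums(gj * nj) * nj
    })
  }
  out
}

# --- per-mesh preparation and fast internal distances ------------------------

# precomputed per-mesh machinery for the optimizer: Steiner graph,
# vertex-to-vertex geodesic matrix, mean edge length
gessa_prep <- function(mesh, n_steiner = 2L) {
  key <- paste0("gessa_prep_", n_steiner)
  cached(mesh, key, function() {
    gg <- geodesic_graph(mesh, n_steiner)
    nv <- gg$n_vertices
    D_vv <- igraph::distances(gg$graph, v = seq_len(nv), to = seq_len(nv),
                              algorithm = "dijkstra")
    el <- gg$edges
    mean_edge <- mean(sqrt(rowSums((mesh$vertices[el[, 1], , drop = FALSE] -
                                    mesh$vertices[el[, 2], , drop = FALSE])^2)))
    list(gg = gg, D_vv = D_vv, mean_edge = mean_edge)
  })
}

# geodesic distances between all landmark pairs within `cutoff`, approximated
# through the vertex-to-vertex matrix with per-endpoint chord corrections;
# sub-edge-length separations use the chord itself. Returns symmetric pair
# list (i, k, d) with i != k.
ls_pair_distances <- function(mesh, prep, ls, xyz, cutoff) {
  M <- nrow(xyz)
  if (M < 2) return(list(i = integer(0), k = integer(0), d = numeric(0)))
  dE <- as.matrix(stats::dist(xyz))
  sel <- which(dE <= cutoff, arr.ind = TRUE)
  sel <- sel[sel[, 1] != sel[, 2], , drop = FALSE]
  i <- sel[, 1]; k <- sel[, 2]
  de <- dE[sel]
  fv <- mesh$faces[ls$face, , drop = FALSE]        # M x 3 vertex ids
  # chord distances from each landmark to its face's vertices
  ca <- vapply(1:3, function(a)
    sqrt(rowSums((xyz - mesh$vertices[fv[, a], , drop = FALSE])^2)),
    numeric(M))
  d <- rep(Inf, length(i))
  for (a in 1:3) for (b in 1:3) {
    d <- pmin(d, ca[i, a] + prep$D_vv[cbind(fv[i, a], fv[k, b])] + ca[k, b])
  }
  d <- pmax(d, de)
  # sub-edge-length separations: the chord is the better estimate; blend
  # linearly over [h, 2h] so the estimator is continuous in the positions
  # (a jump here would put spurious noise into the cost used by backtracking)
  h <- prep$mean_edge
  wmix <- pmin(pmax((de - h) / h, 0), 1)
  d <- (1 - wmix) * de + wmix * d
  same_face <- ls$face[i] == ls$face[k]
  d[same_face] <- de[same_face]
  keep <- d <= cutoff
  list(i = i[keep], k = k[keep], d = d[keep], de = de[keep])
}

# per-surface densities, entropy and uniformity move field, vectorized over
# the truncated pair list; chord log maps in the tangent plane.
#
# The kernel bandwidth is adapted per landmark to the local nearest-neighbor
# spacing (clamped to [sigma/100, sigma]): right after a split, twin landmarks
# sit far below the level bandwidth, and with a fixed kernel their mutual
# repulsion would be diluted by every neighbor within 4 sigma, separating the
# pair by only a few percent per iteration. At the local scale the twin
# dominates the kernel sum and separation proceeds at a scale-free gamma rate.
# The returned `move` is sigma_i^2 times the entropy gradient -- the weighted
# mean log map toward the neighbors, a length-scaled quantity; the uniformity
# update in gessa_step is -gamma * move.
surface_terms <- function(mesh, prep, ls, xyz, sigma, cutoff = 4 * sigma) {
  M <- nrow(xyz)
  if (M < 2)
    return(list(density = numeric(0), entropy = 0,
                move = matrix(0, M, 3)))
  pr <- ls_pair_distances(mesh, prep, ls, xyz, cutoff)
  nn <- rep(sigma, M)
  if (length(pr$i) > 0) {
    mn <- tapply(pr$d, pr$i, min)
    nn[as.integer(names(mn))] <- mn
  }
  sig_i <- pmin(pmax(nn, sigma / 100), sigma)
  w <- exp(-pr$d^2 / (2 * sig_i[pr$i]^2))
  sw <- rep(0, M)
  if (length(pr$i) > 0) {
    agg <- rowsum(w, pr$i)
    sw[as.integer(rownames(agg))] <- agg
  }
  dens <- pmax(sw, 1e-300) / ((M - 1) * 2 * pi * sig_i^2)
  nrm <- face_normals(mesh)[ls$face, , drop = FALSE]
  move <- matrix(0, M, 3)
  if (length(pr$i) > 0) {
    ch <- xyz[pr$k, , drop = FALSE] - xyz[pr$i, , drop = FALSE]
    ni <- nrm[pr$i, , drop = FALSE]
    proj <- ch - rowSums(ch * ni) * ni
    pl <- sqrt(rowSums(proj^2))
    scale <- ifelse(pl > 0, pr$d / pl, 0)
    contrib <- proj * (w * scale)
    for (col in 1:3) {
      agg <- rowsum(contrib[, col], pr$i)
      move[as.integer(rownames(agg)), col] <- agg
    }
    nz <- sw > 1e-300
    move[nz, ] <- move[nz, ] / sw[nz]
  }
  list(density = dens, entropy = -mean(log(dens)), move = move)
}

# --- optimizer state, step, splitting ----------------------------------------

#' Create an ensemble-correspondence optimizer state
#'
#' Bundles the meshes, the current index-aligned landmark sets and the
#' optimizer parameters. Heavy per-mesh structures (geodesic graph,
#' vertex-distance matrix) are cached on the meshes.
#'
#' @param meshes list of [triangle_mesh()]; all landmark sets must have equal
#'   length.
#' @param landmarks list of [landmark_set()], one per mesh.
#' @param sigma kernel bandwidth; `NULL` = `sqrt(mean area / (pi * M))`, the
#'   mean inter-landmark spacing.
#' @param gamma gradient step as a multiple of `sigma^2` (the uniformity
#'   gradient scales as `1/sigma`, so the move length scales as
#'   `gamma * sigma`).
#' @param alpha shape-covariance regularizer; `NULL` = `1e-4 * trace/(3M)` of
#'   the current shape covariance (floored for degenerate ensembles).
#' @param weight_shape,weight_uniform relative weights of the correspondence
#'   and uniformity terms (both 1 in the canonical cost).
#' @param n_steiner accuracy of the internal geodesic machinery.
#' @return a `gessa_state` list.
#' @export
gessa_state <- function(meshes, landmarks, sigma = NULL, gamma = 0.1,
                        alpha = NULL, weight_shape = 1, weight_uniform = 1,
                        n_steiner = 2L) {
  M <- n_landmarks(landmarks[[1]])
  stopifnot(length(meshes) == length(landmarks),
            all(vapply(landmarks, n_landmarks, 0L) == M))
  mean_area <- mean(vapply(meshes, mesh_area, 0))
  if (is.null(sigma)) sigma <- sqrt(mean_area / (pi * max(M, 1)))
  if (is.null(alpha)) alpha <- auto_alpha(meshes, landmarks, sigma, mean_area)
  stopifnot(sigma > 0, gamma > 0, alpha > 0)
  structure(list(meshes = meshes, landmarks = landmarks, sigma = sigma,
                 gamma = gamma, alpha = alpha, weight_shape = weight_shape,
                 weight_uniform = weight_uniform,
                 n_steiner = as.integer(n_steiner), level = 0L),
            class = "gessa_state")
}

# automatic covariance regularizer: a fraction of the current shape variance,
# floored at (0.32 sigma)^2 -- cross-surface variation below a third of the
# landmark spacing is treated as sampling noise, which also bounds the
# log-det gradient and prevents the degenerate all-landmarks-collapse solution
auto_alpha <- function(meshes, landmarks, sigma, mean_area) {
  z <- shape_matrix(meshes, landmarks)
  tr <- sum(sweep(z, 2, colMeans(z))^2) / max(nrow(z) - 1, 1)
  max(1e-4 * tr / ncol(z), 0.1 * sigma^2, 1e-12 * mean_area)
}

# N x 3M matrix of concatenated landmark coordinates (landmark-major blocks)
shape_matrix <- function(meshes, landmarks) {
  do.call(rbind, lapply(seq_along(meshes), function(j) {
    as.vector(t(sp_position(meshes[[j]], landmarks[[j]])))
  }))
}

# total cost Q = weight_shape * H(Z) - weight_uniform * sum_j H(P_j)
gessa_cost <- function(state) {
  n <- length(state$meshes)
  h_surf <- 0
  for (j in seq_len(n)) {
    prep <- gessa_prep(state$meshes[[j]], state$n_steiner)
    xyz <- sp_position(state$meshes[[j]], state$landmarks[[j]])
    st <- surface_terms(state$meshes[[j]], prep, state$landmarks[[j]], xyz,
                        state$sigma)
    h_surf <- h_surf + st$entropy
  }
  h_shape <- if (n >= 2 && state$weight_shape > 0)
    shape_entropy(shape_matrix(state$meshes, state$landmarks), state$alpha)
  else 0
  state$weight_shape * h_shape - state$weight_uniform * h_surf
}

#' One gradient-descent step of the ensemble correspondence cost
#'
#' For every surface and landmark, combines the projected correspondence
#' gradient and the uniformity term into a tangent update
#' `u = -gamma * (alpha (N-1) weight_shape * corr + weight_uniform * move)`
#' and displaces the landmark with the exponential map. Each term is
#' preconditioned by its natural scale: the uniformity `move` is the kernel
#' bandwidth squared times the entropy gradient (the weighted mean log map
#' toward the neighbors, a length), and `alpha (N-1)` turns the
#' correspondence descent into a per-eigendirection contraction of the shape
#' covariance by `gamma * alpha / (lambda + alpha)` -- strong on sub-noise
#' directions, gentle on genuine shape variance, and bounded by `gamma`.
#' If the cost does not decrease, the step is retried with a halved `gamma`
#' (up to `max_halvings`) and rejected outright when halving does not help,
#' so the cost never increases across accepted steps; the reduced step size
#' is kept in the returned state (and recovers in [run_gessa()]).
#'
#' @param state a [gessa_state()].
#' @param max_halvings backtracking halvings before accepting the last trial.
#' @return list with `state` (updated) and `cost` (Q after the step).
#' @export
gessa_step <- function(state, max_halvings = 5L) {
  n <- length(state$meshes)
  M <- n_landmarks(state$landmarks[[1]])
  # per-surface uniformity terms
  moves_u <- vector("list", n)
  h_surf <- 0
  for (j in seq_len(n)) {
    prep <- gessa_prep(state$meshes[[j]], state$n_steiner)
    xyz <- sp_position(state$meshes[[j]], state$landmarks[[j]])
    st <- surface_terms(state$meshes[[j]], prep, state$landmarks[[j]], xyz,
                        state$sigma)
    moves_u[[j]] <- st$move
    h_surf <- h_surf + st$entropy
  }
  # correspondence term
  if (n >= 2 && state$weight_shape > 0) {
    z <- shape_matrix(state$meshes, state$landmarks)
    normals <- lapply(seq_len(n), function(j)
      face_normals(state$meshes[[j]])[state$landmarks[[j]]$face, ,
                                      drop = FALSE])
    cg <- correspondence_gradient(z, state$alpha, normals = normals)
    grads_c <- cg$projected
    q_before <- state$weight_shape * shape_entropy(z, state$alpha) -
      state$weight_uniform * h_surf
  } else {
    grads_c <- rep(list(matrix(0, M, 3)), n)
    q_before <- -state$weight_uniform * h_surf
  }
  gamma <- state$gamma
  corr_scale <- state$alpha * max(n - 1, 1)
  for (try in 0:max_halvings) {
    new_landmarks <- vector("list", n)
    for (j in seq_len(n)) {
      upd <- -gamma * (corr_scale * state$weight_shape * grads_c[[j]] +
                         state$weight_uniform * moves_u[[j]])
      ls <- state$landmarks[[j]]
      tp <- trace_pack(state$meshes[[j]])
      nf <- integer(M); nb <- matrix(0, M, 3)
      for (i in seq_len(M)) {
        len <- sqrt(sum(upd[i, ]^2))
        if (len == 0) { nf[i] <- ls$face[i]; nb[i, ] <- ls$bary[i, ]; next }
        tr <- trace_geodesic_fast(tp, ls$face[i], ls$bary[i, ], upd[i, ], len)
        nf[i] <- tr$face; nb[i, ] <- tr$bary
      }
      new_landmarks[[j]] <- landmark_set(nf, nb)
    }
    cand <- state
    cand$landmarks <- new_landmarks
    cand$gamma <- gamma
    q_after <- gessa_cost(cand)
    if (q_after <= q_before + 1e-9 * max(abs(q_before), 1))
      return(list(state = cand, cost = q_after))
    gamma <- gamma / 2
  }
  # no decreasing step found: reject the move, keep the reduced step size
  state$gamma <- gamma
  list(state = state, cost = q_before)
}

#' Split every landmark in two
#'
#' Doubles the landmark count: each parent stays in place and spawns a child
#' offset by an exponential-map step of length `epsilon * sigma`. The offset
#' direction is drawn once per landmark index (in a local tangent frame) and
#' reused on every surface, so children inherit the parents' correspondence.
#' Parent `k` becomes children `2k - 1` and `2k`.
#'
#' @param state a [gessa_state()].
#' @param epsilon offset length as a fraction of `sigma`.
#' @return the state with `2M` landmarks per surface (and `level + 1`).
#' @export
split_landmarks <- function(state, epsilon = 0.1) {
  M <- n_landmarks(state$landmarks[[1]])
  # one direction per landmark index, drawn in WORLD coordinates and shared by
  # all surfaces: projected onto each landmark's (nearly parallel) face plane
  # it yields nearly parallel offsets, so the split adds no spurious
  # cross-surface variance and the children stay in correspondence
  dirs <- matrix(stats::rnorm(3 * M), M, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (j in seq_along(state$meshes)) {
    mesh <- state$meshes[[j]]
    ls <- state$landmarks[[j]]
    tp <- trace_pack(mesh)
    nrm <- face_normals(mesh)[ls$face, , drop = FALSE]
    nf <- integer(2 * M); nb <- matrix(0, 2 * M, 3)
    for (i in seq_len(M)) {
      nf[2 * i - 1] <- ls$face[i]; nb[2 * i - 1, ] <- ls$bary[i, ]
      dir <- dirs[i, ] - sum(dirs[i, ] * nrm[i, ]) * nrm[i, ]
      dl <- sqrt(sum(dir^2))
      if (dl < 0.1) {  # pick a stable fallback when the draw is near-normal
        alt <- if (abs(nrm[i, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        dir <- alt - sum(alt * nrm[i, ]) * nrm[i, ]
        dl <- sqrt(sum(dir^2))
      }
      dir <- dir / dl
      tr <- trace_geodesic_fast(tp, ls$face[i], ls$bary[i, ],
                                dir, epsilon * state$sigma)
      nf[2 * i] <- tr$face; nb[2 * i, ] <- tr$bary
    }
    state$landmarks[[j]] <- landmark_set(nf, nb)
  }
  state$level <- state$level + 1L
  state
}

#' Run the full ensemble landmarking algorithm
#'
#' Seeds one random landmark per surface, then alternates gradient
#' optimization of the correspondence cost with landmark splitting until
#' `M_target` landmarks per surface are placed and optimized. `M_target` must
#' be a power of two (the doubling schedule: 4096 landmarks = 12 splitting
#' rounds). All randomness (seeding, split directions) flows from `seed`.
#'
#' @param meshes list of two or more [triangle_mesh()]es, pre-aligned (see
#'   [align_from_fiducials()] and [icp_align()]).
#' @param M_target landmarks per surface; a power of two.
#' @param gamma step-size multiplier (see [gessa_state()]).
#' @param alpha covariance regularizer (`NULL` = automatic, per level).
#' @param epsilon split offset as a fraction of sigma.
#' @param iters_per_level maximum optimization iterations per level; a vector
#'   is indexed by level (last entry reused beyond its length), which allows
#'   spending more of the budget on the cheap coarse levels where the
#'   correspondence is established.
#' @param tol relative cost-change convergence tolerance: a level stops after
#'   5 consecutive iterations with `|dQ| < tol * |Q|`.
#' @param seed integer RNG seed; fixed seed gives bit-identical landmarks.
#' @param n_steiner internal geodesic accuracy.
#' @param weight_shape,weight_uniform cost-term weights.
#' @param verbose print per-level progress.
#' @return list with `landmarks` (list of index-aligned [landmark_set()]s),
#'   `log` (per-iteration cost trace), and the final `state`.
#' @export
run_gessa <- function(meshes, M_target, gamma = 0.1, alpha = NULL,
                      epsilon = 0.1, iters_per_level = 100, tol = 1e-6,
                      seed = 1, n_steiner = 2L, weight_shape = 1,
                      weight_uniform = 1, verbose = FALSE) {
  lv <- log2(M_target)
  if (M_target < 1 || abs(lv - round(lv)) > 1e-9)
    stop("M_target must be a power of two (doubling schedule)")
  if (length(meshes) < 2) stop("need an ensemble of at least 2 meshes")
  set.seed(seed)
  landmarks <- lapply(meshes, random_surface_points, n = 1)
  state <- gessa_state(meshes, landmarks, gamma = gamma, alpha = alpha,
                       n_steiner = n_steiner, weight_shape = weight_shape,
                       weight_uniform = weight_uniform)
  log_rows <- list()
  optimize_level <- function(state, n_iters) {
    q_prev <- NA_real_; calm <- 0L
    for (it in seq_len(n_iters)) {
      stp <- gessa_step(state)
      state <- stp$state
      # let a halved step size recover so one noisy evaluation cannot
      # permanently stall the descent
      state$gamma <- min(gamma, state$gamma * 1.5)
      log_rows[[length(log_rows) + 1]] <<-
        data.frame(level = state$level, M = n_landmarks(state$landmarks[[1]]),
                   iter = it, Q = stp$cost, gamma = state$gamma)
      if (!is.na(q_prev)) {
        calm <- if (abs(stp$cost - q_prev) < tol * max(abs(stp$cost), 1e-12))
          calm + 1L else 0L
        if (calm >= 5L) break
      }
      q_prev <- stp$cost
    }
    state
  }
  mean_area <- mean(vapply(meshes, mesh_area, 0))
  repeat {
    M <- n_landmarks(state$landmarks[[1]])
    state$sigma <- sqrt(mean_area / (pi * M))
    if (is.null(alpha))     # refresh the automatic regularizer per level
      state$alpha <- auto_alpha(state$meshes, state$landmarks, state$sigma,
                                mean_area)
    state$gamma <- gamma    # reset the step size at each level
    level_iters <- iters_per_level[min(state$level + 1L,
                                       length(iters_per_level))]
    if (M >= 2 || length(meshes) >= 2)
      state <- optimize_level(state, level_iters)
    if (verbose)
      message(sprintf("level %d: M = %d, Q = %.6g", state$level, M,
                      if (length(log_rows)) utils::tail(log_rows, 1)[[1]]$Q
                      else NA))
    if (M >= M_target) break
    state <- split_landmarks(state, epsilon = epsilon)
  }
  list(landmarks = state$landmarks,
       log = do.call(rbind, log_rows),
       state = state)
}

#' Validate generated landmarks against ground-truth fiducials
#'
#' For every ground-truth label, computes the mean (over surfaces) of the
#' distance from the ground-truth point to its nearest generated landmark,
#' the corresponding standard deviation, and both normalized by the mean
#' facial width (the distance between the two `width_pair` fiducials, e.g.
#' the zygions), mirroring the usual dense-landmarking validation protocol.
#'
#' @param landmark_sets list of [landmark_set()]s (one per surface).
#' @param meshes matching list of meshes.
#' @param groundtruth list (one per surface) of named `k x 3` matrices: rows
#'   are labelled ground-truth points (same labels on every surface).
#' @param width_pair character(2): the labels whose distance defines the
#'   facial width.
#' @return data.frame with `label`, `mean_distance`, `sd_distance`,
#'   `norm_mean`, `norm_sd`.
#' @export
validate_against_fiducials <- function(landmark_sets, meshes, groundtruth,
                                       width_pair) {
  labels <- rownames(groundtruth[[1]])
  for (gt in groundtruth)
    if (!all(labels %in% rownames(gt)))
      stop("a ground-truth label is missing on some surface")
  if (!all(width_pair %in% labels)) stop("width_pair labels not found")
  n <- length(landmark_sets)
  dmat <- matrix(NA_real_, n, length(labels),
                 dimnames = list(NULL, labels))
  widths <- numeric(n)
  for (s in seq_len(n)) {
    xyz <- sp_position(meshes[[s]], landmark_sets[[s]])
    gt <- groundtruth[[s]][labels, , drop = FALSE]
    nn <- nearest_rows(gt, xyz)
    dmat[s, ] <- sqrt(nn$dist2)
    widths[s] <- sqrt(sum((groundtruth[[s]][width_pair[1], ] -
                           groundtruth[[s]][width_pair[2], ])^2))
  }
  mean_width <- mean(widths)
  data.frame(label = labels,
             mean_distance = colMeans(dmat),
             sd_distance = apply(dmat, 2, stats::sd),
             norm_mean = colMeans(dmat) / mean_width,
             norm_sd = apply(dmat, 2, stats::sd) / mean_width,
             row.names = NULL)
}
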