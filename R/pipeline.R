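# End-to-end pipeline driver: simulate -> align -> landmark -> phenotype ->
# heritability -> maps, from a single YAML config. Every stage writes its
# artifacts plus a JSON provenance record; identical config + seed reproduces
# identical outputs.

#' Run the phenotyping/heritability pipeline from a config
#'
#' Executes the requested stages in order. Supported stages and their
#' config blocks (all optional; defaults in parentheses):
#' \describe{
#'   \item{simulate}{`n_mz`, `n_dz` (10/10), `resolution` (3), `noise_sd`
#'     (0.15), `a2`/`c2` per bump (first bump heritable 0.8, others 0),
#'     writes `meshes/subject_<i>.ply`, `subjects.csv`, `truth.csv`.}
#'   \item{align}{rigid ICP of every mesh onto the reference mesh
#'     (`reference`, default the first subject; `max_iters`, `tol`).}
#'   \item{gessa}{`M` (64), `iters_per_level` (10), `gamma`, `epsilon`,
#'     `tol`; writes `landmarks/subject_<i>.csv` and `gessa_log.json`.}
#'   \item{curvature}{`radius` (auto); writes `curvature_<index>.csv`.}
#'   \item{traits}{`picks` (named label: [x,y,z] map in the config) plus
#'     `pairs`; writes `distance_traits_<mode>.csv`.}
#'   \item{heritability}{`index` ("MC"), `use_age` (true); writes
#'     `heritability_<index>.csv`.}
#'   \item{maps}{writes `heritability_map_<index>.ply` (+ CSV) on the
#'     average-face landmarks.}
#'   \item{sempower}{`n_mz`, `n_dz`, `h2`, `c2`, `n_replicates`, `alpha`;
#'     writes `power.json`.}
#' }
#' The top-level keys are `stages` (character vector, executed in the given
#' order), `seed` (integer; all stage randomness derives from it) and
#' `output_dir`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param output_dir overrides the config's `output_dir`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file or a list")
  out <- output_dir %||% cfg$output_dir %||% stop("config: output_dir missing")
  stages <- cfg$stages %||% stop("config: stages missing")
  known <- c("simulate", "align", "gessa", "curvature", "traits",
             "heritability", "maps", "sempower")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("config: unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- cfg$seed %||% 1L
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  for (st in stages) {
    t0 <- Sys.time()
    set.seed(seed + match(st, known))       # stage-specific deterministic seed
    switch(st,
           simulate = stage_simulate(cfg$simulate, out, env),
           align = stage_align(cfg$align, out, env),
           gessa = stage_gessa(cfg$gessa, out, env),
           curvature = stage_curvature(cfg$curvature, out, env),
           traits = stage_traits(cfg$traits, out, env),
           heritability = stage_heritability(cfg$heritability, out, env),
           maps = stage_maps(cfg$maps, out, env),
           sempower = stage_sempower(cfg$sempower, out, env))
    write_provenance(out, st, cfg[[st]], seed,
                     as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_provenance <- function(out, stage, params, seed, elapsed) {
  rec <- list(stage = stage, parameters = params, seed = seed,
              elapsed_seconds = round(elapsed, 3),
              package_version = as.character(utils::packageVersion("facetwin")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(out, paste0("provenance_", stage,
                                                  ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_simulate <- function(p, out, env) {
  p <- p %||% list()
  base <- face_params(noise_sd = p$noise_sd %||% 0.15)
  nb <- length(base$bumps)
  a2 <- rep_len(p$a2 %||% c(0.8, rep(0, nb - 1)), nb)
  c2 <- rep_len(p$c2 %||% 0, nb)
  sim <- simulate_twin_ensemble(
    base, data.frame(a2 = a2, c2 = c2, e2 = 1 - a2 - c2),
    n_mz = p$n_mz %||% 10, n_dz = p$n_dz %||% 10,
    resolution = p$resolution %||% 3)
  dir.create(file.path(out, "meshes"), showWarnings = FALSE)
  for (i in seq_along(sim$meshes))
    write_mesh(sim$meshes[[i]],
               file.path(out, "meshes", sprintf("subject_%03d.ply", i)))
  utils::write.csv(sim$subjects, file.path(out, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(out, "truth.csv"), row.names = FALSE)
  env$meshes <- sim$meshes
  env$subjects <- sim$subjects
}

load_ensemble <- function(out, env) {
  if (!is.null(env$meshes)) return()
  files <- sort(list.files(file.path(out, "meshes"), pattern = "\\.ply$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no meshes found: run the simulate stage or ",
                               "point the config at existing outputs")
  env$meshes <- lapply(files, read_mesh)
  env$subjects <- utils::read.csv(file.path(out, "subjects.csv"))
}

stage_align <- function(p, out, env) {
  p <- p %||% list()
  load_ensemble(out, env)
  ref <- env$meshes[[p$reference %||% 1]]
  env$meshes <- lapply(env$meshes, function(m)
    icp_align(m, ref, max_iters = p$max_iters %||% 30,
              tol = p$tol %||% 1e-6)$mesh)
}

stage_gessa <- function(p, out, env) {
  p <- p %||% list()
  load_ensemble(out, env)
  res <- run_gessa(env$meshes, M_target = p$M %||% 64,
                   gamma = p$gamma %||% 0.1,
                   epsilon = p$epsilon %||% 0.1,
                   iters_per_level = p$iters_per_level %||% 10,
                   tol = p$tol %||% 1e-6,
                   seed = p$seed %||% 1)
  env$landmarks <- res$landmarks
  dir.create(file.path(out, "landmarks"), showWarnings = FALSE)
  for (i in seq_along(res$landmarks)) {
    ls <- res$landmarks[[i]]
    xyz <- sp_position(env$meshes[[i]], ls)
    utils::write.csv(
      data.frame(landmark_id = seq_len(n_landmarks(ls)),
                 face_index = ls$face, b0 = ls$bary[, 1], b1 = ls$bary[, 2],
                 b2 = ls$bary[, 3], x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      file.path(out, "landmarks", sprintf("subject_%03d.csv", i)),
      row.names = FALSE)
  }
  jsonlite::write_json(res$log, file.path(out, "gessa_log.json"),
                       dataframe = "columns", digits = NA)
}

load_landmarks <- function(out, env) {
  if (!is.null(env$landmarks)) return()
  files <- sort(list.files(file.path(out, "landmarks"), pattern = "\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no landmark sets found: run the gessa stage")
  env$landmarks <- lapply(files, function(f) {
    d <- utils::read.csv(f)
    landmark_set(d$face_index, as.matrix(d[, c("b0", "b1", "b2")]))
  })
}

stage_curvature <- function(p, out, env) {
  p <- p %||% list()
  load_ensemble(out, env); load_landmarks(out, env)
  cm <- curvature_maps(env$meshes, env$landmarks, radius = p$radius,
                       subjects = env$subjects)
  env$curvature <- cm
  for (x in names(cm$traits)) {
    m <- cm$traits[[x]]
    colnames(m) <- paste0("landmark_", seq_len(ncol(m)))
    utils::write.csv(cbind(subject_id = env$subjects$subject_id, m),
                     file.path(out, sprintf("curvature_%s.csv", x)),
                     row.names = FALSE)
  }
}

stage_traits <- function(p, out, env) {
  p <- p %||% list()
  load_ensemble(out, env); load_landmarks(out, env)
  if (is.null(p$picks)) stop("traits stage requires labelled fiducial picks")
  picks <- do.call(rbind, lapply(p$picks, as.numeric))
  rownames(picks) <- names(p$picks)
  avg <- average_landmark_positions(env$meshes, env$landmarks)
  fid <- pick_fiducials(avg, picks)
  pairs <- p$pairs %||% DISTANCE_TRAIT_PAIRS
  for (mode in c("euclidean", "geodesic")) {
    tm <- distance_traits(env$meshes, env$landmarks, fid, pairs, mode)
    utils::write.csv(cbind(subject_id = env$subjects$subject_id, tm),
                     file.path(out, sprintf("distance_traits_%s.csv", mode)),
                     row.names = FALSE)
  }
}

#' Average-face landmark positions of an ensemble
#' @param meshes list of meshes.
#' @param landmark_sets matching index-aligned landmark sets.
#' @return `M x 3` matrix: per-landmark mean position across subjects.
#' @export
average_landmark_positions <- function(meshes, landmark_sets) {
  acc <- 0
  for (j in seq_along(meshes))
    acc <- acc + sp_position(meshes[[j]], landmark_sets[[j]])
  acc / length(meshes)
}

stage_heritability <- function(p, out, env) {
  p <- p %||% list()
  load_ensemble(out, env)
  index <- p$index %||% "MC"
  if (is.null(env$curvature)) {
    f <- file.path(out, sprintf("curvature_%s.csv", index))
    if (!file.exists(f)) stop("run the curvature stage first")
    d <- utils::read.csv(f)
    tm <- as.matrix(d[, -1])
  } else {
    tm <- env$curvature$traits[[index]]
    colnames(tm) <- paste0("landmark_", seq_len(ncol(tm)))
  }
  res <- mass_univariate(tm, env$subjects, use_age = p$use_age %||% TRUE,
                         se = isTRUE(p$se))
  env$heritability <- res
  env$heritability_index <- index
  utils::write.csv(res, file.path(out, sprintf("heritability_%s.csv", index)),
                   row.names = FALSE)
}

stage_maps <- function(p, out, env) {
  load_ensemble(out, env); load_landmarks(out, env)
  if (is.null(env$heritability)) stop("run the heritability stage first")
  avg <- average_landmark_positions(env$meshes, env$landmarks)
  res <- env$heritability
  heritability_map(pmin(pmax(res$h2, 0), 1), avg,
                   file.path(out, sprintf("heritability_map_%s.ply",
                                          env$heritability_index)),
                   gof_p = res$gof_p, model = res$model)
}

stage_sempower <- function(p, out, env) {
  p <- p %||% list()
  ps <- power_simulation(n_mz = p$n_mz %||% 197, n_dz = p$n_dz %||% 279,
                         h2_true = p$h2 %||% 0.3, c2_true = p$c2 %||% 0,
                         n_replicates = p$n_replicates %||% 1000,
                         alpha_level = p$alpha %||% 0.05)
  jsonlite::write_json(ps[c("rate", "se", "rejections", "n_replicates")],
                       file.path(out, "power.json"), auto_unbox = TRUE,
                       digits = NA)
}
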