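## Pipeline orchestration: strict YAML config, staged execution with
## provenance-stamped artifacts, and a summary report.

config_schema <- function() {
  list(
    seed = "required",
    output = "optional",
    stages = "optional",
    landscape = c("temperature", "halo_fraction", "halo_scale"),
    simulate = c("n_traj", "n_steps", "dt"),
    msm = c("k", "lag", "n_macro", "n_boot"),
    tpt = c("source", "sink"),
    adaptive = c("epochs", "traj_per_epoch", "steps", "mix"),
    cholmap = c("box", "n_particles", "n_frames", "concentration",
                "merge_radius", "cutoff", "sites", "step"))
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with strict schema validation: unknown top-level
#' keys or stage parameters are rejected, and the master seed is
#' mandatory. Per-stage seeds are derived from the master seed by fixed
#' offsets.
#'
#' @param file Path to a YAML file, or a named list.
#' @return Validated config list with class `pipeline_config`.
#' @export
read_config <- function(file) {
  cfg <- if (is.character(file)) yaml::read_yaml(file) else file
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed))
    stop("config must set a seed", call. = FALSE)
  for (stage in setdiff(names(schema), c("seed", "output", "stages"))) {
    bad <- setdiff(names(cfg[[stage]]), schema[[stage]])
    if (length(bad) > 0)
      stop("unknown keys in stage '", stage, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    output = "artifacts",
    stages = c("simulate", "msm", "tpt", "report"),
    landscape = list(temperature = 300, halo_fraction = 0.25,
                     halo_scale = 3),
    simulate = list(n_traj = 50, n_steps = 4000, dt = 0.012),
    msm = list(k = 100, lag = 10, n_macro = 6, n_boot = 50),
    tpt = list(source = "M4", sink = "M2"),
    adaptive = list(epochs = 5, traj_per_epoch = 10, steps = 400,
                    mix = 0.5),
    cholmap = list(box = c(20, 20, 12), n_particles = 60,
                   n_frames = 2500, concentration = NULL,
                   merge_radius = 8, cutoff = -0.22, sites = NULL,
                   step = 1))
  for (k in c("output", "stages"))
    cfg[[k]] <- unlist(cfg[[k]] %||% defaults[[k]])
  for (k in setdiff(names(defaults), c("output", "stages")))
    cfg[[k]] <- utils::modifyList(as.list(defaults[[k]]),
                                  as.list(cfg[[k]] %||% list()))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

provenance <- function(cfg, stage) {
  c(stage = stage, seed = as.character(cfg$seed),
    config_md5 = config_hash(cfg),
    package = paste0("a2amsm ",
                     as.character(utils::packageVersion("a2amsm"))))
}

need_artifact <- function(dir, file, stage) {
  p <- file.path(dir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run the '", stage,
         "' stage first", call. = FALSE)
  p
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing
#' provenance-stamped artifacts into the output directory. Stages:
#' `simulate` (Langevin trajectories on the reference landscape, written
#' as a feature table), `msm` (discretisation, reversible MSM, PCCA
#' macrostates, bootstrap populations), `tpt` (pathway decomposition of
#' the macrostate flux), `adaptive` (goal-directed campaign log),
#' `cholmap` (synthetic lipid scene, occupancy free-energy hotspots) and
#' `report` (summary tables). Identical configs give identical
#' artifacts.
#'
#' @param config Path to a YAML config or a config list.
#' @param out Output directory (overrides the config's `output`).
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, out = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_config(config)
  dir <- out %||% cfg$output
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- reference_landscape(
    temperature = cfg$landscape$temperature,
    halo_fraction = cfg$landscape$halo_fraction,
    halo_scale = cfg$landscape$halo_scale)
  for (stage in cfg$stages) {
    message("[a2amsm] stage ", stage, " ...")
    t0 <- Sys.time()
    switch(stage,
      simulate = stage_simulate(cfg, dir, model),
      msm = stage_msm(cfg, dir, model),
      tpt = stage_tpt(cfg, dir),
      adaptive = stage_adaptive(cfg, dir, model),
      cholmap = stage_cholmap(cfg, dir),
      report = stage_report(cfg, dir),
      stop("unknown stage: ", stage, call. = FALSE))
    message(sprintf("[a2amsm] stage %s done in %.1f s", stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }
  invisible(dir)
}

stage_simulate <- function(cfg, dir, model) {
  s <- cfg$simulate
  feats <- sample_langevin(model, s$n_traj, s$n_steps, dt = s$dt,
                           seed = cfg$seed + 11L)
  write_artifact(feats, file.path(dir, "features.tsv"),
                 provenance(cfg, "simulate"))
}

stage_msm <- function(cfg, dir, model) {
  need_artifact(dir, "features.tsv", "simulate")
  feats <- read_features(file.path(dir, "features.tsv"))
  m <- cfg$msm
  disc <- cluster_features(feats, k = m$k, seed = cfg$seed + 23L)
  pe <- bootstrap_populations(disc, model, lag = m$lag,
                              n_macro = m$n_macro, n_boot = m$n_boot,
                              seed = cfg$seed + 37L)
  write_artifact(as.data.frame(disc$centers),
                 file.path(dir, "centers.tsv"), provenance(cfg, "msm"))
  write_artifact(tibble::tibble(traj = disc$traj,
                                microstate = disc$assignment),
                 file.path(dir, "assignments.tsv"),
                 provenance(cfg, "msm"))
  dtr <- discrete_trajectories(disc)
  C <- count_matrix(dtr, lag = m$lag, n_states = m$k)
  fit <- estimate_msm(C, lag = m$lag)
  write_mtx(C, file.path(dir, "count_matrix.mtx"))
  write_mtx(fit$T, file.path(dir, "transition_matrix.mtx"))
  write_artifact(pe$summary, file.path(dir, "populations.tsv"),
                 provenance(cfg, "msm"))
  ## macrostate trajectory for downstream flux analysis
  macro <- suppressWarnings(pcca_macrostates(fit, m$n_macro))
  lab <- map_macrostates(macro, fit, disc$centers, model)
  micro2macro <- tibble::tibble(
    microstate = fit$active_set,
    macrostate = lab[macro$membership])
  write_artifact(micro2macro, file.path(dir, "macrostates.tsv"),
                 provenance(cfg, "msm"))
}

stage_tpt <- function(cfg, dir) {
  need_artifact(dir, "features.tsv", "simulate")
  need_artifact(dir, "macrostates.tsv", "msm")
  feats <- read_features(file.path(dir, "features.tsv"))
  m2m <- utils::read.table(file.path(dir, "macrostates.tsv"),
                           header = TRUE, sep = "\t",
                           comment.char = "#")
  ## macrostate-level chain re-estimated from the feature trajectories
  disc <- cluster_features(feats, k = cfg$msm$k, seed = cfg$seed + 23L)
  macro_traj <- m2m$macrostate[match(disc$assignment, m2m$microstate)]
  keep <- !is.na(macro_traj)
  dtr <- split(match(macro_traj[keep], sort(unique(macro_traj[keep]))),
               disc$traj[keep])
  labels <- sort(unique(macro_traj[keep]))
  C <- count_matrix(dtr, lag = cfg$msm$lag)
  fit <- estimate_msm(C, lag = cfg$msm$lag)
  A <- match(cfg$tpt$source, labels[fit$active_set])
  B <- match(cfg$tpt$sink, labels[fit$active_set])
  if (is.na(A) || is.na(B))
    stop("source/sink macrostate absent from the estimated model",
         call. = FALSE)
  fl <- net_flux(fit$T, A = A, B = B, pi = fit$pi,
                 labels = labels[fit$active_set])
  paths <- decompose_pathways(fl)
  paths$states <- NULL
  write_artifact(paths, file.path(dir, "pathways.tsv"),
                 provenance(cfg, "tpt"))
  write_dot(fl, file.path(dir, "flux.dot"))
}

stage_adaptive <- function(cfg, dir, model) {
  a <- cfg$adaptive
  st <- run_campaign(model, epochs = a$epochs,
                     traj_per_epoch = a$traj_per_epoch, steps = a$steps,
                     seed = cfg$seed + 53L, mix = a$mix)
  write_artifact(st$log, file.path(dir, "adaptive_log.tsv"),
                 provenance(cfg, "adaptive"))
}

stage_cholmap <- function(cfg, dir) {
  cc <- cfg$cholmap
  sites <- if (!is.null(cc$sites))
    dplyr::bind_rows(lapply(cc$sites, tibble::as_tibble)) else NULL
  scene <- cholesterol_scene(unlist(cc$box), cc$n_particles, cc$n_frames,
                             sites = sites, step = cc$step)
  pos <- sample_cholesterol_scene(scene, seed = cfg$seed + 71L)
  g <- occupancy_grid(pos, scene$box)
  conc <- cc$concentration %||% box_concentration(g, scene$n_particles)
  fe <- free_energy_grid(g, standard_occupancy(g, conc))
  write_dx(fe, file.path(dir, "cholesterol_dG.dx"))
  hs <- find_hotspots(fe, cc$merge_radius, cc$cutoff)
  write_hotspot_pdb(hs, file.path(dir, "hotspots.pdb"))
  write_artifact(as.data.frame(hs), file.path(dir, "hotspots.tsv"),
                 provenance(cfg, "cholmap"))
}

stage_report <- function(cfg, dir) {
  pops_p <- need_artifact(dir, "populations.tsv", "msm")
  pops <- utils::read.table(pops_p, header = TRUE, sep = "\t",
                            comment.char = "#")
  stopifnot(abs(sum(pops$population) - 1) < 1e-4)
  feats <- read_features(need_artifact(dir, "features.tsv", "simulate"))
  ## 2D landscape density histogram over the two descriptors
  bw <- 0.25
  dens <- feats |>
    dplyr::mutate(lock_bin = floor(.data$lock_distance / bw) * bw,
                  rmsd_bin = floor(.data$y753_rmsd / bw) * bw) |>
    dplyr::count(.data$lock_bin, .data$rmsd_bin)
  write_artifact(dens, file.path(dir, "report_density.tsv"),
                 provenance(cfg, "report"))
  pops$percent <- 100 * pops$population
  write_artifact(pops, file.path(dir, "report_populations.tsv"),
                 provenance(cfg, "report"))
  if (file.exists(file.path(dir, "pathways.tsv"))) {
    paths <- utils::read.table(file.path(dir, "pathways.tsv"),
                               header = TRUE, sep = "\t",
                               comment.char = "#")
    write_artifact(paths, file.path(dir, "report_pathways.tsv"),
                   provenance(cfg, "report"))
  } else {
    warning("no tpt artifact found; report omits the pathway section")
  }
}
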