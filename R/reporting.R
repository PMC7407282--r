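#' Physics summary table
#'
#' Cross-tabulates, per fluid, the apparent viscosity (mPa s), the
#' Herschel-Bulkley consistency and flow indices, the tube Reynolds number,
#' and the relaxation time of every particle (s), in the conventional
#' reporting units. Internally everything is strict SI; this is the
#' reporting layer.
#'
#' @param fluids List of [fluid_spec()] (default the L/M/H presets).
#' @param particles List of [particle_spec()] (default the presets).
#' @param hydraulic_diameter Hydraulic diameter for the Reynolds number, m
#'   (default 0.031, the partially filled tube).
#' @param mean_velocity Mean flow velocity for the Reynolds number, m s^-1
#'   (default 0.020, the wave speed).
#' @return A data.frame, one row per fluid, with a `t_o_<label>_s` column
#'   per particle.
#' @export
physics_table <- function(fluids = fluid_presets(),
                          particles = particle_presets(),
                          hydraulic_diameter = 0.031,
                          mean_velocity = 0.020) {
  if (!length(fluids)) stop("no fluids", call. = FALSE)
  if (!length(particles)) stop("no particles", call. = FALSE)
  rows <- lapply(fluids, function(f) {
    re <- reynolds_number(flow_spec(hydraulic_diameter, mean_velocity, f))
    base <- data.frame(fluid = f$label,
                       cmc_pct = 100 * f$cmc_fraction,
                       mu_A_mPa_s = 1000 * f$apparent_viscosity_ref,
                       K_Pa_sn = f$consistency, n = f$flow_index,
                       Re = re)
    for (p in particles) {
      nm <- paste0("t_o_", gsub("[^a-zA-Z0-9]+", "_", p$label), "_s")
      base[[nm]] <- relaxation_time(p, f)
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a named workflow from a configuration
#'
#' Dispatches one of the package's workflows and writes its outputs plus a
#' JSON manifest (inputs, seed, output files with checksums) into the
#' output directory, so a run can be reproduced from the manifest alone.
#'
#' Workflows: `"physics"` (the physics summary table), `"simulate"` (wall
#' protocol, one particle track, tracer profile and a synthetic haustral
#' series for the configured seed), `"analyze-tracks"` (smooth, register,
#' segment and analyse the configured track files), `"analyze-motility"`
#' (event detection, wave linking and motility index on a haustral-series
#' file).
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Required keys: `workflow`, `out_dir`; `seed` defaults to 1. Workflow
#'   sections: `tracks` (character vector of track files) for
#'   analyze-tracks, `series` (file) and `mode` for analyze-motility.
#' @return Invisibly, the manifest list.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  for (key in c("workflow", "out_dir"))
    if (is.null(config[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  workflow <- match.arg(config$workflow,
                        c("physics", "simulate", "analyze-tracks",
                          "analyze-motility"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  outputs <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  if (workflow == "physics") {
    emit(physics_table(), "physics_table.csv")
  } else if (workflow == "simulate") {
    cfg <- sim_config(seed = seed,
                      protocol = wave_protocol(n_waves = 3))
    field <- propagate_wave(cfg$protocol, cfg$kin, cfg$geometry)
    flow <- flow_from_occlusion(field, cfg)
    p <- file.path(out_dir, "occlusion_field.csv")
    write_occlusion_field(field, p); outputs <- c(outputs, p)
    tr <- simulate_particle_track(flow, cfg)
    p <- file.path(out_dir, "track_1.csv")
    write_track(tr, p); outputs <- c(outputs, p)
    ts <- simulate_tracer(flow, cfg)
    emit(data.frame(time = ts$time, t(ts$mass)), "tracer_profile.csv")
    hs <- simulate_haustral_series(
      data.frame(direction = "antegrade", velocity_cm_s = 2,
                 occlusion_pct = 40, onset = 10), seed = seed)
    hd <- data.frame(time = hs$time, t(hs$values))
    names(hd) <- c("time", sprintf("h%d@%.2f", seq_along(hs$positions),
                                   hs$positions))
    emit(hd, "haustral_series.csv")
  } else if (workflow == "analyze-tracks") {
    files <- config$tracks
    if (is.null(files) || !all(file.exists(files)))
      stop("analyze-tracks: missing track file(s): ",
           paste(files[!file.exists(files)], collapse = ", "),
           call. = FALSE)
    inputs <- files
    geo <- tube_geometry()
    disp_all <- list(); res_all <- list()
    for (f in files) {
      tr <- register_track(smooth_track(read_track(f)))
      for (ps in segment_passes(tr, geo)) {
        disp_all[[length(disp_all) + 1]] <-
          detect_propulsive_displacements(ps)
        if (ps$complete)
          res_all[[length(res_all) + 1]] <- residence_times(ps, geo)
      }
    }
    disp <- do.call(rbind, disp_all)
    emit(disp, "displacements.csv")
    emit(distance_velocity_histogram(disp), "distance_velocity.csv")
    if (length(res_all)) {
      res <- do.call(rbind, res_all)
      emit(stats::aggregate(residence_s ~ unit, res, mean),
           "residence_times.csv")
    }
  } else {
    if (is.null(config$series) || !file.exists(config$series))
      stop("analyze-motility: missing series file: ", config$series,
           call. = FALSE)
    inputs <- config$series
    mode <- if (is.null(config$mode)) "length_cm" else config$mode
    hs <- read_haustral_series(config$series, mode = mode)
    ev <- detect_contraction_events(hs)
    emit(ev, "events.csv")
    lw <- link_waves(ev, hs)
    emit(lw$waves, "waves.csv")
    emit(data.frame(motility_index = in_vivo_motility_index(ev, hs),
                    timing_ratio = if (NROW(ev))
                      relaxation_contraction_ratio(ev) else NA_real_),
         "motility_summary.csv")
  }
  manifest <- list(workflow = workflow, seed = seed,
                   inputs = as.list(inputs),
                   outputs = lapply(outputs, function(p)
                     list(file = basename(p),
                          md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
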