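# Config-driven pipeline driver. A configuration (R list, or YAML/JSON
# file) names the stages to run with per-stage parameter blocks; stages
# execute in dependency order, write CSV/JSON outputs into the output
# directory, and a run record (config hash, seed, per-stage manifest) is
# written alongside. Reruns with identical config and seed reproduce
# identical outputs.

PIPELINE_STAGES <- c("synth_traj", "contacts", "pore", "shape", "fit_dsf",
                     "fit_itc", "fit_mm", "deer")

#' Validate a pipeline configuration
#'
#' Unknown top-level or stage keys are rejected by name. Stage defaults
#' equal the analysis defaults throughout the package (beta = 5 A^-1,
#' lambda = 1.5, native cutoff 4.5 A, lipid cutoff 3.5 A, ratio threshold
#' 1.115).
#'
#' @param config list, or path to a YAML/JSON config file.
#' @return The validated config list (with `stages` normalized).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  allowed_top <- c("stages", "outdir", "seed", PIPELINE_STAGES)
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages))
    config$stages <- intersect(PIPELINE_STAGES, names(config))
  bad <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad))
    stop_invalid("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$outdir)) stop_invalid("config must name an outdir")
  config$seed <- config$seed %||% 1L
  config
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (trajectory synthesis
#' before contact analysis), writes each stage's outputs under
#' `config$outdir`, and returns a run record with a config hash and a
#' per-file manifest (md5). Any stage error aborts the run.
#'
#' @param config list or YAML/JSON path; see [validate_config()]. Stage
#'   blocks hold the generator/analysis parameters of the corresponding
#'   functions, e.g. `synth_traj = list(n_frames = 50)`,
#'   `fit_mm = list(vmax = 197, km = 0.2)`.
#' @return List of class `run_record`: `timestamp`, `config_hash`, `seed`,
#'   `outputs` (named file manifest with md5 sums).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  put <- function(name, path) outputs[[name]] <<- path

  stages <- config$stages
  # dependency order
  stages <- intersect(PIPELINE_STAGES, stages)
  traj <- NULL

  for (stage in stages) {
    blk <- config[[stage]] %||% list()
    if (stage == "synth_traj") {
      pars <- do.call(toy_trajectory_params,
                      utils::modifyList(list(seed = seed), blk))
      traj <- generate_idr_membrane_trajectory(pars)
      f <- file.path(outdir, "trajectory.pdb")
      write_trajectory(traj, f); put("trajectory", f)
    } else if (stage == "contacts") {
      if (is.null(traj)) {
        if (is.null(blk$trajectory)) stop_invalid(
          "contacts stage needs a synth_traj stage or a trajectory path")
        traj <- read_trajectory(blk$trajectory)
      }
      spec <- do.call(contact_spec, blk$spec %||% list())
      ga <- select_atoms(traj, segment = "tail", resid = blk$group_a %||% "7-13")
      gb <- select_atoms(traj, segment = "partner")
      nc <- build_native_contacts(get_frame(traj, 1), ga, gb, spec)
      qs <- q_timeseries(traj, nc, spec)
      lc <- lipid_contacts(traj, blk$residues %||% "2-21", spec)
      zd <- z_distance_distribution(traj, blk$residues %||% "2-21")
      tl <- terminus_length(traj, blk$residues %||% "2-21")
      f1 <- file.path(outdir, "q_timeseries.csv"); write_curve_csv(qs, f1)
      f2 <- file.path(outdir, "lipid_contacts.csv")
      write_curve_csv(lc$series, f2)
      f3 <- file.path(outdir, "z_histogram.csv")
      write_curve_csv(zd$histogram, f3)
      f4 <- file.path(outdir, "terminus_length.csv"); write_curve_csv(tl, f4)
      put("q_timeseries", f1); put("lipid_contacts", f2)
      put("z_histogram", f3); put("terminus_length", f4)
    } else if (stage == "pore") {
      if (is.null(blk$structure)) stop_invalid("pore stage needs a structure path")
      s <- read_structure(blk$structure)
      prof <- pore_radius_profile(s,
        step = blk$step %||% 0.5, r_max = blk$r_max %||% 10,
        search_radius = blk$search_radius %||% 5)
      f <- file.path(outdir, "pore_profile.csv"); write_curve_csv(prof, f)
      put("pore_profile", f)
      mc <- min_constriction(prof)
      f2 <- file.path(outdir, "pore_constriction.json")
      jsonlite::write_json(mc, f2, auto_unbox = TRUE, digits = NA)
      put("pore_constriction", f2)
    } else if (stage == "shape") {
      imgs <- if (!is.null(blk$images)) lapply(blk$images, read_class_image)
              else {
                pars <- do.call(class_image_params,
                                utils::modifyList(list(seed = seed),
                                                  blk$generate %||% list()))
                list(generate_class_image(pars))
              }
      rows <- lapply(imgs, function(im) {
        d <- measure_diameters(im)
        call <- classify_shape(d$long_axis, d$short_axis,
                               threshold = blk$threshold %||% 1.115)
        data.frame(long_nm = call$long_axis, short_nm = call$short_axis,
                   ratio = call$ratio, label = call$label)
      })
      tab <- do.call(rbind, rows)
      f <- file.path(outdir, "shape_calls.csv"); write_curve_csv(tab, f)
      put("shape_calls", f)
    } else if (stage == "fit_dsf") {
      pars <- do.call(melt_curve_params,
                      utils::modifyList(list(seed = seed), blk))
      curve <- generate_melt_curve(pars)
      tm <- melting_temperature(curve)
      f <- file.path(outdir, "dsf_fit.json")
      jsonlite::write_json(list(tm = tm), f, auto_unbox = TRUE, digits = NA)
      put("dsf_fit", f)
    } else if (stage == "fit_itc") {
      pars <- do.call(thermogram_params,
                      utils::modifyList(list(seed = seed), blk))
      tg <- generate_itc_thermogram(pars)
      fit <- fit_one_site_itc(tg)
      f <- file.path(outdir, "itc_fit.json")
      jsonlite::write_json(list(kd = fit$kd, dh = fit$dh,
                                n_sites = fit$n_sites),
                           f, auto_unbox = TRUE, digits = NA)
      put("itc_fit", f)
    } else if (stage == "fit_mm") {
      pars <- do.call(uptake_params,
                      utils::modifyList(list(seed = seed), blk))
      kin <- generate_uptake_timecourses(pars)
      v <- vapply(kin$timecourses, function(tc) initial_velocity(tc)$slope,
                  numeric(1))
      fit <- fit_michaelis_menten(pars$substrate_concs, v)
      f <- file.path(outdir, "mm_fit.json")
      jsonlite::write_json(list(vmax = fit$vmax, km = fit$km),
                           f, auto_unbox = TRUE, digits = NA)
      put("mm_fit", f)
    } else if (stage == "deer") {
      dist <- gaussian_distribution(blk$center %||% 3.3, blk$sd %||% 0.15)
      pars <- deer_trace_params(dist,
        modulation_depth = blk$modulation_depth %||% 0.3,
        background_rate = blk$background_rate %||% 0.05,
        noise_sd = blk$noise_sd %||% 0, seed = seed)
      trace <- generate_deer_trace(pars)
      ff <- background_correct(trace)
      inv <- tikhonov_invert(ff)
      st <- distribution_stats(inv$distribution)
      f1 <- file.path(outdir, "deer_trace.csv"); write_curve_csv(trace, f1)
      f2 <- file.path(outdir, "deer_distribution.csv")
      write_curve_csv(inv$distribution, f2)
      f3 <- file.path(outdir, "deer_fit.json")
      jsonlite::write_json(list(alpha = inv$alpha, mode = st$mode,
                                mean = st$mean, width = st$width),
                           f3, auto_unbox = TRUE, digits = NA)
      put("deer_trace", f1); put("deer_distribution", f2); put("deer_fit", f3)
    }
  }

  cfg_for_hash <- config[setdiff(names(config), "outdir")]
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA), tf)
  record <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 config_hash = unname(tools::md5sum(tf)),
                 seed = seed,
                 outputs = lapply(outputs, function(p)
                   list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(record, file.path(outdir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  class(record) <- "run_record"
  record
}
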