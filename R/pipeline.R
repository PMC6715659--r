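# Config-driven entry points tying the stages into reproducible runs:
# simulate -> preprocess -> extract -> kinetics.  Each stage reads its
# inputs from the run directory written by the previous one, so stages
# can be re-run independently; every run_all writes a manifest with the
# config hash, seed and package version.

.config_template <- list(
  experiment = NA, seed = NA,
  paths = list(out = NA),
  geometry = list(pixels_per_side = NA, pixel_size_um = NA, n_z = NA,
                  z_step_um = NA, z_range_um = NA, n_timepoints = NA,
                  dt_min = NA),
  n_positions = NA,
  gel = list(cellulose_pct = NA, pectin_pct = NA, particle_density = NA,
             particle_size_um = NA, particle_shape = NA, binding_k_on = NA,
             label = NA),
  enzyme = list(state = NA, d_base_um2_s = NA, catalytic_factor = NA,
                cellulose_factor = NA, n_residues = NA),
  source = list(channel_width_um = NA, c0 = NA, replenished = NA,
                loading_length_um = NA),
  optics = list(gain_counts_per_conc = NA, ill_min = NA, bkg_level_counts = NA,
                read_noise_sd_counts = NA, shot_noise = NA,
                defocus_sd_um_per_um = NA, bit_depth = NA),
  simulate = list(grid_um = NA, dt_s = NA, method = NA, domain_y_um = NA,
                  n_dark = NA),
  preprocess = list(filter_size = NA, normalize_ill = NA, write_corrected = NA),
  sampler = list(type = NA, exclusion = NA, auto_threshold = NA,
                 max_overlap = NA, max_redraws = NA),
  kinetics = list(positions = NA, times = NA, threshold_fraction = NA))

#' Validate a run configuration
#'
#' Checks the nested structure against the known schema: unknown keys are
#' rejected (they are usually typos) and the master seed and output path
#' must be present.
#'
#' @param config nested named list (e.g. from [read_run_config()]).
#' @return the config, invisibly, or an error.
#' @export
validate_run_config <- function(config) {
  check <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown) > 0) {
      stop("unknown config key(s) under '", path, "': ",
           paste(unknown, collapse = ", "))
    }
    for (k in names(cfg)) {
      if (is.list(tpl[[k]]) && !is.null(names(tpl[[k]]))) {
        if (!is.list(cfg[[k]])) stop("config key '", path, k, "' must be a table")
        check(cfg[[k]], tpl[[k]], paste0(path, k, "/"))
      }
    }
  }
  if (!is.list(config)) stop("config must be a named list")
  check(config, .config_template, "")
  if (is.null(config$seed)) stop("config must set a master seed ('seed')")
  if (is.null(config$paths$out)) stop("config must set an output root ('paths/out')")
  invisible(config)
}

#' Read and validate a JSON run configuration
#' @param path JSON file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
  cfg
}

#' Default run configuration
#'
#' Full-scale stated world: 1024 px frames at 0.2804 um/px, 7 positions,
#' 12 x 5 min time points, 5 z-planes, shipped generator defaults.
#' `scenario` selects the shipped parameter sets: `"g00_active"`
#' (cellulose-free, active enzyme), `"g00_accumulation"` (same plus the
#' weak-binding accumulation mode), `"g15_active"` (1.5% cellulose,
#' active), `"inactive"` (cellulose-free, heat-inactivated enzyme).
#'
#' @param out output root directory.
#' @param seed master seed.
#' @param scenario shipped scenario name.
#' @param reduced use the desk-scale geometry (128 px at 2.2432 um/px,
#'   identical physical field widths and distances, coarser physics
#'   grid); intended for tests and examples.
#' @return validated config list.
#' @export
default_run_config <- function(out = tempfile("gelmob_run_"), seed = 1L,
                               scenario = c("g00_active", "g00_accumulation",
                                            "g15_active", "inactive"),
                               reduced = FALSE) {
  scenario <- match.arg(scenario)
  sc <- scenario_specs(scenario)
  geom <- if (reduced) {
    list(pixels_per_side = 128L, pixel_size_um = 2.2432, n_z = 5L,
         z_step_um = 1, z_range_um = 2, n_timepoints = 12L, dt_min = 5)
  } else {
    list(pixels_per_side = 1024L, pixel_size_um = 0.2804, n_z = 5L,
         z_step_um = 1, z_range_um = 2, n_timepoints = 12L, dt_min = 5)
  }
  cfg <- list(
    experiment = scenario, seed = as.integer(seed),
    paths = list(out = out),
    geometry = geom, n_positions = 7L,
    gel = unclass(sc$gel), enzyme = unclass(sc$enzyme),
    source = unclass(sc$source), optics = unclass(optics_spec()),
    simulate = list(grid_um = if (reduced) 8 else 4,
                    dt_s = if (reduced) 5 else 2,
                    method = "adi", domain_y_um = 300, n_dark = 10L),
    preprocess = list(filter_size = if (reduced) 27L else 105L,
                      normalize_ill = TRUE, write_corrected = FALSE),
    sampler = list(type = "random_line", exclusion = "none",
                   auto_threshold = 0.2, max_overlap = 0.05, max_redraws = 50L),
    kinetics = list(positions = c(0, 1, 3, 6), times = c(0, 15, 30, 45),
                    threshold_fraction = 0.05))
  validate_run_config(cfg)
  cfg
}

#' Shipped generator scenarios
#'
#' @param scenario scenario name (see [default_run_config()]).
#' @return list with `gel`, `enzyme`, `source` spec objects.
#' @export
scenario_specs <- function(scenario = c("g00_active", "g00_accumulation",
                                        "g15_active", "inactive")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    g00_active = list(gel = gel_spec(0), enzyme = enzyme_spec("active"),
                      source = source_spec()),
    g00_accumulation = list(gel = gel_spec(0, binding_k_on = 2e-3),
                            enzyme = enzyme_spec("active"),
                            source = source_spec()),
    g15_active = list(gel = gel_spec(1.5), enzyme = enzyme_spec("active"),
                      source = source_spec()),
    inactive = list(gel = gel_spec(0), enzyme = enzyme_spec("inactive"),
                    source = source_spec()))
}

.specs_from_config <- function(config) {
  list(gel = do.call(gel_spec, config$gel),
       enzyme = do.call(enzyme_spec, config$enzyme),
       source = do.call(source_spec, config$source),
       optics = do.call(optics_spec, config$optics),
       geometry = do.call(acquisition_geometry, config$geometry))
}

.run_dir <- function(config) file.path(config$paths$out, "run")

#' Stage 1: simulate and persist a synthetic acquisition
#' @param config validated run config.
#' @param overwrite passed to [write_run()].
#' @return the in-memory `gelmob_run`, invisibly.
#' @export
run_simulate <- function(config, overwrite = FALSE) {
  validate_run_config(config)
  sp <- .specs_from_config(config)
  run <- simulate_acquisition(gel = sp$gel, enzyme = sp$enzyme,
                              source = sp$source, optics = sp$optics,
                              geometry = sp$geometry,
                              n_positions = config$n_positions,
                              seed = config$seed,
                              grid_um = config$simulate$grid_um,
                              dt_s = config$simulate$dt_s,
                              method = config$simulate$method,
                              domain_y_um = config$simulate$domain_y_um,
                              n_dark = config$simulate$n_dark,
                              experiment = config$experiment)
  write_run(run, .run_dir(config), overwrite = overwrite)
  message("simulate: ", length(run$positions), " positions x ",
          length(run$times_min), " times x ", length(run$z_um), " z -> ",
          .run_dir(config))
  invisible(run)
}

#' Stage 2: estimate the shading model (and optionally write corrected
#' frames)
#' @param config validated run config.
#' @return the `shading_model`, invisibly.
#' @export
run_preprocess <- function(config) {
  validate_run_config(config)
  rd <- .run_dir(config)
  if (!dir.exists(rd)) stop("no simulated run under ", rd, "; run_simulate first")
  run <- load_run(rd)
  mid_z <- (run$geometry$n_z + 1) %/% 2
  model <- build_shading_model(dark_frames(run),
                               get_frame(run, 0L, 1L, mid_z),
                               filter_size = config$preprocess$filter_size,
                               normalize = config$preprocess$normalize_ill)
  sd_dir <- file.path(config$paths$out, "shading")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  write_tiff(model$bkg, file.path(sd_dir, "bkg.tif"), bits = 32L)
  write_tiff(model$ill, file.path(sd_dir, "ill.tif"), bits = 32L)
  jsonlite::write_json(model$provenance, file.path(sd_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(config$preprocess$write_corrected)) {
    cor_root <- file.path(config$paths$out, "corrected")
    for (p in run$positions) for (ti in seq_along(run$times_min)) {
      d <- file.path(cor_root, sprintf("pos%d", p),
                     sprintf("t%02.0fmin", run$times_min[ti]))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (zi in seq_along(run$z_um)) {
        corr <- shading_correct(get_frame(run, p, ti, zi), model)
        write_tiff(corr, file.path(d, sprintf("z%d.tif", zi)), bits = 32L)
      }
    }
  }
  message("preprocess: shading model written to ", sd_dir)
  invisible(model)
}

.load_shading <- function(config) {
  sd_dir <- file.path(config$paths$out, "shading")
  if (!file.exists(file.path(sd_dir, "ill.tif"))) {
    stop("no shading model under ", sd_dir, "; run_preprocess first")
  }
  prov <- jsonlite::read_json(file.path(sd_dir, "provenance.json"),
                              simplifyVector = TRUE)
  shading_model(read_tiff(file.path(sd_dir, "bkg.tif")),
                read_tiff(file.path(sd_dir, "ill.tif")),
                provenance = prov,
                check_unit_mean = isTRUE(prov$ill_normalized))
}

#' Stage 3: extract intensity records
#' @param config validated run config.
#' @return data.frame of intensity records, invisibly (also written to
#'   `records.csv`; random-line coordinates go to a JSON sidecar).
#' @export
run_extract <- function(config) {
  validate_run_config(config)
  rd <- .run_dir(config)
  if (!dir.exists(rd)) stop("no simulated run under ", rd, "; run_simulate first")
  run <- load_run(rd)
  model <- .load_shading(config)
  s <- config$sampler
  records <- extract_profiles(run, model, sampler = s$type,
                              seed = config$seed, exclusion = s$exclusion,
                              auto_threshold = s$auto_threshold,
                              max_overlap = s$max_overlap,
                              max_redraws = s$max_redraws)
  utils::write.csv(records, file.path(config$paths$out, "records.csv"),
                   row.names = FALSE)
  samples <- attr(records, "samples")
  if (s$type == "random_line") {
    jsonlite::write_json(lapply(samples, function(x) {
      list(pos_id = x$pos_id, seed = x$seed,
           overlap_fraction = x$overlap_fraction,
           pixel_coords = unname(x$pixel_coords))
    }), file.path(config$paths$out, "line_samples.json"), auto_unbox = TRUE)
  }
  message("extract: ", nrow(records), " records -> records.csv")
  invisible(records)
}

#' Stage 4: normalize, profile tables, figures and penetration summary
#' @param config validated run config.
#' @return list with `table` (kinetic table), `time_profiles`,
#'   `spatial_profiles` and `penetration` (per experiment, at the last
#'   configured time), invisibly; CSVs and PDF figures are written under
#'   the output root.
#' @export
run_kinetics <- function(config) {
  validate_run_config(config)
  rec_path <- file.path(config$paths$out, "records.csv")
  if (!file.exists(rec_path)) stop("no records.csv under ", config$paths$out,
                                   "; run_extract first")
  records <- utils::read.csv(rec_path)
  table <- normalize_kinetics(records)
  geometry <- do.call(acquisition_geometry, config$geometry)
  layout <- build_position_layout(geometry, config$n_positions)

  tp <- time_profiles(table, config$kinetics$positions)
  sp <- spatial_profiles(table, config$kinetics$times, layout = layout)
  out <- config$paths$out
  utils::write.csv(table, file.path(out, "kinetics.csv"), row.names = FALSE)
  utils::write.csv(tp, file.path(out, "time_profiles.csv"), row.names = FALSE)
  utils::write.csv(sp, file.path(out, "spatial_profiles.csv"), row.names = FALSE)
  grDevices::pdf(file.path(out, "time_profiles.pdf"), width = 7, height = 5)
  print(plot_time_profiles(tp))
  grDevices::dev.off()
  grDevices::pdf(file.path(out, "spatial_profiles.pdf"), width = 7, height = 5)
  print(plot_spatial_profiles(sp))
  grDevices::dev.off()

  t_last <- max(config$kinetics$times)
  pen <- do.call(rbind, lapply(split(sp[sp$time_min == t_last, ],
                                     sp$experiment[sp$time_min == t_last]),
    function(df) data.frame(experiment = df$experiment[1], gel = df$gel[1],
                            enzyme_state = df$enzyme_state[1],
                            time_min = t_last,
                            penetration_um = penetration_depth(
                              df, layout, config$kinetics$threshold_fraction))))
  rownames(pen) <- NULL
  utils::write.csv(pen, file.path(out, "penetration.csv"), row.names = FALSE)
  message("kinetics: tables and figures -> ", out)
  invisible(list(table = table, time_profiles = tp, spatial_profiles = sp,
                 penetration = pen))
}

#' Run the full chain on one configuration
#'
#' @param config validated run config.
#' @param overwrite passed to [run_simulate()].
#' @return the [run_kinetics()] result, invisibly; prints a penetration
#'   summary and writes `manifest.json` (config hash, seed, version).
#' @export
run_all <- function(config, overwrite = FALSE) {
  validate_run_config(config)
  run_simulate(config, overwrite = overwrite)
  run_preprocess(config)
  run_extract(config)
  res <- run_kinetics(config)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config_md5 = unname(tools::md5sum(tf)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("gelmob")))
  jsonlite::write_json(manifest, file.path(config$paths$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cat("penetration depth at", max(config$kinetics$times), "min:\n")
  print(res$penetration)
  invisible(res)
}
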