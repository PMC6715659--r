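# Desk-scale fixtures: same physical field width (287.1296 um) and ROI
# distances as the full 1024-px setup, with coarser pixels so the whole
# suite runs in minutes.

geom_reduced <- function(n_px = 128L, ...) {
  acquisition_geometry(pixels_per_side = n_px,
                       pixel_size_um = 287.1296 / n_px, ...)
}

geom_full <- function(...) acquisition_geometry(...)

loading_lambda <- 287.1296 / log(2)

# one full reduced-scale acquisition + extraction; memoised per scenario
# so several tests can share it
.run_cache <- new.env(parent = emptyenv())
reduced_pipeline <- function(scenario, seed = 7, n_px = 128L, filter_size = 27L) {
  key <- paste(scenario, seed, n_px, sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  sc <- scenario_specs(scenario)
  geom <- geom_reduced(n_px)
  run <- simulate_acquisition(gel = sc$gel, enzyme = sc$enzyme,
                              source = sc$source, geometry = geom,
                              seed = seed, grid_um = 8, dt_s = 5,
                              experiment = scenario)
  mid_z <- (geom$n_z + 1) %/% 2
  model <- build_shading_model(run$dark, get_frame(run, 0L, 1L, mid_z),
                               filter_size = filter_size)
  records <- suppressMessages(extract_profiles(run, model, seed = seed))
  out <- list(geom = geom, run = run, model = model, records = records,
              table = normalize_kinetics(records),
              layout = build_position_layout(geom, 7))
  .run_cache[[key]] <- out
  out
}

# smooth multiplicative vignette with a known analytic form (oracle for
# illumination recovery)
known_vignette <- function(n_px, vmin = 0.7) {
  ctr <- (n_px + 1) / 2
  ij <- expand.grid(r = seq_len(n_px), c = seq_len(n_px))
  d2 <- (ij$r - ctr)^2 + (ij$c - ctr)^2
  dmax2 <- 2 * (n_px / 2)^2
  matrix(vmin + (1 - vmin) * (1 - d2 / dmax2), nrow = n_px)
}
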