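test_that("spec constructors enforce their invariants", {
  expect_error(gel_spec(0, particle_density = 10), "implies")
  expect_equal(gel_spec(0.5)$label, "g05")
  expect_equal(gel_spec(1.5)$label, "g15")
  expect_equal(gel_spec(1.5)$particle_density, 750)
  expect_error(enzyme_spec(d_base_um2_s = 0), "d_base")
  expect_error(source_spec(c0 = 0), "c0")
  expect_error(optics_spec(ill_min = 0), "ill_min")
})

test_that("effective diffusivity follows the state and cellulose scaling", {
  enz <- enzyme_spec("active")
  expect_equal(effective_diffusivity(enzyme_spec("inactive"), gel_spec(1.5)), 5)
  expect_equal(effective_diffusivity(enz, gel_spec(0)), 50)
  expect_equal(effective_diffusivity(enz, gel_spec(1.5)), 600)
})

test_that("particle sampling is deterministic, Poisson-calibrated and empty for g00", {
  expect_true(all(!sample_particles(gel_spec(0), c(1000, 1000), seed = 1)))
  m1 <- sample_particles(gel_spec(1.5), c(1000, 1000), seed = 9)
  m2 <- sample_particles(gel_spec(1.5), c(1000, 1000), seed = 9)
  expect_identical(m1, m2)
  expect_error(sample_particles(gel_spec(1.5), c(3, 3), seed = 1), "smaller")
  # empirical mean particle count over 200 seeds within 3 sigma of the
  # configured density (750 per mm^2 on a 1 mm^2 domain)
  counts <- vapply(1:200, function(s) {
    nrow(attr(sample_particles(gel_spec(1.5), c(1000, 1000), seed = s,
                               grid_um = 50), "particles"))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 750), 3 * sqrt(750 / 200))
})

test_that("zero diffusivity freezes the field; solver conserves mass", {
  geom <- geom_reduced(64L)
  lay <- build_position_layout(geom, 2)
  frozen <- simulate_concentration(gel_spec(0),
                                   enzyme_spec("inactive", d_base_um2_s = 1e-12),
                                   source_spec(), geom, lay, grid_um = 16,
                                   seed = 1, dt_s = 30, x_max_um = 800)
  expect_equal(frozen$conc[[12]], frozen$conc[[1]], tolerance = 1e-6)
  # no-flux boundaries, unreplenished source: total mass conserved
  sim <- simulate_concentration(gel_spec(1.5), enzyme_spec("active"),
                                source_spec(), geom, lay, grid_um = 16,
                                seed = 2, dt_s = 30, x_max_um = 800)
  m <- total_mass(sim)
  expect_lt(max(abs(m - m[1]) / m[1]), 1e-3)
  # with trapping on, mobile + bound mass is still conserved
  simb <- simulate_concentration(gel_spec(0, binding_k_on = 2e-3),
                                 enzyme_spec("active"), source_spec(), geom,
                                 lay, grid_um = 16, seed = 2, dt_s = 30,
                                 x_max_um = 800)
  mb <- total_mass(simb)
  expect_lt(max(abs(mb - mb[1]) / mb[1]), 1e-3)
  expect_gt(sum(simb$bound[[12]]), 0)
})

test_that("explicit scheme enforces its stability bound and matches ADI", {
  geom <- geom_reduced(64L)
  lay <- build_position_layout(geom, 2)
  expect_error(simulate_concentration(gel_spec(0), enzyme_spec("active"),
                                      source_spec(), geom, lay, grid_um = 16,
                                      seed = 1, dt_s = 30, method = "explicit",
                                      x_max_um = 800),
               "dt <= h\\^2/\\(4 Dmax\\)")
  a <- simulate_concentration(gel_spec(0), enzyme_spec("active"), source_spec(),
                              geom, lay, grid_um = 16, seed = 1, dt_s = 1,
                              method = "explicit", x_max_um = 800)
  b <- simulate_concentration(gel_spec(0), enzyme_spec("active"), source_spec(),
                              geom, lay, grid_um = 16, seed = 1, dt_s = 1,
                              method = "adi", x_max_um = 800)
  expect_equal(a$conc[[6]], b$conc[[6]], tolerance = 1e-3)
})

test_that("penetration grows with time and with effective diffusivity", {
  geom <- geom_reduced(64L)
  lay <- build_position_layout(geom, 4)
  depth <- function(sim, ti) {
    prof <- colMeans(sim$conc[[ti]])
    gel <- sim$x_um > 0
    ref <- prof[gel][1]
    xs <- sim$x_um[gel]
    hit <- xs[prof[gel] > 0.05 * ref]
    if (length(hit) == 0) 0 else max(hit)
  }
  s_slow <- simulate_concentration(gel_spec(0), enzyme_spec("inactive"),
                                   source_spec(), geom, lay, grid_um = 16,
                                   seed = 1, dt_s = 15)
  s_fast <- simulate_concentration(gel_spec(0), enzyme_spec("active"),
                                   source_spec(), geom, lay, grid_um = 16,
                                   seed = 1, dt_s = 15)
  d_slow <- vapply(seq_along(s_slow$times_min), function(ti) depth(s_slow, ti),
                   numeric(1))
  d_fast <- vapply(seq_along(s_fast$times_min), function(ti) depth(s_fast, ti),
                   numeric(1))
  expect_true(all(diff(d_slow) >= 0))
  expect_true(all(diff(d_fast) >= 0))
  expect_gt(d_fast[12], d_slow[12])
})

test_that("obstacle-free simulator matches the erfc solution within 1%", {
  # 1-D reduction: uniform in y; replenished source held at c0, no smear.
  # The held cells impose C = c0 at their centres, so the analytic
  # boundary sits half a cell behind the channel/gel interface.
  geom <- geom_reduced(128L, n_timepoints = 7L)   # to 30 min
  lay <- build_position_layout(geom, 2)
  sim <- simulate_concentration(gel_spec(0), enzyme_spec("active"),
                                source_spec(replenished = TRUE,
                                            loading_length_um = 0),
                                geom, lay, grid_um = 4, seed = 1, dt_s = 2,
                                x_max_um = 1500)
  h <- sim$grid_um
  keep <- sim$x_um > 0 & sim$x_um <= 1000   # away from the far boundary
  for (ti in c(4, 7)) {
    t_s <- sim$times_min[ti] * 60
    num <- sim$conc[[ti]][1, keep]
    ana <- analytic_diffusion_profile(50, t_s, sim$x_um[keep] + h / 2)
    expect_lt(sqrt(sum((num - ana)^2) / sum(ana^2)), 0.01)
    # y-uniformity of the 1-D reduction
    expect_lt(max(apply(sim$conc[[ti]][, keep], 2, stats::sd)), 1e-9)
  }
})

test_that("rendering obeys its limiting cases", {
  geom <- geom_reduced(64L)
  lay <- build_position_layout(geom, 2)
  optics_quiet <- optics_spec(shot_noise = FALSE, read_noise_sd_counts = 0)
  # zero concentration -> pure background
  sim0 <- simulate_concentration(gel_spec(0),
                                 enzyme_spec("inactive", d_base_um2_s = 1e-9),
                                 source_spec(c0 = 1e-12, loading_length_um = 0),
                                 geom, lay, grid_um = 16, seed = 1, dt_s = 30,
                                 x_max_um = 800)
  st <- render_zstack(sim0, 1, optics_quiet, geom, 1, lay, seed = 1)
  expect_true(all(st[[1]] == optics_quiet$bkg_level_counts))
  # uniform concentration, flat ILL, no particles -> gain * c + bkg
  simu <- sim0
  simu$conc[[1]][] <- 0.5
  stu <- render_zstack(simu, 1, optics_quiet, geom, 1, lay, seed = 1)
  expect_true(all(stu[[3]] ==
                    round(0.5 * optics_quiet$gain_counts_per_conc +
                            optics_quiet$bkg_level_counts)))
  # frames are 16-bit integers in range
  opt <- optics_spec()
  stn <- render_zstack(simu, 1, opt, geom, 1, lay, seed = 1,
                       ill = make_illumination_field(64, opt, seed = 2))
  for (fr in stn) {
    expect_true(is.integer(fr))
    expect_true(all(fr >= 0 & fr <= 65535))
  }
  expect_error(render_zstack(sim0, 1, opt, geom, 9, lay, seed = 1),
               "not present")
})

test_that("particles render dark and defocus blurs them", {
  geom <- geom_reduced(64L)
  lay <- build_position_layout(geom, 2)
  optics_quiet <- optics_spec(shot_noise = FALSE, read_noise_sd_counts = 0,
                              defocus_sd_um_per_um = 2)
  sim <- simulate_concentration(gel_spec(1.5), enzyme_spec("active"),
                                source_spec(), geom, lay, grid_um = 8,
                                seed = 5, dt_s = 15, x_max_um = 800)
  st <- render_zstack(sim, 3, optics_quiet, geom, 0, lay, seed = 1)
  w <- field_width_um(geom)
  y0 <- (max(sim$y_um) + sim$grid_um / 2 - w) / 2
  pmask <- rasterize_particles(sim$particles, x0_um = 0, y0_um = y0,
                               nx = 64, ny = 64, spacing_um = w / 64)
  expect_gt(sum(pmask), 0)
  mid <- st[[3]]   # z = 0: no blur, particles at exactly bkg
  expect_true(all(mid[pmask] == optics_quiet$bkg_level_counts))
  # defocused plane: particle interiors brightened by blurred surround
  edge <- st[[1]]  # z = -2 um
  expect_gt(mean(edge[pmask]), mean(mid[pmask]))
})

test_that("whole acquisitions are reproducible and complete", {
  geom <- geom_reduced(32L)
  r1 <- simulate_acquisition(geometry = geom, seed = 3, grid_um = 16,
                             dt_s = 30, n_dark = 5L)
  r2 <- simulate_acquisition(geometry = geom, seed = 3, grid_um = 16,
                             dt_s = 30, n_dark = 5L)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$dark, r2$dark)
  r3 <- simulate_acquisition(geometry = geom, seed = 4, grid_um = 16,
                             dt_s = 30, n_dark = 5L)
  expect_false(identical(r1$frames, r3$frames))
  # 7 positions x 12 times x 5 z
  expect_length(r1$frames, 7)
  expect_length(r1$frames[["0"]], 12)
  expect_length(r1$frames[["0"]][[1]], 5)
  expect_length(r1$dark, 5)
})

test_that("runs persist to disk and reload byte-identically", {
  geom <- geom_reduced(32L)
  run <- simulate_acquisition(geometry = geom, seed = 6, grid_um = 16,
                              dt_s = 30, n_dark = 5L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_run(run, d1, overwrite = TRUE)
  write_run(run, d2, overwrite = TRUE)
  files <- list.files(d1, recursive = TRUE)
  expect_equal(length(grep("^frames/", files)), 7 * 12 * 5)
  expect_true(length(grep("^dark/", files)) >= 5)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
  expect_error(write_run(run, d1), "not empty")

  back <- load_run(d1)
  expect_identical(get_frame(back, 0L, 1L, 3L), get_frame(run, 0L, 1L, 3L))
  expect_length(dark_frames(back), 5)
  expect_equal(back$times_min, run$times_min)
})
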