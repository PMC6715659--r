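# Synthetic acquisition generator.
#
# A stated world for testing the analysis chain: a pectin gel strip with
# non-fluorescent cellulose particles, an enzyme reservoir channel along
# one edge (finite, draining, with a convective loading smear into the
# gel), 2-D diffusion with obstacles, and an optics/camera model
# (vignetting, defocus blur per z-plane, Poisson shot noise, Gaussian
# read noise, 16-bit quantization).

#' Gel specification
#'
#' @param cellulose_pct cellulose content, w/w % (0, 0.5, 1.0 or 1.5 in
#'   the reference gels; any non-negative value accepted).
#' @param pectin_pct pectin content, fixed at 1.5% in the reference gels.
#' @param particle_density non-fluorescent particles per mm^2; default
#'   scales with cellulose content (500 per mm^2 per % cellulose).
#' @param particle_size_um (min, max) particle diameter in um.
#' @param particle_shape `"ellipse"` or `"blob"` (union of overlapping
#'   ellipses).
#' @param binding_k_on first-order trapping rate (1/s) of the optional
#'   accumulation mode (weak binding into an immobile pool); 0 = off,
#'   the default.
#' @param label gel label; default `g00`/`g05`/`g10`/`g15` style.
#' @return object of class `gel_spec`.
#' @export
gel_spec <- function(cellulose_pct = 0, pectin_pct = 1.5,
                     particle_density = 500 * cellulose_pct,
                     particle_size_um = c(5, 30),
                     particle_shape = c("ellipse", "blob"),
                     binding_k_on = 0,
                     label = sprintf("g%02.0f", 10 * cellulose_pct)) {
  particle_shape <- match.arg(particle_shape)
  stopifnot(cellulose_pct >= 0, pectin_pct > 0, particle_density >= 0,
            length(particle_size_um) == 2, all(particle_size_um > 0),
            particle_size_um[1] <= particle_size_um[2], binding_k_on >= 0)
  if (cellulose_pct == 0 && particle_density != 0) {
    stop("cellulose_pct = 0 implies particle_density = 0")
  }
  structure(list(cellulose_pct = cellulose_pct, pectin_pct = pectin_pct,
                 particle_density = particle_density,
                 particle_size_um = particle_size_um,
                 particle_shape = particle_shape,
                 binding_k_on = binding_k_on, label = label),
            class = "gel_spec")
}

#' Enzyme specification
#'
#' Diffusivities are generator parameters, not measurements: the
#' heat-inactivated enzyme moves passively at `d_base_um2_s`; catalysis
#' multiplies mobility by `catalytic_factor`, and cellulose further
#' scales the active enzyme's effective diffusivity by
#' `(1 + cellulose_factor * cellulose_pct)` (600 um^2/s at 1.5% cellulose
#' with the defaults).
#'
#' @param state `"active"` or `"inactive"`.
#' @param d_base_um2_s base (passive) diffusivity, um^2/s.
#' @param catalytic_factor mobility multiplier when active (>= 1).
#' @param cellulose_factor per-%-cellulose multiplier when active.
#' @param n_residues residue count (314 for the reference enzyme).
#' @return object of class `enzyme_spec`.
#' @export
enzyme_spec <- function(state = c("active", "inactive"), d_base_um2_s = 5,
                        catalytic_factor = 10, cellulose_factor = 22 / 3,
                        n_residues = 314L) {
  state <- match.arg(state)
  stopifnot(d_base_um2_s > 0, catalytic_factor >= 1, cellulose_factor >= 0,
            n_residues >= 1)
  structure(list(state = state, d_base_um2_s = d_base_um2_s,
                 catalytic_factor = catalytic_factor,
                 cellulose_factor = cellulose_factor,
                 n_residues = as.integer(n_residues)),
            class = "enzyme_spec")
}

#' Effective diffusivity of an enzyme in a gel
#'
#' @param enzyme an [enzyme_spec()].
#' @param gel a [gel_spec()].
#' @return effective diffusivity in um^2/s.
#' @export
effective_diffusivity <- function(enzyme, gel) {
  stopifnot(inherits(enzyme, "enzyme_spec"), inherits(gel, "gel_spec"))
  if (enzyme$state == "inactive") return(enzyme$d_base_um2_s)
  enzyme$d_base_um2_s * enzyme$catalytic_factor *
    (1 + enzyme$cellulose_factor * gel$cellulose_pct)
}

#' Enzyme source (deposit channel) specification
#'
#' The channel is a finite reservoir column at `x < 0`, initially at
#' concentration `c0`, that drains into the gel (it is empty at the end
#' of an acquisition unless `replenished`).  `loading_length_um` models
#' the convective intrusion that occurs while the channel is filled: the
#' gel starts with `C(x, 0) = c0 * exp(-x / lambda)`.  The default
#' `lambda = field_width / ln 2` makes the T0 field-average ratio
#' Pos1/Pos0 exactly 1/2, the behaviour reported for the immobile
#' (inactive) enzyme.
#'
#' @param channel_width_um reservoir width in um.
#' @param c0 initial reservoir concentration (arbitrary units, > 0).
#' @param replenished hold the channel at `c0` (default FALSE: it
#'   empties).
#' @param loading_length_um intrusion decay length in um (0 disables).
#' @return object of class `source_spec`.
#' @export
source_spec <- function(channel_width_um = 500, c0 = 1, replenished = FALSE,
                        loading_length_um = 287.1296 / log(2)) {
  stopifnot(channel_width_um > 0, c0 > 0, loading_length_um >= 0)
  structure(list(channel_width_um = channel_width_um, c0 = c0,
                 replenished = isTRUE(replenished),
                 loading_length_um = loading_length_um),
            class = "source_spec")
}

#' Optics and camera specification
#'
#' @param gain_counts_per_conc counts per concentration unit.  The
#'   default (1080) puts the corrected Pos0 mean at the first time point
#'   near 700 counts for `c0 = 1` (the reference range is 600-800).
#' @param ill_min vignette value at the farthest corner (peak is 1 at a
#'   randomized off-centre point).
#' @param bkg_level_counts additive dark level (counts).
#' @param read_noise_sd_counts Gaussian read noise sd (counts).
#' @param shot_noise apply Poisson noise to the expected signal.
#' @param defocus_sd_um_per_um Gaussian blur growth per um of |z|.
#' @param bit_depth sensor bit depth (16: values clipped to 0..65535).
#' @return object of class `optics_spec`.
#' @export
optics_spec <- function(gain_counts_per_conc = 1080, ill_min = 0.7,
                        bkg_level_counts = 100, read_noise_sd_counts = 8,
                        shot_noise = TRUE, defocus_sd_um_per_um = 0.5,
                        bit_depth = 16L) {
  stopifnot(gain_counts_per_conc > 0, ill_min > 0, ill_min <= 1,
            bkg_level_counts >= 0, read_noise_sd_counts >= 0,
            defocus_sd_um_per_um >= 0, bit_depth %in% c(8L, 12L, 16L))
  structure(list(gain_counts_per_conc = gain_counts_per_conc, ill_min = ill_min,
                 bkg_level_counts = bkg_level_counts,
                 read_noise_sd_counts = read_noise_sd_counts,
                 shot_noise = isTRUE(shot_noise),
                 defocus_sd_um_per_um = defocus_sd_um_per_um,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_spec")
}

#' True illumination (vignette) field
#'
#' Smooth 2-D Gaussian vignette: value 1 at a randomized off-centre peak,
#' `ill_min` at the farthest corner.  Built once per experiment and
#' shared by all frames.
#'
#' @param n_px frame side length in pixels.
#' @param optics an [optics_spec()].
#' @param seed integer seed for the peak position.
#' @return `n_px x n_px` matrix in `(0, 1]`.
#' @export
make_illumination_field <- function(n_px, optics, seed = 1L) {
  stopifnot(inherits(optics, "optics_spec"))
  ctr <- .with_seed(seed, stats::runif(2, 0.4, 0.6)) * n_px
  ij <- expand.grid(row = seq_len(n_px), col = seq_len(n_px))
  d2 <- (ij$row - ctr[1])^2 + (ij$col - ctr[2])^2
  # farthest corner pinned to ill_min
  corners <- expand.grid(r = c(1, n_px), c = c(1, n_px))
  dmax2 <- max((corners$r - ctr[1])^2 + (corners$c - ctr[2])^2)
  sigma2 <- dmax2 / (2 * log(1 / optics$ill_min))
  matrix(exp(-d2 / (2 * sigma2)), nrow = n_px)
}

# ---------------------------------------------------------------------------
# Particles

#' Sample non-fluorescent cellulose particles
#'
#' Particle count is Poisson with mean `particle_density x area`;
#' positions are uniform over the domain, shapes are random ellipses (or
#' blobs: unions of overlapping ellipses) with characteristic diameter
#' uniform in `particle_size_um`.  Deterministic under a fixed seed.
#'
#' @param gel a [gel_spec()].
#' @param domain_um (width, height) of the gel domain in um (x measured
#'   from the deposit edge; particles never enter the channel at x < 0).
#' @param seed integer seed.
#' @param grid_um raster spacing of the returned mask in um.
#' @return logical matrix (rows = y, cols = x), TRUE inside particles,
#'   with the parametric particle table attached as attribute
#'   `"particles"` (columns `x_um, y_um, a_um, b_um, angle`).
#' @export
sample_particles <- function(gel, domain_um, seed, grid_um = 4) {
  stopifnot(inherits(gel, "gel_spec"), length(domain_um) == 2,
            all(domain_um > 0), grid_um > 0)
  if (min(domain_um) < gel$particle_size_um[1]) {
    stop("domain (", paste(domain_um, collapse = " x "),
         " um) is smaller than one particle")
  }
  area_mm2 <- prod(domain_um) / 1e6
  parts <- .with_seed(seed, {
    n <- stats::rpois(1, gel$particle_density * area_mm2)
    if (n == 0) {
      data.frame(x_um = numeric(0), y_um = numeric(0), a_um = numeric(0),
                 b_um = numeric(0), angle = numeric(0))
    } else {
      diam <- stats::runif(n, gel$particle_size_um[1], gel$particle_size_um[2])
      base <- data.frame(x_um = stats::runif(n, 0, domain_um[1]),
                         y_um = stats::runif(n, 0, domain_um[2]),
                         a_um = diam / 2,
                         b_um = diam / 2 * stats::runif(n, 0.4, 1),
                         angle = stats::runif(n, 0, pi))
      if (gel$particle_shape == "blob") {
        # each blob = parent ellipse plus two offset lobes
        lobes <- lapply(1:2, function(k) {
          off <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2) * diam / 2
          data.frame(x_um = base$x_um + off[, 1], y_um = base$y_um + off[, 2],
                     a_um = base$a_um * stats::runif(n, 0.4, 0.8),
                     b_um = base$b_um * stats::runif(n, 0.4, 0.8),
                     angle = stats::runif(n, 0, pi))
        })
        base <- rbind(base, lobes[[1]], lobes[[2]])
      }
      base
    }
  })
  mask <- rasterize_particles(parts, x0_um = 0, y0_um = 0,
                              nx = max(1L, round(domain_um[1] / grid_um)),
                              ny = max(1L, round(domain_um[2] / grid_um)),
                              spacing_um = grid_um)
  attr(mask, "particles") <- parts
  mask
}

#' Rasterize a parametric particle table on an arbitrary grid
#'
#' @param particles data.frame as produced by [sample_particles()].
#' @param x0_um,y0_um physical coordinates of the grid origin (the first
#'   cell spans `[x0, x0 + spacing)`).
#' @param nx,ny grid size (cols, rows).
#' @param spacing_um cell size in um.
#' @return logical `ny x nx` matrix, TRUE inside a particle.
#' @export
rasterize_particles <- function(particles, x0_um, y0_um, nx, ny, spacing_um) {
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  if (nrow(particles) == 0) return(mask)
  xs <- x0_um + (seq_len(nx) - 0.5) * spacing_um
  ys <- y0_um + (seq_len(ny) - 0.5) * spacing_um
  for (i in seq_len(nrow(particles))) {
    p <- particles[i, ]
    jr <- which(abs(xs - p$x_um) <= p$a_um)
    ir <- which(abs(ys - p$y_um) <= p$a_um)
    if (length(jr) == 0 || length(ir) == 0) next
    dx <- outer(rep(1, length(ir)), xs[jr] - p$x_um)
    dy <- outer(ys[ir] - p$y_um, rep(1, length(jr)))
    u <- dx * cos(p$angle) + dy * sin(p$angle)
    v <- -dx * sin(p$angle) + dy * cos(p$angle)
    inside <- (u / p$a_um)^2 + (v / p$b_um)^2 <= 1
    mask[ir, jr] <- mask[ir, jr] | inside
  }
  mask
}

# ---------------------------------------------------------------------------
# Physics

#' Simulate enzyme concentration fields over the acquisition
#'
#' 2-D diffusion of a finite reservoir into a gel strip with
#' non-fluorescent obstacle particles (diffusivity zero inside: the
#' enzyme is excluded from them), no-flux outer boundaries, optional
#' replenished source, optional weak-binding accumulation
#' (`gel$binding_k_on`).  Solved on a square grid with the
#' Peaceman-Rachford ADI scheme (unconditionally stable, conservative
#' finite-volume fluxes) or an explicit scheme whose stability bound
#' `dt <= h^2 / (4 Dmax)` is enforced.
#'
#' @param gel a [gel_spec()].
#' @param enzyme an [enzyme_spec()].
#' @param source a [source_spec()].
#' @param geometry an [acquisition_geometry()].
#' @param layout a [build_position_layout()].
#' @param grid_um grid spacing h in um (>= pixel size).
#' @param seed seed for the particle sampling.
#' @param dt_s solver time step in seconds.
#' @param method `"adi"` or `"explicit"`.
#' @param domain_y_um strip height in um (must exceed the field width).
#' @param x_max_um gel extent in um; default covers all layout fields.
#' @return object of class `gelmob_sim`: cell-centre coordinates `x_um`
#'   (signed; negative = channel) and `y_um`, `times_min`, lists `conc`
#'   (mobile) and `bound` (immobile) of matrices (rows = y, cols = x),
#'   `particle_mask`, `particles`, `d_eff_um2_s` and the specs.
#' @export
simulate_concentration <- function(gel, enzyme, source, geometry, layout,
                                   grid_um = 4, seed = 1L, dt_s = 2,
                                   method = c("adi", "explicit"),
                                   domain_y_um = 300, x_max_um = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(gel, "gel_spec"), inherits(enzyme, "enzyme_spec"),
            inherits(source, "source_spec"), inherits(geometry, "acq_geometry"),
            inherits(layout, "position_layout"))
  if (grid_um < geometry$pixel_size_um) {
    stop("grid_um must be at least the pixel size")
  }
  if (domain_y_um < field_width_um(geometry)) {
    stop("domain_y_um must be at least one field width")
  }
  if (is.null(x_max_um)) x_max_um <- max(layout$end_um) + 50
  h <- grid_um
  d_eff <- effective_diffusivity(enzyme, gel)
  if (method == "explicit" && dt_s > h^2 / (4 * d_eff)) {
    stop(sprintf(paste0("unstable explicit configuration: dt = %g s violates ",
                        "dt <= h^2/(4 Dmax) = %g s"), dt_s, h^2 / (4 * d_eff)))
  }

  n_ch <- round(source$channel_width_um / h)
  nx_gel <- round(x_max_um / h)
  nx <- n_ch + nx_gel
  ny <- round(domain_y_um / h)
  x_um <- (seq_len(nx) - 0.5) * h - n_ch * h   # signed; < 0 inside channel
  y_um <- (seq_len(ny) - 0.5) * h

  gel_mask <- sample_particles(gel, c(nx_gel * h, ny * h), seed, grid_um = h)
  particle_mask <- matrix(FALSE, nrow = ny, ncol = nx)
  particle_mask[, n_ch + seq_len(nx_gel)] <- gel_mask

  D <- matrix(d_eff, nrow = ny, ncol = nx)
  D[particle_mask] <- 0

  src_mask <- matrix(rep(x_um < 0, each = ny), nrow = ny)
  C0 <- matrix(0, nrow = ny, ncol = nx)
  C0[src_mask] <- source$c0
  if (source$loading_length_um > 0) {
    smear <- source$c0 * exp(-pmax(x_um, 0) / source$loading_length_um)
    C0 <- C0 + matrix(rep(ifelse(x_um >= 0, smear, 0), each = ny), nrow = ny)
  }
  C0[particle_mask] <- 0

  times_min <- acquisition_times_min(geometry)
  steps_per_interval <- max(1L, round(geometry$dt_min * 60 / dt_s))
  dt_used <- geometry$dt_min * 60 / steps_per_interval

  conc <- vector("list", length(times_min))
  bound <- vector("list", length(times_min))
  conc[[1]] <- C0
  bound[[1]] <- matrix(0, nrow = ny, ncol = nx)
  state <- list(C = C0, B = bound[[1]])
  for (ti in seq_along(times_min)[-1]) {
    state <- .cpp_diffuse(state$C, D, h, dt_used, steps_per_interval,
                          src_mask, source$c0, source$replenished,
                          gel$binding_k_on, state$B, method)
    conc[[ti]] <- state$C
    bound[[ti]] <- state$B
  }
  structure(list(x_um = x_um, y_um = y_um, grid_um = h, times_min = times_min,
                 conc = conc, bound = bound, particle_mask = particle_mask,
                 particles = attr(gel_mask, "particles"),
                 d_eff_um2_s = d_eff, gel = gel, enzyme = enzyme,
                 source = source, seed = seed, dt_s = dt_used, method = method),
            class = "gelmob_sim")
}

#' Total mass (mobile + bound) of a simulation at each output time
#' @param sim a [simulate_concentration()] result.
#' @return numeric vector (arbitrary units, cell sums).
#' @export
total_mass <- function(sim) {
  stopifnot(inherits(sim, "gelmob_sim"))
  vapply(seq_along(sim$times_min),
         function(ti) sum(sim$conc[[ti]]) + sum(sim$bound[[ti]]), numeric(1))
}

# tensor-grid bilinear interpolation of Z (rows = y over yg, cols = x
# over xg) at query centre vectors xq, yq; queries clamped to the grid
.bilinear <- function(xg, yg, Z, xq, yq) {
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  xq <- clamp(xq, xg[1], xg[length(xg)])
  yq <- clamp(yq, yg[1], yg[length(yg)])
  j0 <- clamp(findInterval(xq, xg), 1L, length(xg) - 1L)
  i0 <- clamp(findInterval(yq, yg), 1L, length(yg) - 1L)
  wx <- (xq - xg[j0]) / (xg[j0 + 1L] - xg[j0])
  wy <- (yq - yg[i0]) / (yg[i0 + 1L] - yg[i0])
  WX <- matrix(wx, nrow = length(yq), ncol = length(xq), byrow = TRUE)
  WY <- matrix(wy, nrow = length(yq), ncol = length(xq))
  i1 <- i0 + 1L; j1 <- j0 + 1L
  (1 - WY) * ((1 - WX) * Z[i0, j0, drop = FALSE] + WX * Z[i0, j1, drop = FALSE]) +
    WY * ((1 - WX) * Z[i1, j0, drop = FALSE] + WX * Z[i1, j1, drop = FALSE])
}

#' Render the z-stack of one position at one time point
#'
#' Expected signal is `gain x concentration x ILL + BKG`, zero inside
#' particles before the background is added; each plane is blurred with a
#' Gaussian of `sigma = defocus_sd_um_per_um x |z|`; Poisson shot noise
#' and Gaussian read noise are applied when enabled; values are clipped
#' to the sensor range and quantized.
#'
#' @param sim a [simulate_concentration()] result.
#' @param time_index index into `sim$times_min`.
#' @param optics an [optics_spec()].
#' @param geometry an [acquisition_geometry()].
#' @param pos_id position id present in `layout`.
#' @param layout a [build_position_layout()].
#' @param seed seed for this stack's noise draws.
#' @param ill illumination field (`n_px x n_px`, from
#'   [make_illumination_field()]); NULL = flat 1.
#' @param z_planes_um z offsets in um; default from `geometry`.
#' @return list of `n_px x n_px` integer matrices, one per z-plane.
#' @export
render_zstack <- function(sim, time_index, optics, geometry, pos_id, layout,
                          seed = 1L, ill = NULL,
                          z_planes_um = z_offsets_um(geometry)) {
  stopifnot(inherits(sim, "gelmob_sim"), inherits(optics, "optics_spec"),
            inherits(geometry, "acq_geometry"), inherits(layout, "position_layout"))
  n_px <- geometry$pixels_per_side
  px <- geometry$pixel_size_um
  row <- match(pos_id, layout$pos_id)
  if (is.na(row)) stop("pos_id ", pos_id, " not present in layout")
  w <- field_width_um(geometry)
  if (layout$end_um[row] > max(sim$x_um) + sim$grid_um / 2) {
    stop("simulation domain does not cover position ", pos_id)
  }
  if (is.null(ill)) ill <- matrix(1, n_px, n_px)

  xq <- layout$start_um[row] + (seq_len(n_px) - 0.5) * px
  y0 <- (max(sim$y_um) + sim$grid_um / 2 - w) / 2
  yq <- y0 + (seq_len(n_px) - 0.5) * px

  total <- sim$conc[[time_index]] + sim$bound[[time_index]]
  conc_px <- .bilinear(sim$x_um, sim$y_um, total, xq, yq)
  pmask <- rasterize_particles(sim$particles,
                               x0_um = layout$start_um[row], y0_um = y0,
                               nx = n_px, ny = n_px, spacing_um = px)
  base <- optics$gain_counts_per_conc * conc_px
  base[pmask] <- 0
  base[base < 0] <- 0

  vmax <- 2^optics$bit_depth - 1
  .with_seed(seed, {
    lapply(z_planes_um, function(z) {
      sigma_px <- optics$defocus_sd_um_per_um * abs(z) / px
      expected <- .cpp_gaussian_blur(base, sigma_px) * ill
      signal <- if (optics$shot_noise) {
        matrix(stats::rpois(length(expected), lambda = expected),
               nrow = n_px)
      } else expected
      frame <- signal + optics$bkg_level_counts
      if (optics$read_noise_sd_counts > 0) {
        frame <- frame + matrix(stats::rnorm(length(frame),
                                             sd = optics$read_noise_sd_counts),
                                nrow = n_px)
      }
      frame <- round(pmin(pmax(frame, 0), vmax))
      storage.mode(frame) <- "integer"
      frame
    })
  })
}

# ---------------------------------------------------------------------------
# Whole acquisitions

# deterministic per-frame sub-seed below 2^31
.sub_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master %% 2147483647L)
  for (k in ids) s <- (s * 131071 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

#' Simulate a complete acquisition in memory
#'
#' Runs the physics once, builds the shared illumination field, renders
#' every (position, time, z) frame plus dark frames, and returns a
#' `gelmob_run` object ready for [extract_profiles()].
#'
#' @param gel,enzyme,source,optics spec objects (defaults used when NULL).
#' @param geometry an [acquisition_geometry()].
#' @param n_positions number of ROI positions.
#' @param seed master seed; all particle, noise and vignette draws derive
#'   from it, so runs are reproducible.
#' @param grid_um,dt_s,method,domain_y_um passed to
#'   [simulate_concentration()].
#' @param n_dark number of dark frames (>= 5 recommended).
#' @param experiment experiment identifier recorded in the records.
#' @return object of class `gelmob_run` with fields `geometry`, `layout`,
#'   `positions`, `times_min`, `z_um`, `frames` (nested
#'   `[[pos]][[time]][[z]]`), `dark` (list), `ill_true`, `sim` (ground
#'   truth), `meta`, `seed`.
#' @export
simulate_acquisition <- function(gel = gel_spec(), enzyme = enzyme_spec(),
                                 source = source_spec(), optics = optics_spec(),
                                 geometry = acquisition_geometry(),
                                 n_positions = 7L, seed = 1L, grid_um = 4,
                                 dt_s = 2, method = "adi", domain_y_um = 300,
                                 n_dark = 10L, experiment = "sim") {
  layout <- build_position_layout(geometry, n_positions)
  sim <- simulate_concentration(gel, enzyme, source, geometry, layout,
                                grid_um = grid_um, seed = .sub_seed(seed, 1),
                                dt_s = dt_s, method = method,
                                domain_y_um = domain_y_um)
  n_px <- geometry$pixels_per_side
  ill <- make_illumination_field(n_px, optics, seed = .sub_seed(seed, 2))
  times <- sim$times_min
  zs <- z_offsets_um(geometry)

  frames <- list()
  for (p in layout$pos_id) {
    per_t <- vector("list", length(times))
    for (ti in seq_along(times)) {
      per_t[[ti]] <- render_zstack(sim, ti, optics, geometry, p, layout,
                                   seed = .sub_seed(seed, 3, p, ti), ill = ill)
    }
    frames[[as.character(p)]] <- per_t
  }
  dark <- .with_seed(.sub_seed(seed, 4), {
    lapply(seq_len(n_dark), function(i) {
      fr <- optics$bkg_level_counts +
        matrix(stats::rnorm(n_px^2, sd = optics$read_noise_sd_counts), n_px)
      fr <- round(pmin(pmax(fr, 0), 2^optics$bit_depth - 1))
      storage.mode(fr) <- "integer"
      fr
    })
  })
  structure(list(geometry = geometry, layout = layout,
                 positions = layout$pos_id, times_min = times, z_um = zs,
                 frames = frames, dark = dark, ill_true = ill, sim = sim,
                 optics = optics,
                 meta = list(experiment = experiment, gel = gel$label,
                             enzyme_state = enzyme$state),
                 seed = seed),
            class = "gelmob_run")
}

#' Fetch one frame of a run
#' @param run a `gelmob_run`.
#' @param pos_id position id.
#' @param time_index,z_index 1-based indices into the run's time points
#'   and z-planes.
#' @return numeric matrix.
#' @export
get_frame <- function(run, pos_id, time_index, z_index) {
  stopifnot(inherits(run, "gelmob_run"))
  if (!is.null(run$frames)) {
    fr <- run$frames[[as.character(pos_id)]][[time_index]][[z_index]]
    if (is.null(fr)) stop("missing frame (pos ", pos_id, ", t index ", time_index,
                          ", z index ", z_index, ")")
    return(fr)
  }
  path <- .frame_path(run$dir, pos_id, run$times_min[time_index], z_index)
  if (!file.exists(path)) stop("missing frame file: ", path)
  read_tiff(path)
}

#' Does a run contain a given frame?
#' @inheritParams get_frame
#' @export
has_frame <- function(run, pos_id, time_index, z_index) {
  stopifnot(inherits(run, "gelmob_run"))
  if (!is.null(run$frames)) {
    p <- run$frames[[as.character(pos_id)]]
    return(!is.null(p) && time_index <= length(p) && !is.null(p[[time_index]]) &&
             z_index <= length(p[[time_index]]) &&
             !is.null(p[[time_index]][[z_index]]))
  }
  file.exists(.frame_path(run$dir, pos_id, run$times_min[time_index], z_index))
}

.frame_path <- function(dir, pos_id, time_min, z_index) {
  file.path(dir, "frames", sprintf("pos%d", pos_id),
            sprintf("t%02.0fmin", time_min), sprintf("z%d.tif", z_index))
}

#' Persist a synthetic acquisition to disk
#'
#' Writes `frames/pos{K}/t{MM}min/z{P}.tif` (16-bit grayscale TIFF),
#' `dark/dark_{i}.tif`, `truth/conc_t{MM}.txt` (total concentration on
#' the physics grid, tab-separated) and `manifest.json` (all parameters
#' and seeds).  Re-running with the same seed reproduces byte-identical
#' files.
#'
#' @param run a `gelmob_run` from [simulate_acquisition()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, overwrite = FALSE) {
  stopifnot(inherits(run, "gelmob_run"), !is.null(run$frames))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory ", out_dir, " is not empty; use overwrite = TRUE")
  }
  for (sub in c("frames", "dark", "truth")) {
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (p in run$positions) for (ti in seq_along(run$times_min)) {
    d <- dirname(.frame_path(out_dir, p, run$times_min[ti], 1L))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (zi in seq_along(run$z_um)) {
      write_tiff(run$frames[[as.character(p)]][[ti]][[zi]],
                 .frame_path(out_dir, p, run$times_min[ti], zi), bits = 16L)
    }
  }
  for (i in seq_along(run$dark)) {
    write_tiff(run$dark[[i]],
               file.path(out_dir, "dark", sprintf("dark_%d.tif", i)), bits = 16L)
  }
  for (ti in seq_along(run$times_min)) {
    utils::write.table(run$sim$conc[[ti]] + run$sim$bound[[ti]],
                       file.path(out_dir, "truth",
                                 sprintf("conc_t%02.0f.txt", run$times_min[ti])),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("gelmob")),
                   seed = run$seed, meta = run$meta,
                   geometry = unclass(run$geometry),
                   gel = unclass(run$sim$gel), enzyme = unclass(run$sim$enzyme),
                   source = unclass(run$sim$source), optics = unclass(run$optics),
                   grid_um = run$sim$grid_um, dt_s = run$sim$dt_s,
                   method = run$sim$method,
                   times_min = run$times_min, z_um = run$z_um,
                   positions = run$positions, n_dark = length(run$dark))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load a persisted acquisition as a lazily-read run
#'
#' @param dir directory written by [write_run()] (or any tree with the
#'   same layout and `manifest.json`).
#' @return a `gelmob_run` whose frames are read from disk on demand;
#'   `dark_frames(run)` reads the dark frames.
#' @export
load_run <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  g <- mf$geometry
  geometry <- acquisition_geometry(g$pixels_per_side, g$pixel_size_um, g$n_z,
                                   g$z_step_um, g$z_range_um, g$n_timepoints,
                                   g$dt_min)
  layout <- build_position_layout(geometry, length(mf$positions))
  structure(list(geometry = geometry, layout = layout,
                 positions = mf$positions, times_min = mf$times_min,
                 z_um = mf$z_um, frames = NULL, dir = dir,
                 n_dark = mf$n_dark, meta = mf$meta, seed = mf$seed),
            class = "gelmob_run")
}

#' Dark frames of a run
#' @param run a `gelmob_run`.
#' @return list of matrices.
#' @export
dark_frames <- function(run) {
  stopifnot(inherits(run, "gelmob_run"))
  if (!is.null(run$dark)) return(run$dark)
  paths <- list.files(file.path(run$dir, "dark"), pattern = "^dark_.*\\.tif$",
                      full.names = TRUE)
  if (length(paths) == 0) stop("no dark frames under ", run$dir)
  lapply(paths[order(nchar(paths), paths)], read_tiff)
}
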