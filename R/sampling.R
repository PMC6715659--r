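# Measurement-pixel selection and intensity extraction.
#
# The reference procedure selects, for each position of each experiment,
# one set of pixels -- a random chord across the field (which can dodge
# non-fluorescent cellulose particles) or a centred circle of 1/2 or 3/4
# of the field width -- and averages the corrected intensity over those
# pixels and over the z-stack.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One chord candidate: uniform angle in [0, pi), uniform signed offset
# from centre within the inscribed radius, clipped to the frame square and
# rasterized to a connected pixel path.  Returns NULL when the chord's
# endpoints do not land on opposite borders.
.chord_candidate <- function(n_px) {
  theta <- stats::runif(1, 0, pi)
  offset <- stats::runif(1, -n_px / 2, n_px / 2)
  ctr <- (n_px - 1) / 2
  d <- c(cos(theta), sin(theta))       # direction (x, y)
  nrm <- c(-sin(theta), cos(theta))
  p0 <- c(ctr, ctr) + offset * nrm
  # clip the infinite line p0 + t*d to [0, n-1]^2 (slab method)
  tmin <- -Inf; tmax <- Inf
  for (k in 1:2) {
    if (abs(d[k]) < 1e-12) {
      if (p0[k] < 0 || p0[k] > n_px - 1) return(NULL)
    } else {
      t1 <- (0 - p0[k]) / d[k]; t2 <- (n_px - 1 - p0[k]) / d[k]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (!is.finite(tmin) || tmax <= tmin) return(NULL)
  a <- p0 + tmin * d; b <- p0 + tmax * d
  border_of <- function(p) {
    if (abs(p[1]) < 0.5) "left" else if (abs(p[1] - (n_px - 1)) < 0.5) "right"
    else if (abs(p[2]) < 0.5) "bottom" else if (abs(p[2] - (n_px - 1)) < 0.5) "top"
    else NA_character_
  }
  ba <- border_of(a); bb <- border_of(b)
  opposite <- (identical(sort(c(ba, bb)), c("left", "right")) ||
               identical(sort(c(ba, bb)), c("bottom", "top")))
  if (is.na(ba) || is.na(bb) || !opposite) return(NULL)
  n_steps <- max(abs(b - a)) + 1
  xs <- round(seq(a[1], b[1], length.out = ceiling(n_steps)))
  ys <- round(seq(a[2], b[2], length.out = ceiling(n_steps)))
  keep <- !duplicated(cbind(xs, ys))
  cbind(row = ys[keep] + 1L, col = xs[keep] + 1L)  # 1-based matrix indices
}

#' Draw a random measurement line across the field
#'
#' Draws a chord with uniformly random orientation and offset, rasterized
#' to a connected pixel path whose endpoints lie on opposite image
#' borders.  If an exclusion mask is supplied (TRUE = excluded pixel,
#' e.g. cellulose particles), candidates are redrawn until the fraction of
#' path pixels falling inside the mask is at most `max_overlap`; after
#' `max_redraws` unsuccessful draws the minimum-overlap candidate is
#' returned with a warning (never a silent failure).
#'
#' @param geometry an [acquisition_geometry()] object.
#' @param seed integer seed; the path is a deterministic function of
#'   (seed, geometry, mask).
#' @param exclusion_mask optional logical matrix, TRUE where measurement
#'   pixels are not wanted.
#' @param max_overlap maximum tolerated overlap fraction (default 0.05).
#' @param max_redraws redraw budget (default 50).
#' @param pos_id optional position id recorded in the sample.
#' @return Object of class `line_sample`: `pixel_coords` (two-column
#'   matrix of 1-based row/col), `seed`, `overlap_fraction`, `pos_id`.
#' @export
draw_random_line <- function(geometry, seed, exclusion_mask = NULL,
                             max_overlap = 0.05, max_redraws = 50L,
                             pos_id = NA_integer_) {
  stopifnot(inherits(geometry, "acq_geometry"))
  n_px <- geometry$pixels_per_side
  if (!is.null(exclusion_mask)) {
    stopifnot(is.matrix(exclusion_mask))
    if (!all(dim(exclusion_mask) == c(n_px, n_px))) {
      stop("exclusion_mask shape does not match the frame")
    }
  }
  best <- NULL
  .with_seed(seed, {
    for (attempt in seq_len(max_redraws)) {
      coords <- NULL
      for (sub in 1:100) {          # opposite-border rejection, not counted
        coords <- .chord_candidate(n_px)
        if (!is.null(coords)) break
      }
      if (is.null(coords)) next
      ov <- if (is.null(exclusion_mask)) 0 else {
        mean(exclusion_mask[cbind(coords[, 1], coords[, 2])])
      }
      if (is.null(best) || ov < best$overlap_fraction) {
        best <- list(coords = coords, overlap_fraction = ov, attempts = attempt)
      }
      if (ov <= max_overlap) break
    }
  })
  if (is.null(best)) stop("failed to draw any chord candidate")
  if (best$overlap_fraction > max_overlap) {
    warning(sprintf(paste0("no chord with overlap <= %.3f found in %d draws; ",
                           "returning best candidate (overlap %.3f)"),
                    max_overlap, max_redraws, best$overlap_fraction))
  }
  structure(list(pos_id = pos_id, pixel_coords = best$coords, seed = seed,
                 overlap_fraction = best$overlap_fraction,
                 n_attempts = best$attempts),
            class = "line_sample")
}

#' Rasterize a centred measurement circle
#'
#' Perimeter pixels (not the disk) of the circle whose diameter is
#' `fraction` of the field width, centred in the frame.  Pixels are those
#' whose centre lies within half a pixel of the target radius.
#'
#' @param geometry an [acquisition_geometry()] object.
#' @param fraction circle diameter as a fraction of the frame width;
#'   supported values are 1/2 and 3/4.
#' @return two-column matrix of 1-based (row, col) pixel indices.
#' @export
draw_circle <- function(geometry, fraction) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (!isTRUE(all.equal(fraction, 0.5)) && !isTRUE(all.equal(fraction, 0.75))) {
    stop("unsupported circle fraction ", fraction, "; use 1/2 or 3/4")
  }
  n_px <- geometry$pixels_per_side
  r <- fraction * n_px / 2
  ctr <- (n_px + 1) / 2
  ij <- expand.grid(row = seq_len(n_px), col = seq_len(n_px))
  dist <- sqrt((ij$row - ctr)^2 + (ij$col - ctr)^2)
  keep <- abs(dist - r) <= 0.5
  as.matrix(ij[keep, c("row", "col")])
}

#' Within-field x offsets of a pixel sample
#'
#' Converts sample pixel columns to physical offsets (um) from the
#' deposit-side edge of the field, using pixel centres.  Useful as the
#' measurement model of [fit_effective_diffusivity()]: a random chord
#' samples x non-uniformly, and these offsets say exactly where.
#'
#' @param sample a [draw_random_line()] result or (row, col) matrix.
#' @param geometry an [acquisition_geometry()] object.
#' @return numeric vector of offsets in um.
#' @export
sample_x_offsets_um <- function(sample, geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  coords <- if (inherits(sample, "line_sample")) sample$pixel_coords else sample
  (coords[, "col"] - 0.5) * geometry$pixel_size_um
}

#' Mean intensity of a pixel sample, averaged over the z-stack
#'
#' The same pixel set is evaluated in every z-plane; the per-plane means
#' are then averaged (with a fixed pixel set this equals the grand mean).
#'
#' @param corrected_zstack list of corrected numeric matrices (one per
#'   z-plane), or a single matrix.
#' @param sample a [draw_random_line()] result or a two-column (row, col)
#'   index matrix such as [draw_circle()] returns.
#' @return mean intensity (counts).
#' @export
measure_intensity <- function(corrected_zstack, sample) {
  if (is.matrix(corrected_zstack)) corrected_zstack <- list(corrected_zstack)
  if (length(corrected_zstack) == 0) stop("empty z-stack")
  coords <- if (inherits(sample, "line_sample")) sample$pixel_coords else sample
  if (!is.matrix(coords) || nrow(coords) == 0) stop("empty pixel sample")
  per_plane <- vapply(corrected_zstack,
                      function(pl) mean(pl[cbind(coords[, 1], coords[, 2])]),
                      numeric(1))
  mean(per_plane)
}

#' Extract the intensity profiles I = f(Pos, t) of one experiment
#'
#' For each position one pixel sample is drawn (at the first time point)
#' and reused across all times and z-planes, so the time series are
#' directly comparable.  Every frame is shading-corrected before
#' measurement.
#'
#' @param run a `gelmob_run` (see [simulate_acquisition()] / [load_run()]).
#' @param model a [shading_model()].
#' @param sampler one of `"random_line"`, `"circle_half"`,
#'   `"circle_threequarter"`.
#' @param seed seed for the random-line sampler; position k uses
#'   `seed + k` so lines differ between positions but are reproducible.
#' @param exclusion `"none"`, `"auto"` (threshold each position's
#'   corrected first-time mid-z frame at `auto_threshold` times its
#'   median; pixels below are treated as particles), or a logical matrix
#'   applied to every position.
#' @param auto_threshold threshold factor for `exclusion = "auto"`.
#' @param max_overlap,max_redraws passed to [draw_random_line()].
#' @return data.frame of intensity records with columns `experiment`,
#'   `gel`, `enzyme_state`, `pos`, `time_min`, `sampler`, `n_pixels`,
#'   `mean_counts`; the per-position samples are attached as attribute
#'   `"samples"` for audit.
#' @export
extract_profiles <- function(run, model, sampler = c("random_line", "circle_half",
                                                     "circle_threequarter"),
                             seed = 1L, exclusion = "none", auto_threshold = 0.2,
                             max_overlap = 0.05, max_redraws = 50L) {
  stopifnot(inherits(run, "gelmob_run"), inherits(model, "shading_model"))
  sampler <- match.arg(sampler)
  geom <- run$geometry
  times <- run$times_min
  n_z <- geom$n_z
  mid_z <- (n_z + 1) %/% 2

  missing <- character(0)
  for (p in run$positions) for (ti in seq_along(times)) for (zi in seq_len(n_z)) {
    if (!has_frame(run, p, ti, zi)) {
      missing <- c(missing, sprintf("(pos %d, t %g min, z %d)", p, times[ti], zi))
    }
  }
  if (length(missing) > 0) {
    stop("missing frames: ", paste(missing, collapse = ", "))
  }

  samples <- list()
  records <- vector("list", length(run$positions) * length(times))
  k <- 0L
  frac_neg <- 0
  for (p in run$positions) {
    if (sampler == "random_line") {
      mask <- NULL
      if (is.matrix(exclusion)) {
        mask <- exclusion
      } else if (identical(exclusion, "auto")) {
        ref <- shading_correct(get_frame(run, p, 1L, mid_z), model)
        mask <- ref < auto_threshold * stats::median(ref)
      } else if (!identical(exclusion, "none")) {
        stop("exclusion must be 'none', 'auto' or a logical matrix")
      }
      smp <- draw_random_line(geom, seed = seed + p, exclusion_mask = mask,
                              max_overlap = max_overlap,
                              max_redraws = max_redraws, pos_id = p)
      coords <- smp$pixel_coords
    } else {
      frac <- if (sampler == "circle_half") 0.5 else 0.75
      coords <- draw_circle(geom, frac)
      smp <- list(pos_id = p, pixel_coords = coords)
    }
    samples[[as.character(p)]] <- smp

    for (ti in seq_along(times)) {
      zstack <- lapply(seq_len(n_z), function(zi) {
        suppressMessages(shading_correct(get_frame(run, p, ti, zi), model))
      })
      frac_neg <- max(vapply(zstack, function(m) mean(m < 0), numeric(1)),
                      frac_neg)
      k <- k + 1L
      records[[k]] <- data.frame(experiment = run$meta$experiment,
                                 gel = run$meta$gel,
                                 enzyme_state = run$meta$enzyme_state,
                                 pos = p, time_min = times[ti],
                                 sampler = sampler, n_pixels = nrow(coords),
                                 mean_counts = measure_intensity(zstack, coords))
    }
  }
  out <- do.call(rbind, records)
  attr(out, "samples") <- samples
  if (frac_neg > 0.01) {
    # near-dark frames straddle zero after background subtraction
    message(sprintf(paste0("extract_profiles: up to %.0f%% negative pixels in ",
                           "corrected frames (expected where signal ~ 0)"),
                    100 * frac_neg))
  }
  out
}
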