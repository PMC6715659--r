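#' Acquisition geometry
#'
#' Single source of truth for the physical coordinates of an acquisition:
#' sensor size, pixel pitch, z-stack sampling and time-lapse sampling.
#' Defaults describe the reference setup: a 1024 x 1024 CCD at
#' 0.2804 um/pixel (field of view 287 x 287 um^2), 5 focal planes spanning
#' -2..+2 um in 1 um steps, and 12 acquisitions at 5 min intervals
#' (0 to 55 min).
#'
#' @param pixels_per_side integer, sensor side length in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param n_z number of focal planes.
#' @param z_step_um focal-plane spacing in micrometres.
#' @param z_range_um symmetric half-range of the z-stack in micrometres;
#'   must satisfy `n_z == 2 * z_range_um / z_step_um + 1`.
#' @param n_timepoints number of acquisitions in the time lapse.
#' @param dt_min interval between acquisitions in minutes.
#' @return An object of class `acq_geometry`.
#' @examples
#' g <- acquisition_geometry()
#' field_width_um(g)   # 287.1296
#' @export
acquisition_geometry <- function(pixels_per_side = 1024L, pixel_size_um = 0.2804,
                                 n_z = 5L, z_step_um = 1, z_range_um = 2,
                                 n_timepoints = 12L, dt_min = 5) {
  stopifnot(pixels_per_side >= 1, pixel_size_um > 0, n_z >= 1, z_step_um > 0,
            z_range_um >= 0, n_timepoints >= 1, dt_min > 0)
  if (n_z != 2 * (z_range_um / z_step_um) + 1) {
    stop("inconsistent z sampling: need n_z == 2 * z_range_um / z_step_um + 1")
  }
  structure(list(pixels_per_side = as.integer(pixels_per_side),
                 pixel_size_um = pixel_size_um,
                 n_z = as.integer(n_z), z_step_um = z_step_um,
                 z_range_um = z_range_um,
                 n_timepoints = as.integer(n_timepoints), dt_min = dt_min),
            class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("Acquisition geometry: %d x %d px at %.4f um/px (field %.1f um)\n",
              x$pixels_per_side, x$pixels_per_side, x$pixel_size_um,
              field_width_um(x)))
  cat(sprintf("  z: %d planes, step %g um (range +/- %g um)\n",
              x$n_z, x$z_step_um, x$z_range_um))
  cat(sprintf("  t: %d acquisitions every %g min (span %g min)\n",
              x$n_timepoints, x$dt_min, (x$n_timepoints - 1) * x$dt_min))
  invisible(x)
}

#' Width of one field of view in micrometres
#' @param geometry an [acquisition_geometry()] object.
#' @export
field_width_um <- function(geometry) {
  geometry$pixels_per_side * geometry$pixel_size_um
}

#' Acquisition time points in minutes
#' @param geometry an [acquisition_geometry()] object.
#' @export
acquisition_times_min <- function(geometry) {
  seq(0, by = geometry$dt_min, length.out = geometry$n_timepoints)
}

#' Focal-plane offsets in micrometres
#' @param geometry an [acquisition_geometry()] object.
#' @export
z_offsets_um <- function(geometry) {
  seq(-geometry$z_range_um, geometry$z_range_um, by = geometry$z_step_um)
}

#' Lay out the regions of interest along the enzyme-migration axis
#'
#' Positions (Pos0..Pos6 in the reference setup) are fields of view placed
#' along a 1-D axis x with x = 0 at the gel edge adjacent to the enzyme
#' deposit channel, increasing into the gel.  The first two positions are
#' contiguous fields; every later position skips one field ("1 field over
#' 2"), i.e. field indices 0, 1, 3, 5, 7, 9, 11, ...
#'
#' @param geometry an [acquisition_geometry()] object.
#' @param n_positions number of positions (default 7).
#' @return A data.frame of class `position_layout` with columns `pos_id`
#'   (0-based), `field_index`, `start_um`, `end_um`, and `start_rounded_um`
#'   (`start_um` rounded to the nearest 10 um, the precision used in prose;
#'   e.g. Pos2 starts at 861.4 um, printed as 860 um).  The field width is
#'   attached as attribute `field_width_um`.
#' @examples
#' build_position_layout(acquisition_geometry(), 7)
#' @export
build_position_layout <- function(geometry, n_positions = 7L) {
  stopifnot(inherits(geometry, "acq_geometry"))
  n_positions <- as.integer(n_positions)
  if (length(n_positions) != 1L || is.na(n_positions) || n_positions < 1L) {
    stop("n_positions must be a positive integer")
  }
  w <- field_width_um(geometry)
  pos_id <- seq_len(n_positions) - 1L
  field_index <- ifelse(pos_id <= 1L, pos_id, 2L * pos_id - 1L)
  layout <- data.frame(pos_id = pos_id,
                       field_index = as.integer(field_index),
                       start_um = field_index * w,
                       end_um = (field_index + 1) * w)
  layout$start_rounded_um <- round(layout$start_um / 10) * 10
  attr(layout, "field_width_um") <- w
  class(layout) <- c("position_layout", "data.frame")
  layout
}

#' Physical distance of a pixel column from the enzyme deposit point
#'
#' Images are stored in acquisition orientation; analysis uses a 1-D axis
#' whose origin is the deposit-side edge of Pos0.  `pixel_column` is
#' 0-based and counted from the deposit-side edge of the field; a field
#' spans the half-open interval `[start_um, end_um)` so column 0 of Pos0
#' maps to exactly 0 um.
#'
#' @param geometry an [acquisition_geometry()] object.
#' @param layout a [build_position_layout()] result.
#' @param pos_id position identifier (0-based) present in `layout`.
#' @param pixel_column 0-based column offset within the field.
#' @return Distance in micrometres from the deposit point.
#' @export
pixel_to_physical <- function(geometry, layout, pos_id, pixel_column) {
  stopifnot(inherits(geometry, "acq_geometry"), inherits(layout, "position_layout"))
  row <- match(pos_id, layout$pos_id)
  if (is.na(row)) stop("pos_id ", pos_id, " not present in layout")
  if (any(pixel_column < 0 | pixel_column >= geometry$pixels_per_side)) {
    stop("pixel_column out of range [0, ", geometry$pixels_per_side - 1, "]")
  }
  layout$start_um[row] + pixel_column * geometry$pixel_size_um
}
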