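# Shading correction: IMC = (IM - BKG) / ILL.
# BKG is the additive camera background, averaged from dark frames.
# ILL is the multiplicative illumination inhomogeneity, estimated from one
# raw frame by grayscale morphological opening, then closing, then a mean
# filter, all with the same window size (105 px at full resolution).

#' Average dark camera frames into an additive background image
#'
#' @param frames list of numeric matrices of identical shape.
#' @return numeric matrix, the pixelwise arithmetic mean (floating point).
#' @export
average_dark_frames <- function(frames) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("frames must be a non-empty list of matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("dark frames have mismatched shapes")
  }
  Reduce(`+`, frames) / length(frames)
}

#' Estimate the illumination inhomogeneity field from one raw frame
#'
#' Applies, in order, grayscale morphological opening, morphological
#' closing, and an average filter, each over a square window of
#' `filter_size` pixels (replicate-edge padding).  The opening removes
#' bright structure smaller than the window, the closing removes dark
#' structure (e.g. non-fluorescent cellulose particles), and the mean
#' filter smooths what remains, leaving only the slow illumination
#' pattern.  The result is divided by its mean, so the returned field is
#' dimensionless with unit mean and the corrected image keeps the count
#' scale of the raw image (see `normalize` to disable).
#'
#' @param raw_frame raw (uncorrected) numeric matrix; the convention is to
#'   use the Pos0 frame at T0, middle z-plane.
#' @param filter_size odd window size in pixels (default 105).
#' @param normalize divide by the field mean (default TRUE).  With
#'   `FALSE` the field keeps raw-count units and the corrected image is
#'   dimensionless, of order 1.
#' @return numeric matrix, strictly positive.
#' @export
estimate_illumination <- function(raw_frame, filter_size = 105L, normalize = TRUE) {
  stopifnot(is.matrix(raw_frame))
  filter_size <- as.integer(filter_size)
  if (filter_size < 1L || filter_size %% 2L == 0L) {
    stop("filter_size must be a positive odd integer")
  }
  if (filter_size > min(dim(raw_frame))) {
    stop("filter_size (", filter_size, ") exceeds frame size (",
         min(dim(raw_frame)), ")")
  }
  opened <- .cpp_dilate(.cpp_erode(raw_frame, filter_size), filter_size)
  closed <- .cpp_erode(.cpp_dilate(opened, filter_size), filter_size)
  ill <- .cpp_mean_filter(closed, filter_size)
  if (any(ill <= 0)) {
    stop("degenerate input: estimated illumination field is not strictly positive")
  }
  if (normalize) ill <- ill / mean(ill)
  ill
}

#' Bundle background and illumination fields into a shading model
#'
#' @param bkg additive background image (counts), non-negative.
#' @param ill multiplicative illumination field, strictly positive; by
#'   convention unit mean (checked unless `check_unit_mean = FALSE`).
#' @param provenance optional list (number of dark frames averaged, source
#'   frame id for `ill`, filter size) carried along for audit.
#' @param check_unit_mean require `mean(ill)` within 1e-6 of 1.
#' @return object of class `shading_model`.
#' @export
shading_model <- function(bkg, ill, provenance = list(), check_unit_mean = TRUE) {
  stopifnot(is.matrix(bkg), is.matrix(ill))
  if (!all(dim(bkg) == dim(ill))) stop("bkg and ill shapes differ")
  if (any(bkg < 0)) stop("bkg must be non-negative")
  if (any(ill <= 0)) stop("ill must be strictly positive")
  if (check_unit_mean && abs(mean(ill) - 1) > 1e-6) {
    stop("ill is not unit mean (mean = ", format(mean(ill)), "); ",
         "set check_unit_mean = FALSE for raw-count ILL fields")
  }
  structure(list(bkg = bkg, ill = ill, provenance = provenance),
            class = "shading_model")
}

#' Shading-correct a raw frame
#'
#' Computes `(im - bkg) / ill` pixelwise in floating point.  Negative
#' values are permitted (read noise around zero signal); if more than 1%
#' of pixels are negative a warning reports the fraction.
#'
#' @param im raw numeric matrix.
#' @param model a [shading_model()].
#' @return corrected numeric matrix.
#' @export
shading_correct <- function(im, model) {
  stopifnot(is.matrix(im), inherits(model, "shading_model"))
  if (!all(dim(im) == dim(model$bkg))) stop("frame and shading model shapes differ")
  out <- (im - model$bkg) / model$ill
  frac_neg <- mean(out < 0)
  if (frac_neg > 0.01) {
    # expected for frames that carry no signal: read noise straddles zero
    message(sprintf("shading_correct: %.1f%% of corrected pixels are negative",
                    100 * frac_neg))
  }
  out
}

#' Build a shading model from dark frames and a reference raw frame
#'
#' Convenience wrapper: averages the dark frames into BKG and estimates
#' ILL from `reference_frame` (by convention the Pos0 frame at the first
#' time point, middle z-plane); the same model is reused for every
#' position, time and z-plane of the experiment.
#'
#' @param dark_frames list of dark camera frames.
#' @param reference_frame raw frame used for the illumination estimate.
#' @param filter_size window size for [estimate_illumination()].
#' @param normalize passed to [estimate_illumination()].
#' @return a [shading_model()].
#' @export
build_shading_model <- function(dark_frames, reference_frame, filter_size = 105L,
                                normalize = TRUE) {
  bkg <- average_dark_frames(dark_frames)
  ill <- estimate_illumination(reference_frame, filter_size = filter_size,
                               normalize = normalize)
  shading_model(bkg, ill,
                provenance = list(n_dark = length(dark_frames),
                                  filter_size = as.integer(filter_size),
                                  ill_normalized = normalize),
                check_unit_mean = normalize)
}
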