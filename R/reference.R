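# Reference displacement estimators: ROI-phase-corrected averaging and the
# four-image EPI-style difference-of-differences. Phase differences are
# always computed through complex-conjugate products, never wrapped-phase
# subtraction, to avoid +/-pi wrap errors. Both share the model's theta
# convention (per-image contrast phase), so one conversion formula applies
# to all estimators.

#' Rectangular region of interest
#'
#' 0-based, half-open voxel bounds `[row_start, row_stop) x
#' [col_start, col_stop)`.
#'
#' @param row_start,row_stop,col_start,col_stop Integer bounds.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row_start, row_stop, col_start, col_stop) {
  b <- as.integer(c(row_start, row_stop, col_start, col_stop))
  if (anyNA(b) || b[1L] < 0L || b[3L] < 0L || b[2L] <= b[1L] || b[4L] <= b[3L])
    stop_validation("ROI bounds must be 0-based, half-open and non-empty")
  structure(list(row_start = b[1L], row_stop = b[2L],
                 col_start = b[3L], col_stop = b[4L]),
            class = "rect_roi")
}

roi_indices <- function(roi, gs) {
  if (roi$row_stop > gs[1L] || roi$col_stop > gs[2L])
    stop_validation("ROI extends outside the image grid")
  rows <- (roi$row_start + 1L):roi$row_stop
  cols <- (roi$col_start + 1L):roi$col_stop
  list(rows = rows, cols = cols)
}

#' ROI-phase-corrected displacement map
#'
#' The reference method: subtract from each image the phase of its complex
#' mean over a manually selected out-of-focus rectangular ROI, average the
#' corrected positive-contrast and negative-contrast images, and take half
#' the phase of mean_pos * conj(mean_neg) as the displacement phase. The
#' half makes theta the per-image contrast phase, matching [fit_arfi()].
#' Exactly invariant to per-timepoint spatially constant phase offsets.
#'
#' @param series A [complex_image_series()] containing both contrasts.
#' @param roi A [rect_roi()] inside the grid, away from the focus.
#' @param params An [acquisition_params()]; defaults to the series' own.
#' @param mask Optional logical matrix for the output map.
#' @return A [displacement_map()] in meters.
#' @export
roi_corrected_map <- function(series, roi, params = series$params,
                              mask = NULL) {
  stopifnot(inherits(series, "complex_image_series"),
            inherits(roi, "rect_roi"))
  gs <- grid_shape(series)
  idx <- roi_indices(roi, gs)
  ind <- unclass(series$schedule)
  Nt <- n_timepoints(series)
  corrected <- vapply(seq_len(Nt), function(n) {
    im <- series$data[, , n]
    roi_phase <- Arg(mean(im[idx$rows, idx$cols]))
    im * exp(-1i * roi_phase)
  }, series$data[, , 1L])
  mean_pos <- apply(corrected[, , ind == 0L, drop = FALSE], c(1, 2), mean)
  mean_neg <- apply(corrected[, , ind == 1L, drop = FALSE], c(1, 2), mean)
  theta <- Arg(mean_pos * Conj(mean_neg)) / 2
  displacement_map(phase_to_displacement(theta, params), mask = mask,
                   provenance = list(method = "roi", roi = unclass(roi)),
                   pixel_spacing = series$pixel_spacing)
}

#' Four-image EPI-style displacement map
#'
#' The difference-of-differences estimator used with interleaved
#' ultrasound-on/off acquisitions: cycles of four timepoints ordered
#' (FUS off, positive MEG), (FUS on, positive), (FUS off, negative),
#' (FUS on, negative). Per cycle the on-minus-off phase difference is formed
#' for each polarity via conjugate products, the two are differenced, and
#' half of the cycle-averaged result is the displacement phase.
#'
#' @param series_on_off A [complex_image_series()] whose length is a
#'   multiple of 4 and whose schedule follows the cycle above (as produced
#'   by [make_schedule]`("epi4", n)`).
#' @param params An [acquisition_params()]; defaults to the series' own.
#' @param mask Optional logical matrix.
#' @return A [displacement_map()] in meters.
#' @export
epi_style_map <- function(series_on_off, params = series_on_off$params,
                          mask = NULL) {
  stopifnot(inherits(series_on_off, "complex_image_series"))
  Nt <- n_timepoints(series_on_off)
  if (Nt %% 4L != 0L)
    stop_validation("epi-style series must have a multiple of 4 timepoints")
  ind <- unclass(series_on_off$schedule)
  if (!all(ind == rep(c(0L, 0L, 1L, 1L), Nt / 4L)))
    stop_validation("schedule does not follow the off/pos, on/pos, off/neg, ",
                    "on/neg cycle")
  X <- series_on_off$data
  cyc <- seq(1L, Nt, by = 4L)
  acc_pos <- 0i * X[, , 1L]
  acc_neg <- acc_pos
  for (k in cyc) {
    acc_pos <- acc_pos + X[, , k + 1L] * Conj(X[, , k])
    acc_neg <- acc_neg + X[, , k + 3L] * Conj(X[, , k + 2L])
  }
  theta <- Arg(acc_pos * Conj(acc_neg)) / 2
  displacement_map(phase_to_displacement(theta, params), mask = mask,
                   provenance = list(method = "epi4", n_cycles = length(cyc)),
                   pixel_spacing = series_on_off$pixel_spacing)
}
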