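#' @keywords internal
"_PACKAGE"

# Gyromagnetic constant used throughout the displacement <-> phase conversion,
# on the MHz/T scale: phase [rad] = 2*pi * 42.58 * G[mT/m] * T[ms] * d[m].
GAMMA_BAR <- 42.58

stop_validation <- function(...) stop(..., call. = FALSE)

#' Acquisition parameters for an MR-ARFI scan
#'
#' Bundles the motion-encoding gradient (MEG) settings and ultrasound
#' parameters needed to convert displacement-encoding phase to meters and to
#' compute acoustic indices.
#'
#' @param meg_amplitude MEG gradient strength in mT/m (> 0).
#' @param meg_duration MEG duration in ms (> 0).
#' @param us_frequency Ultrasound center frequency in MHz (> 0).
#' @param free_field_pressure Optional free-field peak negative pressure, MPa.
#' @param skull_transmission Optional pressure transmission fraction through
#'   the skull, in (0, 1].
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params(40, 7, 0.65)
#' @export
acquisition_params <- function(meg_amplitude, meg_duration, us_frequency,
                               free_field_pressure = NULL,
                               skull_transmission = NULL) {
  for (nm in c("meg_amplitude", "meg_duration", "us_frequency")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_validation(nm, " must be a single positive number")
  }
  if (!is.null(free_field_pressure) &&
      (!is.numeric(free_field_pressure) || free_field_pressure <= 0))
    stop_validation("free_field_pressure must be positive when given")
  if (!is.null(skull_transmission) &&
      (!is.numeric(skull_transmission) || skull_transmission <= 0 ||
       skull_transmission > 1))
    stop_validation("skull_transmission must lie in (0, 1]")
  structure(list(meg_amplitude = as.numeric(meg_amplitude),
                 meg_duration = as.numeric(meg_duration),
                 gamma_bar = GAMMA_BAR,
                 us_frequency = as.numeric(us_frequency),
                 free_field_pressure = free_field_pressure,
                 skull_transmission = skull_transmission),
            class = "acquisition_params")
}

#' Trigger schedule: which timepoints carry negated displacement contrast
#'
#' A per-timepoint indicator sequence: 0 means the ultrasound trigger
#' coincided with the first MEG (positive displacement phase contrast),
#' 1 means the second MEG (negated contrast). A schedule must contain both
#' values, otherwise the displacement phase is unidentifiable.
#'
#' @param indicators Integer vector of 0/1, length >= 2.
#' @param fus Optional logical vector (same length) marking timepoints with
#'   the ultrasound actually firing; used by the four-image EPI-style cycle
#'   where half the timepoints are acquired with ultrasound off. Default:
#'   ultrasound on at every timepoint.
#' @return An object of class `trigger_schedule` (an integer vector with a
#'   `fus` attribute).
#' @export
trigger_schedule <- function(indicators, fus = NULL) {
  ind <- as.integer(indicators)
  if (length(ind) < 2L || anyNA(ind) || !all(ind %in% c(0L, 1L)))
    stop_validation("indicators must be a 0/1 vector of length >= 2")
  if (all(ind == ind[1L]))
    stop_validation("schedule must contain both contrasts (0 and 1); ",
                    "a constant schedule makes the displacement phase unidentifiable")
  if (is.null(fus)) fus <- rep(TRUE, length(ind))
  if (length(fus) != length(ind) || !is.logical(fus) || anyNA(fus))
    stop_validation("fus must be a logical vector matching indicators")
  structure(ind, fus = fus, class = "trigger_schedule")
}

#' Contrast signs of a schedule
#'
#' Returns (-1)^indicator per timepoint: +1 for positive contrast, -1 for
#' negated contrast.
#' @param schedule A `trigger_schedule`.
#' @return Numeric vector of +1/-1.
#' @export
schedule_signs <- function(schedule) {
  ifelse(unclass(schedule) == 1L, -1, 1)
}

#' Complex-valued MR-ARFI image timeseries
#'
#' The measured data: Nt complex 2D images on one fixed spatial grid, with
#' the trigger schedule and acquisition metadata attached. Time is the
#' slowest (last) array dimension.
#'
#' @param data Complex array, dim c(rows, cols, timepoints); finite.
#' @param schedule A `trigger_schedule` of length = number of timepoints.
#' @param params An `acquisition_params`.
#' @param pixel_spacing Length-2 numeric, mm per voxel (row, col).
#' @param origin Length-2 numeric, mm coordinates of voxel (1, 1).
#' @return An object of class `complex_image_series`.
#' @export
complex_image_series <- function(data, schedule, params,
                                 pixel_spacing = c(1, 1), origin = c(0, 0)) {
  if (!is.complex(data)) data <- data + 0i
  if (length(dim(data)) != 3L)
    stop_validation("data must be a 3D complex array (rows x cols x timepoints)")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop_validation("data must be finite (no NaN/Inf)")
  if (!inherits(schedule, "trigger_schedule"))
    schedule <- trigger_schedule(schedule)
  if (length(schedule) != dim(data)[3L])
    stop_validation("schedule length (", length(schedule),
                    ") does not match number of timepoints (", dim(data)[3L], ")")
  if (!inherits(params, "acquisition_params"))
    stop_validation("params must be an acquisition_params object")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop_validation("pixel_spacing must be two positive numbers (mm)")
  structure(list(data = data, schedule = schedule, params = params,
                 pixel_spacing = as.numeric(pixel_spacing),
                 origin = as.numeric(origin)),
            class = "complex_image_series")
}

#' @export
dim.complex_image_series <- function(x) dim(x$data)

n_timepoints <- function(series) dim(series$data)[3L]
grid_shape <- function(series) dim(series$data)[1:2]

#' Per-voxel tissue displacement map
#'
#' Displacement in meters (typically reported in nm) on the same grid as the
#' source series, with an optional validity mask and provenance describing
#' the estimator that produced it.
#'
#' @param values Numeric matrix of displacement in meters.
#' @param mask Optional logical matrix; values outside the mask are not
#'   required to be meaningful.
#' @param provenance Named list: estimator name and parameters.
#' @param pixel_spacing Length-2 numeric, mm.
#' @return An object of class `displacement_map`.
#' @export
displacement_map <- function(values, mask = NULL, provenance = list(),
                             pixel_spacing = c(1, 1)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("values must be a numeric matrix (meters)")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop_validation("mask must be a logical matrix matching values")
  if (any(!is.finite(values[mask])))
    stop_validation("displacement values must be finite inside the mask")
  structure(list(values = values, mask = mask, provenance = provenance,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "displacement_map")
}

#' @export
print.complex_image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("complex_image_series: %d x %d grid, %d timepoints\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  schedule: %s\n",
              paste(utils::head(unclass(x$schedule), 12L), collapse = "")))
  cat(sprintf("  MEG: %g mT/m x %g ms; f0 = %g MHz\n",
              x$params$meg_amplitude, x$params$meg_duration,
              x$params$us_frequency))
  invisible(x)
}

#' @export
print.displacement_map <- function(x, ...) {
  v <- x$values[x$mask] * 1e9
  cat(sprintf("displacement_map: %d x %d, %d voxels in mask\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  cat(sprintf("  range %.2f .. %.2f nm (%s)\n", min(v), max(v),
              if (is.null(x$provenance$method)) "unknown estimator"
              else x$provenance$method))
  invisible(x)
}
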