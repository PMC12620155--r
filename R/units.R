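# Displacement <-> phase conversion and transcranial mechanical-index
# arithmetic. All functions are pure.

#' Convert tissue displacement to displacement-encoding phase
#'
#' A displacement d (meters) sustained during a motion-encoding gradient of
#' strength G (mT/m) and duration T (ms) accrues image phase
#' \deqn{\theta = 2\pi \cdot 42.58 \cdot G \cdot T \cdot d,}
#' e.g. 200 nm with a 40 mT/m, 7 ms MEG gives ~0.015 rad.
#'
#' @param d_m Displacement in meters (vector or matrix).
#' @param params An [acquisition_params()].
#' @return Phase in radians, same shape as `d_m`.
#' @seealso [phase_to_displacement()]
#' @export
displacement_to_phase <- function(d_m, params) {
  stopifnot(inherits(params, "acquisition_params"))
  2 * pi * params$gamma_bar * params$meg_amplitude * params$meg_duration * d_m
}

#' Convert displacement-encoding phase to displacement in meters
#'
#' Exact inverse of [displacement_to_phase()]:
#' d = theta / (2 pi 42.58 G T), with G in mT/m and T in ms.
#'
#' @param theta_rad Phase in radians (vector or matrix).
#' @param params An [acquisition_params()].
#' @return Displacement in meters, same shape as `theta_rad`.
#' @export
phase_to_displacement <- function(theta_rad, params) {
  stopifnot(inherits(params, "acquisition_params"))
  theta_rad / (2 * pi * params$gamma_bar * params$meg_amplitude *
                 params$meg_duration)
}

#' Acoustic pressure specification
#'
#' @param free_field_MPa Peak negative pressure measured in free-field water,
#'   MPa (> 0).
#' @param transmission Pressure transmission fraction through the skull,
#'   in (0, 1].
#' @param frequency_MHz Ultrasound center frequency, MHz (> 0).
#' @return An object of class `pressure_spec`.
#' @export
pressure_spec <- function(free_field_MPa, transmission, frequency_MHz) {
  if (!is.numeric(free_field_MPa) || any(free_field_MPa <= 0))
    stop_validation("free_field_MPa must be positive")
  if (!is.numeric(transmission) || any(transmission <= 0) ||
      any(transmission > 1))
    stop_validation("transmission must lie in (0, 1]")
  if (!is.numeric(frequency_MHz) || any(frequency_MHz <= 0))
    stop_validation("frequency_MHz must be positive")
  structure(list(free_field_MPa = free_field_MPa,
                 transmission = transmission,
                 frequency_MHz = frequency_MHz),
            class = "pressure_spec")
}

#' Skull-derated peak negative pressure
#'
#' Free-field pressure multiplied by the skull transmission fraction, e.g.
#' 7 MPa at 39% transmission gives 2.7 MPa at the focus.
#'
#' @param spec A [pressure_spec()].
#' @return Derated pressure in MPa.
#' @export
derated_pressure <- function(spec) {
  stopifnot(inherits(spec, "pressure_spec"))
  spec$free_field_MPa * spec$transmission
}

#' Transcranial mechanical index
#'
#' Derated peak negative pressure divided by the square root of the center
#' frequency in MHz. The FDA limit for diagnostic ultrasound is MI = 1.9.
#'
#' @param spec A [pressure_spec()].
#' @return Mechanical index (unitless).
#' @export
mechanical_index <- function(spec) {
  derated_pressure(spec) / sqrt(spec$frequency_MHz)
}
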