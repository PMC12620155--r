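# Synthetic MR-ARFI acquisition with known ground truth. The simulator
# emulates the statistical structure the reconstruction assumes: a smooth
# complex baseline (disk phantom or smooth random field), a compact Gaussian
# focal displacement-phase spot, per-timepoint spatially smooth phase drift
# (second-order polynomial content plus higher-order content outside the
# model's span, both AR(1)-correlated in time), and i.i.d. circular complex
# Gaussian noise, under alternating, blocked, or four-image EPI-style
# trigger schedules.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a trigger schedule of a given design
#'
#' `alternating` switches contrast every timepoint (0,1,0,1,...), so each
#' consecutive pair forms one average; `blocked` collects all
#' positive-contrast timepoints first, then all negative; `epi4` encodes the
#' four-image interleaved cycle FUS off/positive, on/positive, off/negative,
#' on/negative used by [epi_style_map()].
#'
#' @param kind One of "alternating", "blocked", "epi4".
#' @param n_timepoints Total timepoints (>= 2; a multiple of 4 for epi4).
#' @return A [trigger_schedule()].
#' @export
make_schedule <- function(kind = c("alternating", "blocked", "epi4"),
                          n_timepoints) {
  kind <- match.arg(kind)
  n <- as.integer(n_timepoints)
  if (n < 2L) stop_validation("n_timepoints must be >= 2")
  switch(kind,
    alternating = trigger_schedule(rep_len(c(0L, 1L), n)),
    blocked = trigger_schedule(c(rep(0L, ceiling(n / 2)),
                                 rep(1L, n - ceiling(n / 2)))),
    epi4 = {
      if (n %% 4L != 0L)
        stop_validation("epi4 schedule needs a multiple of 4 timepoints")
      trigger_schedule(rep(c(0L, 0L, 1L, 1L), n / 4L),
                       fus = rep(c(FALSE, TRUE, FALSE, TRUE), n / 4L))
    })
}

#' Simulation configuration
#'
#' Defaults mirror the acquisition regime the package targets: mean image
#' magnitude 1e4, a 2.2 mm lateral-FWHM focal spot, a 200 nm peak
#' displacement, slow (AR(1) rho = 0.9) spatially smooth phase drift of
#' ~0.05 rad, and magnitude SNR 100.
#'
#' @param grid_shape Rows x cols (default 64 x 64).
#' @param pixel_spacing mm per voxel (default 1 x 1).
#' @param baseline_kind "disk" (soft-edged disk phantom) or "smooth_random".
#' @param baseline_amplitude Mean in-object magnitude (default 1e4).
#' @param focus_center Voxel (row, col) of the focal spot; default grid
#'   center.
#' @param focus_fwhm_mm Lateral full width at half maximum of the focal
#'   spot, mm (default 2.2).
#' @param displacement_nm Ground-truth peak displacement, nm (default 200).
#' @param drift_poly_std Stationary std of the random second-order
#'   polynomial drift coefficients, rad (default 0.05).
#' @param drift_highorder_std Stationary spatial std of smooth drift content
#'   outside the second-order span (a random fourth-order field minus its
#'   best second-order approximation), rad (default 0.05).
#' @param drift_ar1 Temporal AR(1) correlation of both drift processes,
#'   in `[0, 1)` (default 0.9).
#' @param noise_std Std of the complex Gaussian noise per real/imaginary
#'   channel (default 100, i.e. SNR 100 at the default amplitude).
#' @param schedule_kind "alternating", "blocked", or "epi4".
#' @param n_timepoints Number of timepoints (default 48, i.e. 24 averages).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(64L, 64L), pixel_spacing = c(1, 1),
                       baseline_kind = c("disk", "smooth_random"),
                       baseline_amplitude = 1e4, focus_center = NULL,
                       focus_fwhm_mm = 2.2, displacement_nm = 200,
                       drift_poly_std = 0.05, drift_highorder_std = 0.05,
                       drift_ar1 = 0.9, noise_std = 100,
                       schedule_kind = c("alternating", "blocked", "epi4"),
                       n_timepoints = 48L, seed) {
  baseline_kind <- match.arg(baseline_kind)
  schedule_kind <- match.arg(schedule_kind)
  grid_shape <- as.integer(grid_shape)
  if (missing(seed) || !is.numeric(seed))
    stop_validation("seed is mandatory for reproducibility")
  if (displacement_nm < 0) stop_validation("displacement_nm must be >= 0")
  if (drift_ar1 < 0 || drift_ar1 >= 1)
    stop_validation("drift_ar1 must lie in [0, 1)")
  if (is.null(focus_center)) focus_center <- ceiling(grid_shape / 2)
  focus_center <- as.numeric(focus_center)
  if (any(focus_center < 1) || any(focus_center > grid_shape))
    stop_validation("focus_center lies outside the grid")
  structure(list(grid_shape = grid_shape,
                 pixel_spacing = as.numeric(pixel_spacing),
                 baseline_kind = baseline_kind,
                 baseline_amplitude = baseline_amplitude,
                 focus_center = focus_center,
                 focus_fwhm_mm = focus_fwhm_mm,
                 displacement_nm = displacement_nm,
                 drift_poly_std = drift_poly_std,
                 drift_highorder_std = drift_highorder_std,
                 drift_ar1 = drift_ar1, noise_std = noise_std,
                 schedule_kind = schedule_kind,
                 n_timepoints = as.integer(n_timepoints),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Distance (mm) of every voxel from a center given in voxel coordinates.
radial_mm <- function(grid_shape, pixel_spacing, center) {
  r <- (seq_len(grid_shape[1L]) - center[1L]) * pixel_spacing[1L]
  c <- (seq_len(grid_shape[2L]) - center[2L]) * pixel_spacing[2L]
  sqrt(outer(r^2, c^2, `+`))
}

#' Circular focus-exclusion mask
#'
#' TRUE within `factor` times the focal FWHM of the center; used to exclude
#' the focal region from background statistics.
#'
#' @param grid_shape Rows x cols.
#' @param pixel_spacing mm per voxel.
#' @param center Voxel (row, col).
#' @param fwhm_mm Focal FWHM in mm.
#' @param factor Exclusion radius in FWHM units (default 3).
#' @return Logical matrix.
#' @export
focus_exclusion_mask <- function(grid_shape, pixel_spacing, center,
                                 fwhm_mm, factor = 3) {
  radial_mm(grid_shape, pixel_spacing, center) <= factor * fwhm_mm
}

# AR(1) matrix of dimension (k x n): stationary N(0, sd^2) per entry,
# correlation rho between consecutive timepoints.
ar1_matrix <- function(k, n, sd, rho) {
  out <- matrix(0, k, n)
  if (sd <= 0) return(out)
  out[, 1L] <- stats::rnorm(k, 0, sd)
  if (n > 1L) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:n) out[, t] <- rho * out[, t - 1L] +
        stats::rnorm(k, 0, innov_sd)
  }
  out
}

make_baseline <- function(config) {
  gs <- config$grid_shape
  basis2 <- build_basis(gs, 2L)
  phase <- eval_phase(basis2, stats::rnorm(n_terms(basis2), 0, 0.3))
  amp <- config$baseline_amplitude
  if (config$baseline_kind == "disk") {
    extent <- min(gs * config$pixel_spacing)
    r <- radial_mm(gs, config$pixel_spacing, (gs + 1) / 2)
    edge <- 0.05 * extent
    mag <- amp * (0.01 + 0.99 * 0.5 * (1 - tanh((r - 0.42 * extent) / edge)))
  } else {
    smooth <- eval_phase(basis2, stats::rnorm(n_terms(basis2), 0, 1))
    smooth <- (smooth - min(smooth)) / max(1e-12, diff(range(smooth)))
    mag <- amp * (0.5 + 0.7 * smooth)
  }
  mag * exp(1i * phase)
}

#' Simulate an MR-ARFI image series with ground truth
#'
#' Builds the series through the same forward model the reconstruction
#' fits: per timepoint, baseline x exp(i[drift + sign x theta_true]) plus
#' complex Gaussian noise, where theta_true is the displacement-encoding
#' phase of a Gaussian focal displacement bump and drift combines
#' second-order polynomial and higher-order smooth fields, AR(1)-correlated
#' in time. For the epi4 schedule theta contributes only at
#' ultrasound-on timepoints. Bit-identical output for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param params An [acquisition_params()] (default: 40 mT/m, 7 ms MEG at
#'   0.65 MHz).
#' @return List with `series` (a [complex_image_series()]) and `truth`:
#'   `theta` (rad), `displacement_nm`, `drift` (num_voxels x Nt),
#'   `baseline`, `brain_mask`, `focus_exclusion`, `config`, `seed`.
#' @export
simulate_series <- function(config,
                            params = acquisition_params(40, 7, 0.65)) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$grid_shape
  Ns <- prod(gs)
  Nt <- config$n_timepoints
  schedule <- make_schedule(config$schedule_kind, Nt)
  s <- schedule_signs(schedule)
  fus <- as.numeric(attr(schedule, "fus"))

  with_seed(config$seed, {
    baseline <- make_baseline(config)

    d_m <- config$displacement_nm * 1e-9 *
      exp(-radial_mm(gs, config$pixel_spacing, config$focus_center)^2 /
            (2 * (config$focus_fwhm_mm / (2 * sqrt(2 * log(2))))^2))
    theta_true <- displacement_to_phase(d_m, params)

    basis2 <- build_basis(gs, 2L)
    drift <- basis2$design %*%
      ar1_matrix(n_terms(basis2), Nt, config$drift_poly_std, config$drift_ar1)
    if (config$drift_highorder_std > 0) {
      basis4 <- build_basis(gs, 4L)
      hi <- basis4$design %*% ar1_matrix(n_terms(basis4), Nt, 1,
                                         config$drift_ar1)
      hi <- hi - basis2$design %*% qr.coef(qr(basis2$design), hi)
      pooled <- stats::sd(as.vector(hi))
      if (pooled > 0)
        drift <- drift + hi * (config$drift_highorder_std / pooled)
    }

    Phi <- drift + outer(as.vector(theta_true), s * fus)
    X <- as.vector(baseline) * exp(1i * Phi)
    if (config$noise_std > 0)
      X <- X + complex(real = stats::rnorm(Ns * Nt, 0, config$noise_std),
                       imaginary = stats::rnorm(Ns * Nt, 0, config$noise_std))

    series <- complex_image_series(array(X, c(gs, Nt)), schedule, params,
                                   pixel_spacing = config$pixel_spacing)
    brain_mask <- Mod(baseline) > 0.5 * config$baseline_amplitude
    truth <- list(theta = theta_true, displacement_nm = d_m * 1e9,
                  drift = drift, baseline = baseline,
                  brain_mask = brain_mask,
                  focus_exclusion = focus_exclusion_mask(
                    gs, config$pixel_spacing, config$focus_center,
                    config$focus_fwhm_mm),
                  config = config, seed = config$seed)
    list(series = series, truth = truth)
  })
}
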