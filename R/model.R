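# Model-based displacement-map reconstruction.
#
# Each image timepoint n is modeled per voxel j as
#   I_n(x_j) = m_j * exp(i[ (A c_n)_j + (-1)^{1[n]} theta_j ]),
# where m is a complex baseline common to all timepoints, A c_n is a smooth
# per-timepoint polynomial phase error, and theta is the displacement phase,
# negated at timepoints whose trigger fired on the second MEG. Fitting
# minimizes
#   (1/Nt) sum_n sum_j |I_n - Ihat_n|^2 + lambda * sum_j |theta_j|
# with the analytic (closed-form) baseline substituted at every loss
# evaluation, so the optimizer only sees theta and the {c_n}.

#' Options for the model-based fit
#'
#' @param lambda_sparsity Sparsity penalty weight on |theta|. With
#'   `auto_scale_lambda = TRUE` this is a unit weight multiplied by the mean
#'   image magnitude at fit time (default 0.2, which reproduces the working
#'   weight 2000 at a mean amplitude of 1e4); with `auto_scale_lambda =
#'   FALSE` it is used as-is.
#' @param auto_scale_lambda Scale `lambda_sparsity` by the series' mean
#'   magnitude so the default is amplitude-invariant. Default TRUE.
#' @param max_iterations Maximum quasi-Newton iterations (default 200).
#' @param gradient_tolerance Convergence threshold on the projected gradient
#'   of the normalized loss (loss divided by the data energy). Default 1e-8.
#' @param l1_smoothing_eps Smoothing for |t| ~ sqrt(t^2 + eps), default 1e-8;
#'   results are insensitive to eps <= 1e-6.
#' @param history_size L-BFGS history length (default 10).
#' @param gauge_fix Transfer any polynomial-span content remaining in theta
#'   to the per-timepoint coefficients after optimization (an exact partial
#'   minimization over the model's flat direction; see Details). Default TRUE.
#' @param seed Optional integer; reserved for randomized restarts (the
#'   default fit is deterministic and uses no randomness).
#' @details The decomposition is invariant under
#'   (theta, c_n) -> (theta - A b, c_n + s_n b) for any coefficient vector b
#'   (s_n the contrast sign), so theta is determined only modulo the basis
#'   span when lambda = 0, and only weakly resolved by the penalty when
#'   lambda > 0. The final gauge step picks b minimizing the smoothed-L1
#'   norm of theta - A b, which never increases the loss and equals the
#'   lambda -> 0+ limit.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(lambda_sparsity = 0.2, auto_scale_lambda = TRUE,
                        max_iterations = 200L, gradient_tolerance = 1e-8,
                        l1_smoothing_eps = 1e-8, history_size = 10L,
                        gauge_fix = TRUE, seed = NULL) {
  if (lambda_sparsity < 0) stop_validation("lambda_sparsity must be >= 0")
  if (l1_smoothing_eps <= 0) stop_validation("l1_smoothing_eps must be > 0")
  structure(list(lambda_sparsity = lambda_sparsity,
                 auto_scale_lambda = isTRUE(auto_scale_lambda),
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 l1_smoothing_eps = l1_smoothing_eps,
                 history_size = as.integer(history_size),
                 gauge_fix = isTRUE(gauge_fix),
                 seed = seed),
            class = "fit_options")
}

smooth_abs <- function(t, eps) sqrt(t * t + eps)

effective_lambda <- function(series, options) {
  if (options$auto_scale_lambda)
    options$lambda_sparsity * mean(Mod(series$data))
  else options$lambda_sparsity
}

#' Predicted complex image for one timepoint
#'
#' Evaluates m_j * exp(i[(A c_n)_j + (-1)^indicator * theta_j]). The
#' predicted magnitude equals |baseline| exactly; the model only moves phase.
#'
#' @param baseline Complex matrix m (rows x cols).
#' @param coeffs_n Polynomial coefficient vector for this timepoint, rad.
#' @param theta Displacement phase matrix, rad.
#' @param indicator_n 0 (positive contrast) or 1 (negated contrast).
#' @param basis A [build_basis()] on the same grid.
#' @param fus_n Logical: is the ultrasound firing at this timepoint (theta
#'   contributes only if TRUE). Default TRUE.
#' @return Complex matrix of predicted values.
#' @export
forward_model <- function(baseline, coeffs_n, theta, indicator_n, basis,
                          fus_n = TRUE) {
  if (!identical(dim(baseline), basis$grid_shape) &&
      !identical(as.integer(dim(baseline)), basis$grid_shape))
    stop_validation("baseline shape does not match basis grid")
  if (!identical(as.integer(dim(theta)), basis$grid_shape))
    stop_validation("theta shape does not match basis grid")
  s <- if (indicator_n == 1) -1 else 1
  phase <- eval_phase(basis, coeffs_n) +
    (if (isTRUE(fus_n)) s * theta else 0 * theta)
  baseline * exp(1i * phase)
}

# Internal: data matrix (Ns x Nt), signs, fus flags.
series_matrix <- function(series) {
  d <- dim(series$data)
  matrix(series$data, d[1L] * d[2L], d[3L])
}

# Phase matrix (Ns x Nt) for coefficient matrix C (Nk x Nt) and theta vector.
phase_matrix <- function(basis, C, theta_vec, s, fus) {
  basis$design %*% C + outer(theta_vec, s * as.numeric(fus))
}

#' Model loss for an explicit baseline
#'
#' The mean (over timepoints) sum of squared complex residuals plus the
#' smoothed-L1 sparsity penalty on theta:
#' (1/Nt) sum_n sum_j |I_n - Ihat_n|^2 + lambda sum_j sqrt(theta_j^2 + eps).
#'
#' @param series A [complex_image_series()].
#' @param baseline Complex matrix m.
#' @param coeffs Matrix (n_terms x Nt) of polynomial coefficients, or a list
#'   of Nt coefficient vectors.
#' @param theta Displacement phase matrix, rad.
#' @param basis A [build_basis()] on the series grid.
#' @param options A [fit_options()]; supplies lambda (after auto-scaling)
#'   and the L1 smoothing epsilon.
#' @return Scalar loss (>= 0 up to the smoothing epsilon).
#' @export
arfi_loss <- function(series, baseline, coeffs, theta, basis,
                      options = fit_options()) {
  if (is.list(coeffs)) coeffs <- do.call(cbind, coeffs)
  Nt <- n_timepoints(series)
  if (ncol(coeffs) != Nt)
    stop_validation("coeffs must have one column per timepoint")
  X <- series_matrix(series)
  s <- schedule_signs(series$schedule)
  fus <- attr(series$schedule, "fus")
  Phi <- phase_matrix(basis, coeffs, as.vector(theta), s, fus)
  R <- X - as.vector(baseline) * exp(1i * Phi)
  lambda <- effective_lambda(series, options)
  sum(Mod(R)^2) / Nt +
    lambda * sum(smooth_abs(as.vector(theta), options$l1_smoothing_eps))
}

#' Closed-form optimal baseline image
#'
#' For fixed coefficients and theta, the complex baseline minimizing the
#' data term is the mean of the images over timepoints after removing the
#' polynomial and displacement phase from each:
#' m_j = (1/Nt) sum_n I_n(x_j) exp(-i[(A c_n)_j + (-1)^{1[n]} theta_j]).
#'
#' @inheritParams arfi_loss
#' @return Complex matrix m (rows x cols).
#' @export
analytic_baseline <- function(series, coeffs, theta, basis) {
  if (is.list(coeffs)) coeffs <- do.call(cbind, coeffs)
  Nt <- n_timepoints(series)
  if (ncol(coeffs) != Nt)
    stop_validation("coeffs must have one column per timepoint")
  X <- series_matrix(series)
  s <- schedule_signs(series$schedule)
  fus <- attr(series$schedule, "fus")
  Phi <- phase_matrix(basis, coeffs, as.vector(theta), s, fus)
  m <- rowMeans(X * exp(-1i * Phi))
  matrix(m, basis$grid_shape[1L], basis$grid_shape[2L])
}

# IRLS least-absolute-deviations fit of a voxel vector on the basis columns.
# Used for the gauge step; the smoothing scale sqrt(eps) must sit far below
# the phase amplitudes of interest (default 1e-8 rad) or the fit degrades to
# ordinary least squares on small fields.
lad_coeffs <- function(A, v, eps = 1e-16, max_iter = 60L, tol = 1e-12) {
  b <- qr.coef(qr(A), v)
  for (it in seq_len(max_iter)) {
    r <- v - A %*% b
    w <- 1 / smooth_abs(as.vector(r), eps)
    Aw <- A * w
    b_new <- solve(crossprod(Aw, A), crossprod(Aw, v))
    if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
      b <- b_new
      break
    }
    b <- b_new
  }
  as.vector(b)
}

#' Fit the displacement-phase model to an image series
#'
#' Jointly estimates the sparse displacement phase theta and the
#' per-timepoint polynomial phase-error coefficients by L-BFGS-B
#' quasi-Newton minimization of the penalized loss, substituting the
#' closed-form baseline [analytic_baseline()] at every evaluation. The
#' optimizer works on the loss normalized by the data energy so tolerances
#' are amplitude-invariant; gradients are analytic. Deterministic for
#' identical inputs and options.
#'
#' @param series A [complex_image_series()] whose schedule contains both
#'   contrasts.
#' @param basis A [build_basis()] on the series grid; default order 2.
#' @param options A [fit_options()].
#' @return An object of class `arfi_fit`: list with `theta` (rad, matrix),
#'   `coeffs` (n_terms x Nt), `baseline` (complex matrix), `loss_trace`
#'   (best loss after each objective evaluation; non-increasing), `loss`
#'   (final), `lambda` (effective, after auto-scaling), `converged`,
#'   `iterations`, `options`, and the series' grid metadata.
#' @examples
#' sim <- simulate_series(sim_config(grid_shape = c(16, 16), n_timepoints = 6,
#'                                   noise_std = 0, drift_poly_std = 0,
#'                                   drift_highorder_std = 0, seed = 1))
#' fit <- fit_arfi(sim$series, options = fit_options(lambda_sparsity = 0,
#'                                                   auto_scale_lambda = FALSE))
#' max(abs(fit$theta - sim$truth$theta))
#' @export
fit_arfi <- function(series, basis = NULL,
                     options = fit_options()) {
  stopifnot(inherits(series, "complex_image_series"))
  gs <- grid_shape(series)
  if (is.null(basis)) basis <- build_basis(gs, 2L)
  if (!identical(basis$grid_shape, as.integer(gs)))
    stop_validation("basis grid does not match series grid")
  ind <- unclass(series$schedule)
  if (all(ind == ind[1L]))
    stop_validation("constant schedule: displacement phase is unidentifiable")

  X <- series_matrix(series)
  Nt <- ncol(X)
  Ns <- nrow(X)
  A <- basis$design
  Nk <- ncol(A)
  s <- schedule_signs(series$schedule)
  fus <- as.numeric(attr(series$schedule, "fus"))
  sf <- s * fus
  lambda <- effective_lambda(series, options)
  eps <- options$l1_smoothing_eps
  data_energy <- sum(Mod(X)^2) / Nt
  scale <- max(data_energy, .Machine$double.xmin)

  # Diagonal preconditioner: the data-term curvature wrt theta_j scales with
  # the voxel's mean squared magnitude, and wrt c_k with its basis-weighted
  # sum. Optimizing in rescaled variables evens out bright vs. dim tissue,
  # which otherwise slows the quasi-Newton tail convergence badly. The floor
  # at 5% of the mean squared magnitude keeps noise-dominated (air) voxels
  # damped: their data term carries no phase information, and fully
  # equalizing their step scale would let theta fit noise there.
  msq_raw <- rowMeans(Mod(X)^2)
  msq <- pmax(msq_raw, 0.05 * mean(msq_raw))
  d_theta <- sqrt(2 * msq / scale)
  d_C <- sqrt(2 * as.vector(crossprod(A^2, msq)) / scale)
  dvec <- c(d_theta, rep(d_C, Nt))

  # Concentrated loss: substituting the analytic baseline reduces the data
  # term to (1/Nt) sum|X|^2 - sum_j |mhat_j|^2 with
  # mhat = rowMeans(X * exp(-i Phi)); its exact gradient wrt Phi is
  # G = -(2/Nt) Im(conj(mhat) * X * exp(-i Phi)).
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  evals <- numeric(0)

  compute <- function(par_scaled) {
    if (!is.null(cache$par) && identical(par_scaled, cache$par)) return()
    par <- par_scaled / dvec
    theta <- par[seq_len(Ns)]
    C <- matrix(par[-seq_len(Ns)], Nk, Nt)
    Phi <- A %*% C + outer(theta, sf)
    XE <- X * exp(-1i * Phi)
    mhat <- rowMeans(XE)
    # Residuals in the derotated domain: |X - mhat e^{i Phi}| = |XE - mhat|.
    # Evaluating the data term this way (rather than as
    # data_energy - sum |mhat|^2) avoids catastrophic cancellation when the
    # fit is nearly exact, which otherwise stalls the line search.
    R <- XE - mhat
    data_term <- sum(Re(R)^2 + Im(R)^2) / Nt
    pen <- lambda * sum(smooth_abs(theta, eps))
    G <- -(2 / Nt) * Im(Conj(mhat) * XE)
    g_theta <- as.vector(G %*% sf) + lambda * theta / smooth_abs(theta, eps)
    g_C <- crossprod(A, G)
    cache$par <- par_scaled
    cache$loss <- data_term + pen
    cache$grad <- c(g_theta, as.vector(g_C)) / dvec
    invisible()
  }
  fn <- function(par) {
    compute(par)
    evals[length(evals) + 1L] <<- cache$loss
    cache$loss / scale
  }
  gr <- function(par) {
    compute(par)
    cache$grad / scale
  }

  par0 <- numeric(Ns + Nk * Nt)
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = options$max_iterations,
                                     lmm = options$history_size,
                                     pgtol = options$gradient_tolerance,
                                     factr = 0))
  par <- res$par / dvec
  theta <- par[seq_len(Ns)]
  C <- matrix(par[-seq_len(Ns)], Nk, Nt)

  if (options$gauge_fix) {
    # Exact partial minimization over the flat direction
    # (theta, c_n) -> (theta - A b, c_n + s_n b): data term unchanged,
    # L1 penalty (lambda -> 0+ convention at lambda = 0) minimized over b.
    b <- lad_coeffs(A, theta)
    theta <- theta - as.vector(A %*% b)
    C <- C + outer(b, sf)
  }

  theta_mat <- matrix(theta, gs[1L], gs[2L])
  m <- analytic_baseline(series, C, theta_mat, basis)
  final_loss <- arfi_loss(series, m, C, theta_mat, basis,
                          fit_options(lambda_sparsity = lambda,
                                      auto_scale_lambda = FALSE,
                                      l1_smoothing_eps = eps))
  trace <- cummin(c(evals, final_loss))
  structure(list(theta = theta_mat, coeffs = C, baseline = m,
                 loss_trace = trace, loss = final_loss, lambda = lambda,
                 converged = res$convergence == 0L,
                 iterations = res$counts[["function"]],
                 options = options,
                 pixel_spacing = series$pixel_spacing,
                 schedule = series$schedule),
            class = "arfi_fit")
}

#' @export
print.arfi_fit <- function(x, ...) {
  cat(sprintf("arfi_fit: %d x %d grid, %d timepoints\n",
              nrow(x$theta), ncol(x$theta), ncol(x$coeffs)))
  cat(sprintf("  lambda = %.4g, loss = %.6g, converged = %s\n",
              x$lambda, x$loss, x$converged))
  cat(sprintf("  peak |theta| = %.4g rad\n", max(abs(x$theta))))
  invisible(x)
}

#' Convert a fitted displacement phase to a displacement map
#'
#' Applies theta / (2 pi 42.58 G T) with G in mT/m and T in ms, yielding
#' meters (e.g. theta = 0.015 rad with G = 40, T = 7 gives ~200 nm).
#'
#' @param result An `arfi_fit` from [fit_arfi()] (or any list with a
#'   `theta` matrix in radians).
#' @param params An [acquisition_params()].
#' @param mask Optional logical matrix.
#' @return A [displacement_map()] in meters.
#' @export
result_to_map <- function(result, params, mask = NULL) {
  values <- phase_to_displacement(result$theta, params)
  prov <- list(method = "model",
               lambda = result$lambda,
               converged = result$converged)
  displacement_map(values, mask = mask, provenance = prov,
                   pixel_spacing = if (!is.null(result$pixel_spacing))
                     result$pixel_spacing else c(1, 1))
}
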