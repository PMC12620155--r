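# Shared fixtures: tiny series built in code, plus a naive reference
# implementation of the model loss used as an independent oracle.

default_params <- function() acquisition_params(40, 7, 0.65)

# Random complex series with an alternating schedule on a small grid.
random_series <- function(rows = 8, cols = 8, nt = 4, seed = 1,
                          amplitude = 1, params = default_params()) {
  set.seed(seed)
  n <- rows * cols * nt
  data <- array(complex(real = rnorm(n, amplitude, 0.1 * amplitude),
                        imaginary = rnorm(n, 0, 0.1 * amplitude)),
                c(rows, cols, nt))
  complex_image_series(data, make_schedule("alternating", nt), params)
}

# Build a series exactly through the forward model (no noise).
model_series <- function(baseline, coeffs, theta, schedule, basis,
                         params = default_params()) {
  nt <- length(schedule)
  fus <- attr(schedule, "fus")
  data <- vapply(seq_len(nt), function(n)
    forward_model(baseline, coeffs[, n], theta, unclass(schedule)[n], basis,
                  fus_n = fus[n]),
    baseline)
  complex_image_series(data, schedule, params)
}

# Naive double-loop evaluation of the penalized loss; independent of the
# vectorized implementation.
naive_loss <- function(series, baseline, coeffs, theta, basis, lambda, eps) {
  ind <- unclass(series$schedule)
  fus <- attr(series$schedule, "fus")
  nt <- length(ind)
  gs <- dim(series$data)[1:2]
  total <- 0
  for (n in seq_len(nt)) {
    phase_n <- matrix(basis$design %*% coeffs[, n], gs[1], gs[2])
    s_n <- if (ind[n] == 1) -1 else 1
    for (r in seq_len(gs[1])) for (cc in seq_len(gs[2])) {
      ph <- phase_n[r, cc] +
        (if (fus[n]) s_n * theta[r, cc] else 0)
      pred <- baseline[r, cc] * exp(1i * ph)
      total <- total + Mod(series$data[r, cc, n] - pred)^2
    }
  }
  total / nt + lambda * sum(sqrt(theta^2 + eps))
}

lambda0_options <- function(...) {
  fit_options(lambda_sparsity = 0, auto_scale_lambda = FALSE, ...)
}
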