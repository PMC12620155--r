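test_that("forward model moves only phase, with the schedule's sign", {
  basis <- build_basis(c(6, 6), 2)
  m <- matrix(complex(modulus = 1:36, argument = seq(-3, 3, length.out = 36)),
              6, 6)
  theta <- matrix(0.02, 6, 6)
  zero_c <- rep(0, 6)

  expect_equal(forward_model(m, zero_c, 0 * theta, 0, basis), m)
  pos <- forward_model(m, zero_c, theta, 0, basis)
  neg <- forward_model(m, zero_c, theta, 1, basis)
  expect_equal(Mod(pos), Mod(m))
  expect_equal(Arg(pos * Conj(neg)), matrix(0.04, 6, 6))

  ones <- matrix(1 + 0i, 6, 6)
  out <- forward_model(ones, c(pi / 2, rep(0, 5)), 0 * theta, 0, basis)
  expect_equal(out, matrix(1i, 6, 6))
  expect_error(forward_model(m, zero_c, matrix(0, 3, 3), 0, basis), "shape")
})

test_that("loss matches an independently coded double-loop evaluation", {
  set.seed(11)
  basis <- build_basis(c(5, 4), 2)
  series <- random_series(5, 4, 6, seed = 11)
  m <- matrix(complex(real = rnorm(20), imaginary = rnorm(20)), 5, 4)
  coeffs <- matrix(rnorm(6 * 6, sd = 0.1), 6, 6)
  theta <- matrix(rnorm(20, sd = 0.02), 5, 4)
  opts <- fit_options(lambda_sparsity = 3, auto_scale_lambda = FALSE,
                      l1_smoothing_eps = 1e-8)
  expect_equal(arfi_loss(series, m, coeffs, theta, basis, opts),
               naive_loss(series, m, coeffs, theta, basis, 3, 1e-8))
})

test_that("loss vanishes on exact data and reduces to the penalty for sparse theta", {
  basis <- build_basis(c(6, 6), 2)
  sched <- make_schedule("alternating", 4)
  m <- matrix(1e4 + 0i, 6, 6) * exp(1i * eval_phase(basis, c(0.3, 0.1, -0.2,
                                                             0, 0, 0)))
  coeffs <- matrix(rnorm(24, sd = 0.1), 6, 4)
  theta0 <- matrix(0, 6, 6)
  s0 <- model_series(m, coeffs, theta0, sched, basis)
  opts <- fit_options(lambda_sparsity = 5, auto_scale_lambda = FALSE,
                      l1_smoothing_eps = 1e-12)
  expect_equal(arfi_loss(s0, m, coeffs, theta0, basis, opts),
               5 * sum(sqrt(theta0^2 + 1e-12)), tolerance = 1e-8)

  theta1 <- theta0; theta1[3, 4] <- 0.05
  s1 <- model_series(m, coeffs, theta1, sched, basis)
  l1 <- arfi_loss(s1, m, coeffs, theta1, basis, opts)
  expect_equal(l1, 5 * sum(sqrt(theta1^2 + 1e-12)), tolerance = 1e-6)
})

test_that("analytic baseline is the closed-form optimum of the data term", {
  basis <- build_basis(c(6, 6), 2)
  # all images equal m0, no phases: baseline is m0
  m0 <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  sched <- make_schedule("alternating", 4)
  s_const <- complex_image_series(array(rep(m0, 4), c(6, 6, 4)), sched,
                                  default_params())
  z <- matrix(0, 6, 6)
  expect_equal(analytic_baseline(s_const, matrix(0, 6, 4), z, basis), m0)

  # two timepoints at +t/-t with theta = t: phases removed before averaging
  t_field <- matrix(0.04, 6, 6)
  s_pm <- model_series(m0, matrix(0, 6, 2), t_field,
                       make_schedule("alternating", 2), basis)
  expect_equal(analytic_baseline(s_pm, matrix(0, 6, 2), t_field, basis), m0)

  # optimality oracle: random perturbations never beat the analytic solution
  set.seed(5)
  series <- random_series(6, 6, 4, seed = 5)
  coeffs <- matrix(rnorm(24, sd = 0.1), 6, 4)
  theta <- matrix(rnorm(36, sd = 0.02), 6, 6)
  opts0 <- lambda0_options()
  mhat <- analytic_baseline(series, coeffs, theta, basis)
  base_loss <- arfi_loss(series, mhat, coeffs, theta, basis, opts0)
  for (i in 1:100) {
    delta <- matrix(complex(real = rnorm(36, sd = 0.05),
                            imaginary = rnorm(36, sd = 0.05)), 6, 6)
    expect_gte(arfi_loss(series, mhat + delta, coeffs, theta, basis, opts0),
               base_loss * (1 - 1e-10))
  }
})

test_that("fit recovers a known sparse displacement phase exactly", {
  sim <- simulate_series(sim_config(grid_shape = c(20, 20), n_timepoints = 8,
                                    noise_std = 0, drift_poly_std = 0.05,
                                    drift_highorder_std = 0, seed = 21))
  fit <- fit_arfi(sim$series, options = lambda0_options())
  expect_lt(sqrt(mean((fit$theta - sim$truth$theta)^2)), 1e-4)
  expect_equal(max(fit$theta), max(sim$truth$theta), tolerance = 1e-2)
  expect_true(all(diff(fit$loss_trace) <= 1e-9))

  # zero displacement with pure polynomial drift leaves theta at zero
  sim0 <- simulate_series(sim_config(grid_shape = c(20, 20), n_timepoints = 8,
                                     noise_std = 0, displacement_nm = 0,
                                     drift_poly_std = 0.08,
                                     drift_highorder_std = 0, seed = 22))
  fit0 <- fit_arfi(sim0$series, options = lambda0_options())
  expect_lt(max(abs(fit0$theta)), 1e-3)
})

test_that("fit is deterministic and respects the model symmetries", {
  # all-bright baseline: air voxels carry no phase information, so their
  # fitted values converge too loosely to probe exact symmetries
  sim <- simulate_series(sim_config(grid_shape = c(16, 16), n_timepoints = 6,
                                    noise_std = 50, drift_highorder_std = 0,
                                    baseline_kind = "smooth_random",
                                    seed = 31))
  opts <- lambda0_options(gradient_tolerance = 1e-10, max_iterations = 500)
  fit1 <- fit_arfi(sim$series, options = opts)
  fit2 <- fit_arfi(sim$series, options = opts)
  expect_identical(fit1$theta, fit2$theta)

  # complementing the indicators negates theta
  flipped <- complex_image_series(
    sim$series$data,
    trigger_schedule(1L - unclass(sim$series$schedule)),
    sim$series$params)
  fit_f <- fit_arfi(flipped, options = opts)
  expect_lt(max(abs(fit_f$theta + fit1$theta)), 1e-6)

  # a global phase multiplies out: theta unchanged
  rotated <- complex_image_series(sim$series$data * exp(1i * 1.1),
                                  sim$series$schedule, sim$series$params)
  fit_r <- fit_arfi(rotated, options = opts)
  expect_lt(max(abs(fit_r$theta - fit1$theta)), 1e-6)

  const <- complex_image_series(sim$series$data,
                                structure(rep(0L, 6), fus = rep(TRUE, 6),
                                          class = "trigger_schedule"),
                                sim$series$params)
  expect_error(fit_arfi(const, options = opts), "unidentifiable")
})

test_that("the sparsity penalty shrinks the focal peak monotonically", {
  sim <- simulate_series(sim_config(grid_shape = c(16, 16), n_timepoints = 6,
                                    noise_std = 0, drift_poly_std = 0.03,
                                    drift_highorder_std = 0, seed = 41))
  # heavily penalized objectives converge slowly near the L1 kink, so give
  # the optimizer room
  peaks <- sapply(c(0, 10, 1e2, 1e3, 1e4), function(lam) {
    fit <- fit_arfi(sim$series,
                    options = fit_options(lambda_sparsity = lam,
                                          auto_scale_lambda = FALSE,
                                          max_iterations = 3000))
    max(abs(fit$theta))
  })
  expect_true(all(diff(peaks) <= 1e-6))
  expect_lt(peaks[5], peaks[1])
})

test_that("auto-scaled lambda reproduces the working value at amplitude 1e4", {
  s <- random_series(6, 6, 4, seed = 3, amplitude = 1e4)
  opts <- fit_options()                          # lambda 0.2, auto-scale
  expect_equal(arfimap:::effective_lambda(s, opts),
               0.2 * mean(Mod(s$data)))
  expect_equal(arfimap:::effective_lambda(s, opts) / 2000, 1,
               tolerance = 0.05)
})

test_that("theta converts to displacement with the 2*pi*42.58*G*T factor", {
  p <- default_params()
  res <- list(theta = matrix(c(0, 0.015), 1, 2))
  map <- result_to_map(res, p)
  expect_equal(map$values[1, 1], 0)
  expect_equal(map$values[1, 2], 2.0e-7, tolerance = 2e-3)
  map2 <- result_to_map(res, acquisition_params(80, 7, 0.65))
  expect_equal(map2$values[1, 2], map$values[1, 2] / 2)
})
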