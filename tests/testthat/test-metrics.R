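const_map <- function(nm, n = 6) {
  displacement_map(matrix(nm * 1e-9, n, n))
}

test_that("background statistics honor masks exactly", {
  m <- const_map(10)
  bs <- background_stats(m)
  expect_equal(bs$mean_nm, 10)
  expect_equal(bs$std_nm, 0)

  z <- const_map(0)
  expect_equal(background_stats(z)$mean_nm, 0)

  vals <- matrix(0, 4, 4); vals[1, 1] <- 1e-7
  m2 <- displacement_map(vals)
  excl <- matrix(FALSE, 4, 4); excl[1, 1] <- TRUE
  expect_equal(background_stats(m2, focus_exclusion = excl)$mean_nm, 0)
  expect_equal(background_stats(m2, focus_exclusion = excl)$n_voxels, 15)
  expect_error(background_stats(m2, brain_mask = matrix(FALSE, 4, 4)),
               "no voxels")
  expect_error(background_stats(m2, brain_mask = matrix(TRUE, 3, 3)),
               "grid")
})

test_that("subsampling keeps opposite-contrast pairs intact and in order", {
  sim <- simulate_series(sim_config(grid_shape = c(8, 8), n_timepoints = 12,
                                    seed = 4))
  s <- sim$series

  full <- subsample_averages(s, 6, seed = 1)      # all pairs, some order
  expect_equal(dim(full$data), dim(s$data))
  expect_identical(full$data, s$data)             # sorted selection = identity

  one <- subsample_averages(s, 1, seed = 2)
  expect_equal(dim(one$data)[3], 2L)
  expect_equal(sort(unclass(one$schedule)), c(0L, 1L))

  a <- subsample_averages(s, 3, seed = 5)
  b <- subsample_averages(s, 3, seed = 5)
  expect_identical(a$data, b$data)
  expect_error(subsample_averages(s, 7, seed = 1), "between 1 and 6")

  blocked <- simulate_series(sim_config(grid_shape = c(8, 8),
                                        n_timepoints = 12,
                                        schedule_kind = "blocked", seed = 4))
  expect_error(subsample_averages(blocked$series, 2, seed = 1),
               "alternating")
})

test_that("precision curve has the stated cardinality and improves with averages", {
  sim <- simulate_series(sim_config(grid_shape = c(16, 16), n_timepoints = 32,
                                    drift_poly_std = 0,
                                    drift_highorder_std = 0, seed = 6))
  tab <- precision_curve(sim$series, c(2, 8), n_repeats = 4, method = "roi",
                         brain_mask = sim$truth$brain_mask,
                         focus_exclusion = sim$truth$focus_exclusion,
                         roi = rect_roi(0, 4, 0, 4), seed = 3)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$n_averages), c(2, 8))
  agg <- tapply(tab$background_std_nm, tab$n_averages, mean)
  expect_lt(agg[["8"]], agg[["2"]])

  tab2 <- precision_curve(sim$series, c(2, 8), n_repeats = 4, method = "roi",
                          brain_mask = sim$truth$brain_mask,
                          focus_exclusion = sim$truth$focus_exclusion,
                          roi = rect_roi(0, 4, 0, 4), seed = 3)
  expect_identical(tab, tab2)
})

test_that("model backgrounds beat ROI backgrounds under drift", {
  wins <- 0L
  for (s in 1:4) {
    sim <- simulate_series(sim_config(grid_shape = c(16, 16),
                                      n_timepoints = 16, seed = 50 + s))
    bm <- sim$truth$brain_mask; fx <- sim$truth$focus_exclusion
    model_bs <- background_stats(
      result_to_map(fit_arfi(sim$series), sim$series$params), bm, fx)
    roi_bs <- background_stats(
      roi_corrected_map(sim$series, rect_roi(0, 4, 0, 4)), bm, fx)
    if (abs(model_bs$mean_nm) <= abs(roi_bs$mean_nm)) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("contrast-to-noise ratio is the peak over the background std", {
  vals <- matrix(rnorm(100, sd = 16e-9), 10, 10)
  vals[5, 5] <- 160e-9
  excl <- matrix(FALSE, 10, 10); excl[4:6, 4:6] <- TRUE
  m <- displacement_map(vals)
  bs <- background_stats(m, focus_exclusion = excl)
  expect_equal(cnr(m, c(5, 5), focus_exclusion = excl), 160 / bs$std_nm)

  vals0 <- vals; vals0[5, 5] <- 0
  expect_equal(cnr(displacement_map(vals0), c(5, 5), focus_exclusion = excl),
               0)
  expect_error(cnr(const_map(1), c(2, 2)), "zero")
  expect_error(cnr(m, c(11, 2)), "inside")
})
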