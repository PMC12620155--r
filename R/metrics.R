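# Evaluation metrics: out-of-focus background statistics, random-average
# subsampling, precision-vs-averages tables, and contrast-to-noise ratio.

#' Out-of-focus background statistics of a displacement map
#'
#' Mean and standard deviation of displacement (nm) over voxels inside the
#' brain mask and outside the focus-exclusion zone (and inside the map's own
#' mask).
#'
#' @param map A [displacement_map()].
#' @param brain_mask Optional logical matrix; default all TRUE.
#' @param focus_exclusion Optional logical matrix marking the focal zone to
#'   exclude; default none.
#' @return List with `mean_nm`, `std_nm`, `n_voxels`.
#' @export
background_stats <- function(map, brain_mask = NULL, focus_exclusion = NULL) {
  stopifnot(inherits(map, "displacement_map"))
  inc <- map$mask
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(map$values)))
      stop_validation("brain_mask grid does not match the map")
    inc <- inc & brain_mask
  }
  if (!is.null(focus_exclusion)) {
    if (!identical(dim(focus_exclusion), dim(map$values)))
      stop_validation("focus_exclusion grid does not match the map")
    inc <- inc & !focus_exclusion
  }
  if (!any(inc))
    stop_validation("no voxels left after masking")
  v <- map$values[inc] * 1e9
  list(mean_nm = mean(v),
       std_nm = if (length(v) > 1L) stats::sd(v) else 0,
       n_voxels = sum(inc))
}

# Consecutive opposite-contrast pairs of an alternating schedule, or
# four-image cycles of an epi4 schedule. Returns a list of timepoint index
# vectors, one per average.
series_averages <- function(series) {
  ind <- unclass(series$schedule)
  Nt <- length(ind)
  if (Nt %% 4L == 0L && all(ind == rep(c(0L, 0L, 1L, 1L), Nt / 4L)) &&
      !all(attr(series$schedule, "fus")))
    return(lapply(seq(1L, Nt, by = 4L), function(k) k + 0:3))
  if (Nt %% 2L != 0L || !all(ind == rep_len(c(0L, 1L), Nt)))
    stop_validation("subsampling requires an alternating (or epi4) schedule")
  lapply(seq(1L, Nt, by = 2L), function(k) k + 0:1)
}

#' Randomly subsample complete averages from a series
#'
#' Selects `n_averages` consecutive opposite-contrast timepoint pairs
#' (four-image cycles for an epi4 series) uniformly at random without
#' replacement, keeping the selected averages in chronological order so the
#' schedule stays consistent.
#'
#' @param series A [complex_image_series()] with an alternating (or epi4)
#'   schedule.
#' @param n_averages Number of averages to keep (>= 1, <= available).
#' @param seed Integer seed; the selection is identical across runs for a
#'   fixed seed.
#' @return A shorter [complex_image_series()].
#' @export
subsample_averages <- function(series, n_averages, seed) {
  avgs <- series_averages(series)
  n_averages <- as.integer(n_averages)
  if (n_averages < 1L || n_averages > length(avgs))
    stop_validation("n_averages must be between 1 and ", length(avgs))
  keep <- with_seed(seed, sort(sample.int(length(avgs), n_averages)))
  tp <- unlist(avgs[keep])
  ind <- unclass(series$schedule)[tp]
  fus <- attr(series$schedule, "fus")[tp]
  complex_image_series(series$data[, , tp, drop = FALSE],
                       trigger_schedule(ind, fus = fus), series$params,
                       pixel_spacing = series$pixel_spacing,
                       origin = series$origin)
}

fit_map_by_method <- function(series, method, roi = NULL,
                              options = fit_options()) {
  switch(method,
    model = result_to_map(fit_arfi(series, options = options),
                          series$params),
    roi = {
      if (is.null(roi))
        stop_validation("method 'roi' requires an roi")
      roi_corrected_map(series, roi)
    },
    epi4 = epi_style_map(series),
    stop_validation("unknown method: ", method))
}

#' Precision vs. number of averages
#'
#' For each requested number of averages and each repeat, draws a random
#' subsample of complete averages, recomputes the displacement map with the
#' chosen estimator, and records out-of-focus background statistics. Per-cell
#' seeds are derived deterministically from the root seed as
#' `seed + 7919 * cell_index` (cells enumerated row-major over
#' averages x repeats), so the whole table is reproducible.
#'
#' @param series A [complex_image_series()] with an alternating (or epi4)
#'   schedule.
#' @param n_averages_list Integer vector of average counts.
#' @param n_repeats Repeats per count (default 10).
#' @param method One of "model", "roi", "epi4".
#' @param brain_mask,focus_exclusion Masks passed to [background_stats()].
#' @param roi A [rect_roi()], required for method "roi".
#' @param options [fit_options()] for method "model".
#' @param seed Root seed.
#' @return A data.frame with columns `n_averages`, `repeat_index`, `method`,
#'   `background_mean_nm`, `background_std_nm`.
#' @export
precision_curve <- function(series, n_averages_list, n_repeats = 10L,
                            method = c("model", "roi", "epi4"),
                            brain_mask = NULL, focus_exclusion = NULL,
                            roi = NULL, options = fit_options(), seed = 1L) {
  method <- match.arg(method)
  cells <- expand.grid(repeat_index = seq_len(n_repeats),
                       n_averages = as.integer(n_averages_list))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell_seed <- as.integer(seed) + 7919L * i
    sub <- subsample_averages(series, cells$n_averages[i], cell_seed)
    map <- fit_map_by_method(sub, method, roi = roi, options = options)
    bs <- background_stats(map, brain_mask, focus_exclusion)
    data.frame(n_averages = cells$n_averages[i],
               repeat_index = cells$repeat_index[i],
               method = method,
               background_mean_nm = bs$mean_nm,
               background_std_nm = bs$std_nm)
  })
  do.call(rbind, rows)
}

#' Contrast-to-noise ratio of a displacement map
#'
#' Map value at the focal peak voxel divided by the out-of-focus background
#' standard deviation.
#'
#' @param map A [displacement_map()].
#' @param focus_peak_voxel Integer (row, col), 1-based, inside the grid.
#' @param brain_mask,focus_exclusion Masks for [background_stats()].
#' @return Unitless CNR.
#' @export
cnr <- function(map, focus_peak_voxel, brain_mask = NULL,
                focus_exclusion = NULL) {
  pv <- as.integer(focus_peak_voxel)
  if (length(pv) != 2L || any(pv < 1L) || any(pv > dim(map$values)))
    stop_validation("focus_peak_voxel must be a (row, col) inside the grid")
  bs <- background_stats(map, brain_mask, focus_exclusion)
  if (bs$std_nm == 0)
    stop_validation("background standard deviation is zero")
  map$values[pv[1L], pv[2L]] * 1e9 / bs$std_nm
}
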