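# NIfTI + JSON-sidecar I/O. A series is stored as two 3D volumes
# (row x col x time; time is the slowest axis): `<base>_mag.nii.gz` holding
# magnitude and `<base>_pha.nii.gz` holding phase in radians in (-pi, pi],
# plus `<base>.json` holding the trigger indicators and acquisition
# parameters (units: mT/m, ms, MHz, MPa). Volumes are written as doubles so
# the stored magnitude/phase representation round-trips exactly.

series_paths <- function(base) {
  base <- sub("\\.nii(\\.gz)?$", "", base)
  list(mag = paste0(base, "_mag.nii.gz"),
       pha = paste0(base, "_pha.nii.gz"),
       sidecar = paste0(base, ".json"))
}

write_volume <- function(arr, path, pixel_spacing) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- c(pixel_spacing, rep(1, length(dim(arr)) - 2L))
  RNifti::writeNifti(im, path, datatype = "double")
}

#' Write a complex image series to NIfTI + JSON sidecar
#'
#' Emits `<base>_mag.nii.gz`, `<base>_pha.nii.gz` (phase in radians) and
#' `<base>.json` (indicators + acquisition parameters). Deterministic for
#' identical input; round-trips through [read_series()] exactly.
#'
#' @param series A [complex_image_series()].
#' @param base Output path base (any `.nii`/`.nii.gz` extension is
#'   stripped).
#' @param sidecar_path Optional sidecar path (default `<base>.json`).
#' @return Invisibly, the list of written paths.
#' @export
write_series <- function(series, base, sidecar_path = NULL) {
  stopifnot(inherits(series, "complex_image_series"))
  p <- series_paths(base)
  if (!is.null(sidecar_path)) p$sidecar <- sidecar_path
  write_volume(Mod(series$data), p$mag, series$pixel_spacing)
  write_volume(Arg(series$data), p$pha, series$pixel_spacing)
  side <- list(meg_amplitude = series$params$meg_amplitude,
               meg_duration = series$params$meg_duration,
               us_frequency = series$params$us_frequency,
               indicators = as.integer(unclass(series$schedule)),
               pixel_spacing = series$pixel_spacing,
               origin = series$origin)
  if (!is.null(series$params$free_field_pressure))
    side$free_field_pressure <- series$params$free_field_pressure
  if (!is.null(series$params$skull_transmission))
    side$skull_transmission <- series$params$skull_transmission
  fus <- attr(series$schedule, "fus")
  if (!all(fus)) side$fus <- fus
  jsonlite::write_json(side, p$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

require_keys <- function(side, keys, path) {
  missing <- setdiff(keys, names(side))
  if (length(missing))
    stop_validation("sidecar ", path, " is missing required key(s): ",
                    paste(missing, collapse = ", "))
}

#' Read a complex image series from NIfTI + JSON sidecar
#'
#' Expects the layout written by [write_series()]: magnitude and phase
#' volumes plus a sidecar with `indicators`, `meg_amplitude`,
#' `meg_duration`, and `us_frequency`.
#'
#' @param base Path base of the series (extension stripped).
#' @param sidecar_path Optional sidecar path (default `<base>.json`).
#' @return A [complex_image_series()].
#' @export
read_series <- function(base, sidecar_path = NULL) {
  p <- series_paths(base)
  if (!is.null(sidecar_path)) p$sidecar <- sidecar_path
  for (f in c(p$mag, p$pha, p$sidecar))
    if (!file.exists(f))
      stop("cannot read series: missing file ", f, call. = FALSE)
  side <- jsonlite::read_json(p$sidecar, simplifyVector = TRUE)
  require_keys(side, c("meg_amplitude", "meg_duration", "us_frequency",
                       "indicators"), p$sidecar)
  read_volume <- function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim(v))
  }
  mag <- read_volume(p$mag)
  pha <- read_volume(p$pha)
  if (!identical(dim(mag), dim(pha)))
    stop_validation("magnitude and phase volumes have different shapes")
  params <- acquisition_params(side$meg_amplitude, side$meg_duration,
                               side$us_frequency,
                               free_field_pressure = side$free_field_pressure,
                               skull_transmission = side$skull_transmission)
  if (length(side$indicators) != dim(mag)[3L])
    stop_validation("sidecar indicators length (", length(side$indicators),
                    ") does not match timepoints (", dim(mag)[3L], ")")
  schedule <- trigger_schedule(side$indicators,
                               fus = if (!is.null(side$fus))
                                 as.logical(side$fus) else NULL)
  spacing <- if (!is.null(side$pixel_spacing)) side$pixel_spacing else c(1, 1)
  origin <- if (!is.null(side$origin)) side$origin else c(0, 0)
  complex_image_series(mag * exp(1i * pha), schedule, params,
                       pixel_spacing = spacing, origin = origin)
}

map_paths <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  list(vol = paste0(base, ".nii.gz"), sidecar = paste0(base, ".json"))
}

#' Write a displacement map to NIfTI (nanometers)
#'
#' A single volume in nanometers; voxels outside the mask are written as
#' NaN. Provenance goes into a JSON sidecar next to the volume.
#'
#' @param map A [displacement_map()].
#' @param path Output path (`.nii.gz` appended if missing).
#' @return Invisibly, the written paths.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "displacement_map"))
  p <- map_paths(path)
  vol <- map$values * 1e9
  vol[!map$mask] <- NaN
  write_volume(vol, p$vol, map$pixel_spacing)
  jsonlite::write_json(list(units = "nm", provenance = map$provenance,
                            pixel_spacing = map$pixel_spacing),
                       p$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

#' Read a displacement map written by [write_map()]
#'
#' @param path Path to the map volume.
#' @return A [displacement_map()] (NaN voxels become the mask).
#' @export
read_map <- function(path) {
  p <- map_paths(path)
  if (!file.exists(p$vol))
    stop("cannot read map: missing file ", p$vol, call. = FALSE)
  vol <- RNifti::readNifti(p$vol)
  values <- matrix(as.numeric(vol), dim(vol)[1L], dim(vol)[2L])
  mask <- is.finite(values)
  values[!mask] <- 0
  side <- if (file.exists(p$sidecar))
    jsonlite::read_json(p$sidecar, simplifyVector = TRUE) else list()
  displacement_map(values * 1e-9, mask = mask,
                   provenance = if (!is.null(side$provenance))
                     side$provenance else list(),
                   pixel_spacing = if (!is.null(side$pixel_spacing))
                     side$pixel_spacing else c(1, 1))
}
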