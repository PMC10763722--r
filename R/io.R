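# Format readers/writers: profile CSV, lane CSV, measurement CSV and the
# YAML pipeline configuration. Every writer emits a header and round-trips
# through its reader.

#' Write a two-channel intensity profile to CSV
#'
#' Columns: \code{position_nm}, then one intensity column per channel
#' (\code{mir_intensity}, \code{a170_intensity} for the standard channels).
#'
#' @param profile an [IntensityProfile-class].
#' @param path output CSV path.
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "IntensityProfile"))
  d <- data.frame(position_nm = profile@positionsNm)
  for (ch in names(profile@channels))
    d[[paste0(ch, "_intensity")]] <- profile@channels[[ch]]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-channel intensity profile from CSV
#'
#' @param path CSV with \code{position_nm} and \code{*_intensity} columns.
#' @return an [IntensityProfile-class].
#' @export
readProfileCsv <- function(path) {
  d <- utils::read.csv(path)
  if (!"position_nm" %in% names(d))
    stop("profile CSV must have a position_nm column")
  chCols <- grep("_intensity$", names(d), value = TRUE)
  if (!length(chCols))
    stop("profile CSV must have at least one *_intensity column")
  channels <- lapply(chCols, function(cc) d[[cc]])
  names(channels) <- sub("_intensity$", "", chCols)
  new("IntensityProfile", positionsNm = d$position_nm, channels = channels,
      metadata = list(pixel_nm = diff(d$position_nm[1:2]), source = path))
}

#' Write a gel lane trace to CSV (migration_mm, od)
#' @param lane a [GelLaneProfile-class].
#' @param path output CSV path.
#' @export
writeLaneCsv <- function(lane, path) {
  stopifnot(is(lane, "GelLaneProfile"))
  utils::write.csv(data.frame(migration_mm = lane@migrationMm,
                              od = lane@od), path, row.names = FALSE)
  invisible(path)
}

#' Read a gel lane trace from CSV
#' @param path CSV with columns \code{migration_mm} and \code{od}.
#' @param laneId lane identifier (default: file name).
#' @return a [GelLaneProfile-class].
#' @export
readLaneCsv <- function(path, laneId = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("migration_mm", "od") %in% names(d)))
    stop("lane CSV must have columns migration_mm and od")
  new("GelLaneProfile", migrationMm = d$migration_mm, od = d$od,
      laneId = laneId)
}

#' Write a per-sarcomere measurement table to CSV
#'
#' One row per sarcomere; distances in nm, sarcomere length also in um.
#'
#' @param measurements data.frame from [profileDataset()].
#' @param path output CSV path.
#' @export
writeMeasurementsCsv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-sarcomere measurement table from CSV
#' @param path CSV written by [writeMeasurementsCsv()].
#' @export
readMeasurementsCsv <- function(path) utils::read.csv(path)

#' Default pipeline configuration
#'
#' Nested list of every tunable of the simulation-analysis pipeline, with
#' defaults equal to the package's module defaults. Round-trips losslessly
#' through YAML ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param seed master seed; all stages derive child seeds deterministically.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = lapply(.GENOTYPE_DEFAULTS, function(p) p),
    simulation = list(
      sl_series_um = c(1.8, 2.0, 2.2, 2.4, 2.6),
      n_profiles_per_sl = 8L,
      n_sarcomeres = 4L,
      n_titin_per_half = 6L,
      psf_fwhm_nm = 40,
      pixel_nm = 10,
      jitter_sd_nm = 15,
      peak_photon_count = 400,
      labeling_efficiency = 1.0),
    fit = list(
      prominence_k = 3,
      min_prominence_frac = 0.08,
      fwhm_guess_nm = 45,
      doublet_window_nm = c(60, 260),
      qc_threshold = 0.20),
    densitometry = list(
      n_lanes = 10L,
      band_width_mm = 0.4,
      noise_sd = 0.002,
      quantity_cv = 0.05,
      trunc_over_t1 = 0.19,
      calibration = c(150, -38)),
    stats = list(alpha = 0.05, sl_range_um = c(1.8, 2.6)))
}

#' Write a pipeline configuration to YAML
#' @param config configuration list.
#' @param path output YAML path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)
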