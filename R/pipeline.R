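# End-to-end pipeline: simulate (or ingest) -> profile -> QC -> metrics ->
# statistics -> report.

.genotypeFromConfig <- function(config, label) {
  p <- config$geometry[[label]]
  do.call(genotypeParams, c(list(label = label), p))
}

.stedParamsFromConfig <- function(config, label, seed) {
  s <- config$simulation
  stedSimParams(
    genotype = .genotypeFromConfig(config, label),
    slUm = s$sl_series_um[1L],
    nSarcomeres = s$n_sarcomeres, nTitinPerHalf = s$n_titin_per_half,
    psfFwhmNm = s$psf_fwhm_nm, pixelNm = s$pixel_nm,
    jitterSdNm = s$jitter_sd_nm, peakPhotonCount = s$peak_photon_count,
    labelingEfficiency = s$labeling_efficiency, seed = seed)
}

.fitSettingsFromConfig <- function(config) {
  f <- config$fit
  fitSettings(prominenceK = f$prominence_k,
              minProminenceFrac = f$min_prominence_frac,
              fwhmGuessNm = f$fwhm_guess_nm,
              doubletWindowNm = f$doublet_window_nm,
              qcThreshold = f$qc_threshold)
}

#' Run the full simulation-analysis pipeline
#'
#' Simulates TTNtv- and TTNtv+ stretch series, runs the epitope profiler
#' and QC, fits the sarcomere-length regressions of the A-band titin length
#' and the M-to-TK distance, compares slopes between genotypes, summarises
#' the A170/MIR intensity ratios, quantifies simulated TTNtv+ gel lanes,
#' and summarises the packaged synthetic cohort. Idempotent for a fixed
#' configuration: child seeds derive from \code{config$seed}.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outdir optional output directory; when given, the JSON report,
#'   the measurement CSV and the configuration YAML are written there.
#' @return report list (regressions, slope comparisons, intensity ratios,
#'   densitometry ratios, cohort summary, QC accounting, provenance).
#' @export
runEndToEnd <- function(config = defaultPipelineConfig(), outdir = NULL) {
  s <- config$simulation
  fitCfg <- .fitSettingsFromConfig(config)

  measurements <- list()
  for (label in c("TTNTV_NEG", "TTNTV_POS")) {
    seedOff <- if (label == "TTNTV_NEG") 1000L else 2000L
    params <- .stedParamsFromConfig(config, label, config$seed + seedOff)
    sims <- simulateStretchSeries(params, s$sl_series_um, s$n_profiles_per_sl)
    m <- profileDataset(sims, fitCfg)
    measurements[[label]] <- m
  }
  meas <- do.call(rbind, measurements)
  rownames(meas) <- NULL

  slr <- config$stats$sl_range_um
  # stage guard: insufficient data (e.g. a QC threshold of 0 discarding
  # every sarcomere) is reported, not fatal
  safely <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  regress <- list(); slopes <- list()
  for (metric in c("aband_titin_len_nm", "dtk_nm")) {
    fits <- lapply(names(measurements), function(label)
      safely(fitLengthRegression(measurements[[label]], metric,
                                 slRangeUm = slr, group = label)))
    names(fits) <- names(measurements)
    regress[[metric]] <- lapply(fits, function(f)
      if (!is.null(f$error)) f else
        f[c("slope", "se_slope", "intercept_at_slack", "se_intercept", "n")])
    slopes[[metric]] <- safely({
      cs <- compareSlopes(fits$TTNTV_NEG, fits$TTNTV_POS)
      cs[c("delta_slope", "se_delta_slope", "p_value",
           "delta_intercept_at_slack")]
    })
  }

  qcPassed <- if (nrow(meas) && "qc_pass" %in% names(meas))
    meas[meas$qc_pass, , drop = FALSE] else meas
  ratioByGroup <- if (nrow(qcPassed))
    tapply(qcPassed$a170_over_mir_intensity, qcPassed$genotype, mean) else
    numeric()
  ratioSummary <- if (all(c("TTNTV_NEG", "TTNTV_POS") %in%
                          names(ratioByGroup)))
    intensityRatioSummary(ratioByGroup[["TTNTV_POS"]],
                          ratioByGroup[["TTNTV_NEG"]]) else NULL

  d <- config$densitometry
  gel <- gelSimParams(
    bands = defaultGelComposition("TTNTV_POS", truncOverT1 = d$trunc_over_t1),
    calibration = d$calibration, bandWidthMm = d$band_width_mm,
    noiseSd = d$noise_sd, quantityCv = d$quantity_cv,
    seed = config$seed + 3000L)
  cal <- calibrateMobility(data.frame(
    mw_kda = c(4000, 2000, 1000, 500, 250),
    migration_mm = d$calibration[1L] +
      d$calibration[2L] * log10(c(4000, 2000, 1000, 500, 250))))
  predicted <- defaultGelComposition("TTNTV_POS")
  predictedTrunc <- predicted$mw_kda[predicted$label == "truncated"]
  truncRatios <- vapply(seq_len(d$n_lanes), function(i) {
    g <- gel; g$seed <- gel$seed + i
    sim <- simulateGelLane(g, laneId = paste0("lane", i))
    bands <- quantifyLane(sim$lane, cal)
    bands <- identifyTruncatedBand(bands, predictedTrunc)
    computeTitinRatios(bands)$trunc_over_t1
  }, 0)

  cohort <- summarizeCohort(loadVariantTable(syntheticCohortPath()),
                            model = titinIsoformModel())

  report <- list(
    provenance = list(package = "TitinScope",
                      version = as.character(utils::packageVersion("TitinScope")),
                      seed = config$seed,
                      timestamp = format(Sys.time(), tz = "UTC")),
    qc = list(n_measured = nrow(meas), n_qc_passed = nrow(qcPassed),
              n_discarded = nrow(meas) - nrow(qcPassed),
              discard_reasons = if (nrow(meas))
                table(meas$qc_reasons[!meas$qc_pass]) else table(character())),
    regressions = regress,
    slope_comparisons = slopes,
    intensity = list(mean_ratio_by_group = as.list(ratioByGroup),
                     contrast = ratioSummary),
    densitometry = list(mean_trunc_over_t1 = mean(truncRatios),
                        se_trunc_over_t1 = stats::sd(truncRatios) /
                          sqrt(length(truncRatios)),
                        n_lanes = d$n_lanes),
    cohort = unclass(cohort)[c("n_samples", "n_ttntv_pos", "pct_ttntv",
                               "n_dcm_gene_pos", "pct_dcm_gene",
                               "consequence_counts")])

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeMeasurementsCsv(meas, file.path(outdir, "measurements.csv"))
    writePipelineConfig(config, file.path(outdir, "config.yaml"))
    rep2 <- report
    rep2$qc$discard_reasons <- as.list(rep2$qc$discard_reasons)
    jsonlite::write_json(rep2, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
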