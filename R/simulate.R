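# Seeded generators of STED-like two-channel sarcomere profiles and of
# SDS-agarose gel lane traces, with full ground truth recorded so every
# downstream stage can be tested against known generative values.

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Simulation parameters for STED-like sarcomere profiles
#'
#' @param genotype genotype label or a [GenotypeParams-class] object.
#' @param slUm sarcomere length in um (scalar here; see
#'   [simulateStretchSeries()] for series).
#' @param nSarcomeres sarcomeres rendered per profile (>= 3; default 4).
#' @param nTitinPerHalf titin molecules per half thick filament (default 6).
#' @param psfFwhmNm axial PSF full width at half maximum (default 40 nm, the
#'   tested STED resolution).
#' @param pixelNm grid spacing (default 10 nm; must be <= psfFwhmNm/2).
#' @param jitterSdNm per-fluorophore axial registration jitter SD
#'   (default 15 nm).
#' @param peakPhotonCount expected peak photon count of a fully labeled,
#'   perfectly registered band (default 400); Poisson noise is applied at
#'   this scale. Set to 0 to disable noise.
#' @param labelingEfficiency per-fluorophore labeling probability per
#'   channel (default 1).
#' @param seed integer RNG seed.
#' @return validated parameter list of class \code{stedSimParams}.
#' @export
stedSimParams <- function(genotype = "TTNTV_NEG", slUm = 1.8,
                          nSarcomeres = 4L, nTitinPerHalf = 6L,
                          psfFwhmNm = 40, pixelNm = 10,
                          jitterSdNm = 15, peakPhotonCount = 400,
                          labelingEfficiency = 1, seed = 1L) {
  if (is.character(genotype)) genotype <- genotypeParams(genotype)
  stopifnot(is(genotype, "GenotypeParams"))
  if (psfFwhmNm <= 0) stop("psfFwhmNm must be positive")
  if (pixelNm > psfFwhmNm / 2)
    stop("pixelNm must be <= psfFwhmNm/2 (Nyquist-safe sampling)")
  if (nSarcomeres < 3L) stop("nSarcomeres must be >= 3")
  if (nTitinPerHalf < 1L) stop("nTitinPerHalf must be >= 1")
  if (labelingEfficiency < 0 || labelingEfficiency > 1)
    stop("labelingEfficiency must lie in [0, 1]")
  structure(list(
    genotype = genotype, slUm = slUm,
    nSarcomeres = as.integer(nSarcomeres),
    nTitinPerHalf = as.integer(nTitinPerHalf),
    psfFwhmNm = psfFwhmNm, pixelNm = pixelNm,
    jitterSdNm = jitterSdNm, peakPhotonCount = peakPhotonCount,
    labelingEfficiency = labelingEfficiency, seed = as.integer(seed)
  ), class = "stedSimParams")
}

# Expected fluorophore emplacements of one simulated myofibril stretch:
# sarcomeres k = 0 .. n+1 are populated (k = 0 and n+1 are the flanking
# neighbors whose bands spill into the half-sarcomere margins).
.placeFluorophores <- function(params) {
  g <- params$genotype
  slNm <- params$slUm * 1000
  rows <- list()
  for (k in 0:(params$nSarcomeres + 1L)) {
    lay <- expectedPositions(g, params$slUm, originNm = (k - 1L) * slNm)
    for (side in 1:2) {  # left/right half-sarcomere
      truncated <- stats::runif(params$nTitinPerHalf) < g@truncFraction
      shift <- truncMirShiftAt(g, params$slUm)
      mirBase <- lay@mirFullNm[side]
      zdir <- if (side == 1L) -1 else 1  # Z-ward direction on this side
      mirPos <- mirBase + ifelse(truncated, zdir * shift, 0)
      a170Pos <- rep(lay@a170PositionsNm[side], params$nTitinPerHalf)
      rows[[length(rows) + 1L]] <- data.frame(
        sarcomere = k, half = side, molecule = seq_len(params$nTitinPerHalf),
        truncated = truncated, mir_nm = mirPos, a170_nm = a170Pos)
    }
  }
  do.call(rbind, rows)
}

# Render a set of fluorophores (positions nm, amplitudes) as a PSF-convolved
# expected-photon profile on the pixel grid.
.renderKernels <- function(gridNm, positions, amplitude, sigmaNm) {
  if (!length(positions)) return(numeric(length(gridNm)))
  out <- numeric(length(gridNm))
  for (p in positions)
    out <- out + amplitude * exp(-(gridNm - p)^2 / (2 * sigmaNm^2))
  out
}

#' Simulate one STED-like two-channel sarcomere line profile
#'
#' For each half-sarcomere, \code{nTitinPerHalf} titin molecules are drawn;
#' a Bernoulli(\code{truncFraction}) subset is truncated (no A170
#' fluorophore; MIR displaced Z-ward per the geometry model). Every retained
#' fluorophore is jittered by Normal(0, \code{jitterSdNm}), rendered as a
#' Gaussian PSF on the pixel grid, and Poisson noise is applied at the
#' configured photon scale. The profile spans the central sarcomeres plus a
#' half-sarcomere margin on each side (flanking bands are rendered so edge
#' effects are realistic). Fully reproducible from the seed.
#'
#' @param params a [stedSimParams()] list.
#' @return list with elements \code{profile} (an [IntensityProfile-class]
#'   with channels \code{mir} and \code{a170}) and \code{truth} (ground
#'   truth: per-sarcomere [EpitopeLayout-class]s, the fluorophore table,
#'   per-channel noiseless expectation, and the generative metric values).
#' @export
simulateProfile <- function(params) {
  stopifnot(inherits(params, "stedSimParams"))
  set.seed(params$seed)
  g <- params$genotype
  slNm <- params$slUm * 1000
  n <- params$nSarcomeres
  gridNm <- seq(-slNm / 2, n * slNm + slNm / 2, by = params$pixelNm)
  sigma <- params$psfFwhmNm * .FWHM_TO_SIGMA
  ampPerFluor <- params$peakPhotonCount / params$nTitinPerHalf
  if (params$peakPhotonCount == 0) ampPerFluor <- 100 / params$nTitinPerHalf

  fl <- .placeFluorophores(params)
  # per-fluorophore labeling and jitter, independently per channel
  fl$mir_labeled <- stats::runif(nrow(fl)) < params$labelingEfficiency
  fl$a170_labeled <- (stats::runif(nrow(fl)) < params$labelingEfficiency) &
    !fl$truncated
  fl$mir_obs_nm <- fl$mir_nm + stats::rnorm(nrow(fl), 0, params$jitterSdNm)
  fl$a170_obs_nm <- fl$a170_nm + stats::rnorm(nrow(fl), 0, params$jitterSdNm)

  noiseless <- list(
    mir = .renderKernels(gridNm, fl$mir_obs_nm[fl$mir_labeled],
                         ampPerFluor, sigma),
    a170 = .renderKernels(gridNm, fl$a170_obs_nm[fl$a170_labeled],
                          ampPerFluor, sigma))
  channels <- noiseless
  if (params$peakPhotonCount > 0)
    channels <- lapply(noiseless, function(l) stats::rpois(length(l), l) * 1.0)

  layouts <- lapply(1:n, function(k)
    expectedPositions(g, params$slUm, originNm = (k - 1L) * slNm))
  profile <- new("IntensityProfile",
                 positionsNm = gridNm,
                 channels = channels,
                 metadata = list(pixel_nm = params$pixelNm,
                                 source = "simulateProfile",
                                 genotype = g@label,
                                 sl_nominal_um = params$slUm,
                                 seed = params$seed))
  truth <- list(
    layouts = layouts,
    fluorophores = fl,
    noiseless = noiseless,
    grid_nm = gridNm,
    amp_per_fluor = ampPerFluor,
    sigma_nm = sigma,
    a170_separation_nm = 2 * dtkAt(g, params$slUm),
    dtk_nm = dtkAt(g, params$slUm),
    aband_titin_len_nm = abandLengthAt(g, params$slUm),
    params = params)
  list(profile = profile, truth = truth)
}

#' Simulate a stretch series of sarcomere profiles
#'
#' Independent profiles at each sarcomere length; child seeds are derived
#' deterministically from the master seed (\code{seed + index}).
#'
#' @param params a [stedSimParams()] list; its \code{slUm} is ignored in
#'   favour of \code{slUmList}.
#' @param slUmList sarcomere lengths (um) of the series.
#' @param nProfilesPerSl profiles per sarcomere length (0 gives an empty
#'   dataset).
#' @return list of \code{simulateProfile} results; each element carries the
#'   nominal SL in its profile metadata.
#' @export
simulateStretchSeries <- function(params, slUmList, nProfilesPerSl) {
  stopifnot(inherits(params, "stedSimParams"))
  if (nProfilesPerSl < 0) stop("nProfilesPerSl must be >= 0")
  out <- list()
  idx <- 0L
  for (sl in slUmList) {
    for (j in seq_len(nProfilesPerSl)) {
      idx <- idx + 1L
      p <- params
      p$slUm <- sl
      p$seed <- params$seed + idx
      out[[idx]] <- simulateProfile(p)
    }
  }
  out
}

#' Render a simulated profile as a 2D two-channel image
#'
#' Expands the noiseless expectation of a simulated profile across a
#' transverse extent (epitope bands become lines) and applies independent
#' Poisson noise per pixel. Useful for exercising [extractLineProfile()].
#'
#' @param sim result of [simulateProfile()].
#' @param widthPx transverse extent in pixels.
#' @param noise apply Poisson noise (default TRUE).
#' @return list with \code{images} (named list of matrices, rows = axial
#'   positions, columns = transverse samples), \code{positionsNm} and
#'   \code{pixelNm}.
#' @export
renderProfileImage <- function(sim, widthPx = 11L, noise = TRUE) {
  stopifnot(widthPx >= 1L)
  set.seed(sim$truth$params$seed + 977L)
  images <- lapply(sim$truth$noiseless, function(l) {
    m <- matrix(rep(l, widthPx), ncol = widthPx)
    if (noise) m[] <- stats::rpois(length(m), m)
    m
  })
  list(images = images, positionsNm = sim$truth$grid_nm,
       pixelNm = sim$truth$params$pixelNm)
}

# ---------------------------------------------------------------------------
# Gel lane simulation
# ---------------------------------------------------------------------------

#' Default band composition of a simulated titin gel lane
#'
#' Band inventory (label, molecular weight in kDa, quantity in arbitrary
#' units) of a TTNtv+ or TTNtv- cardiac lane. T1 (N2BA + N2B) totals 1.0;
#' the truncated band defaults to 0.19 x T1 at the mass predicted for a
#' representative A-band truncation (residue 17,100), T2 to 0.25 x T1, and
#' MyHC to 2.5 (myosin is far more abundant than titin).
#'
#' @param genotype \code{"TTNTV_POS"} (includes the truncated band) or
#'   \code{"TTNTV_NEG"}.
#' @param truncOverT1 truncated-band quantity as a fraction of T1
#'   (default 0.19).
#' @param truncResidue truncation residue used to set the truncated-band
#'   molecular weight via [predictTruncatedMass()].
#' @param model titin model for the mass prediction.
#' @return data.frame with columns label, mw_kda, quantity_au.
#' @export
defaultGelComposition <- function(genotype = c("TTNTV_POS", "TTNTV_NEG"),
                                  truncOverT1 = 0.19,
                                  truncResidue = 17100L,
                                  model = titinIsoformModel()) {
  genotype <- match.arg(genotype)
  bands <- data.frame(
    label = c("N2BA", "N2B", "T2", "MyHC"),
    mw_kda = c(3700, 3000, 2300, 223),
    quantity_au = c(0.4, 0.6, 0.25, 2.5))
  if (genotype == "TTNTV_POS") {
    t1 <- sum(bands$quantity_au[bands$label %in% c("N2BA", "N2B")])
    bands <- rbind(bands, data.frame(
      label = "truncated",
      mw_kda = predictTruncatedMass(model, truncResidue),
      quantity_au = truncOverT1 * t1))
  }
  bands[order(-bands$mw_kda), , drop = FALSE]
}

#' Simulation parameters for gel lane traces
#'
#' @param bands data.frame (label, mw_kda, quantity_au); defaults to
#'   [defaultGelComposition()] for TTNtv+.
#' @param calibration numeric(2): intercept and slope (mm per decade) of
#'   migration versus log10(MW kDa); the slope must be negative so that
#'   migration decreases with log MW.
#' @param bandWidthMm Gaussian band SD in mm (default 0.4).
#' @param background numeric(2): OD offset and ramp per mm.
#' @param noiseSd additive Gaussian OD noise SD (default 0.002).
#' @param quantityCv lane-to-lane multiplicative (lognormal, mean 1)
#'   variability of each band quantity (default 0.05), emulating loading
#'   variability; set 0 for exactly reproducible quantities.
#' @param gridMm migration grid (default 0 to 80 mm, 0.05 mm step).
#' @param seed integer RNG seed.
#' @return validated parameter list of class \code{gelSimParams}.
#' @export
gelSimParams <- function(bands = defaultGelComposition("TTNTV_POS"),
                         calibration = c(150, -38),
                         bandWidthMm = 0.4,
                         background = c(0.02, 0.001),
                         noiseSd = 0.002,
                         quantityCv = 0.05,
                         gridMm = seq(0, 80, by = 0.05),
                         seed = 1L) {
  if (any(bands$quantity_au < 0)) stop("band quantities must be >= 0")
  if (any(bands$mw_kda <= 0)) stop("band molecular weights must be positive")
  if (calibration[2L] >= 0)
    stop("calibration slope must be negative (migration decreases with log MW)")
  if (bandWidthMm <= 0) stop("bandWidthMm must be positive")
  structure(list(
    bands = bands, calibration = calibration, bandWidthMm = bandWidthMm,
    background = background, noiseSd = noiseSd, quantityCv = quantityCv,
    gridMm = gridMm, seed = as.integer(seed)
  ), class = "gelSimParams")
}

#' Simulate one densitometric gel lane
#'
#' Renders each band as an area-normalised Gaussian centred at the
#' calibrated migration of its molecular weight, scaled by its (optionally
#' lane-jittered) quantity, on top of a linear background, plus Gaussian
#' read noise. Bands closer than half a band width are flagged as merge
#' risks. Ground-truth quantities, centres and the trunc/T1 ratio are
#' recorded.
#'
#' @param params a [gelSimParams()] list.
#' @param laneId lane identifier.
#' @return list with \code{lane} (a [GelLaneProfile-class]) and
#'   \code{truth} (band table with realised quantities and migration
#'   centres, background, merge warnings, trunc/T1 ratio).
#' @export
simulateGelLane <- function(params, laneId = "lane1") {
  stopifnot(inherits(params, "gelSimParams"))
  set.seed(params$seed)
  b <- params$bands
  b$migration_mm <- params$calibration[1L] +
    params$calibration[2L] * log10(b$mw_kda)
  if (any(b$migration_mm < min(params$gridMm)) ||
      any(b$migration_mm > max(params$gridMm)))
    stop("band migration falls outside the lane grid; adjust calibration/grid")
  mergeRisk <- character()
  if (nrow(b) > 1L) {
    d <- diff(sort(b$migration_mm))
    if (any(d < 0.5 * params$bandWidthMm))
      mergeRisk <- "bands closer than 0.5 x band width: merge risk"
  }
  if (length(mergeRisk)) warning(mergeRisk)
  q <- b$quantity_au
  if (params$quantityCv > 0) {
    sdlog <- sqrt(log(1 + params$quantityCv^2))
    q <- q * stats::rlnorm(length(q), -sdlog^2 / 2, sdlog)
  }
  b$quantity_realized <- q
  x <- params$gridMm
  od <- params$background[1L] + params$background[2L] * x
  for (i in seq_len(nrow(b)))
    od <- od + q[i] / (params$bandWidthMm * sqrt(2 * pi)) *
      exp(-(x - b$migration_mm[i])^2 / (2 * params$bandWidthMm^2))
  noiseless <- od
  if (params$noiseSd > 0)
    od <- od + stats::rnorm(length(od), 0, params$noiseSd)
  t1 <- sum(q[b$label %in% c("N2BA", "N2B")])
  truth <- list(
    bands = b, background = params$background, noiseless = noiseless,
    merge_warnings = mergeRisk,
    trunc_over_t1 = if ("truncated" %in% b$label)
      q[b$label == "truncated"] / t1 else 0,
    params = params)
  lane <- new("GelLaneProfile", migrationMm = x, od = od, laneId = laneId)
  list(lane = lane, truth = truth)
}
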