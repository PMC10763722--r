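# Gel lane quantification: mobility calibration, band integration above a
# local baseline, titin stoichiometry ratios, and truncated-band matching
# against sequence-predicted masses.

#' Calibrate electrophoretic mobility against molecular weight
#'
#' Least-squares line of migration versus log10(MW) over the supplied
#' standards. The returned object converts in both directions (see
#' [mwToMigration()] and [migrationToMw()]); the round trip is identity to
#' machine precision.
#'
#' @param standards data.frame with columns \code{mw_kda} and
#'   \code{migration_mm}; at least two standards with distinct MWs.
#' @return a [MobilityCalibration-class].
#' @examples
#' cal <- calibrateMobility(data.frame(mw_kda = c(3000, 300),
#'                                     migration_mm = c(10, 20)))
#' migrationToMw(cal, 15)  # sqrt(3000*300) ~ 948.7 kDa
#' @export
calibrateMobility <- function(standards) {
  if (!all(c("mw_kda", "migration_mm") %in% names(standards)))
    stop("standards must have columns mw_kda and migration_mm")
  if (nrow(standards) < 2L || length(unique(standards$mw_kda)) < 2L)
    stop("calibration needs at least 2 standards with distinct MWs")
  fit <- stats::lm(migration_mm ~ log10(mw_kda), data = standards)
  co <- stats::coef(fit)
  new("MobilityCalibration", intercept = unname(co[1L]),
      slope = unname(co[2L]), standards = standards)
}

#' Predicted migration (mm) of a molecular weight
#' @param calibration a [MobilityCalibration-class].
#' @param mwKda molecular weight(s) in kDa.
#' @export
mwToMigration <- function(calibration, mwKda) {
  calibration@intercept + calibration@slope * log10(mwKda)
}

#' Molecular weight (kDa) at a migration distance
#' @param calibration a [MobilityCalibration-class].
#' @param migrationMm migration distance(s) in mm.
#' @export
migrationToMw <- function(calibration, migrationMm) {
  10^((migrationMm - calibration@intercept) / calibration@slope)
}

# Detect band peaks on a lane trace (shared with auto-windowing).
.detectLanePeaks <- function(x, y, minProminenceFrac = 0.04) {
  ys <- .smooth3(y, 5L)
  thr <- minProminenceFrac * (max(ys) - min(ys))
  cand <- .localMaxima(ys)
  cand <- cand[vapply(cand, function(i) .prominence(ys, i), 0) >= thr]
  cand[order(x[cand])]
}

#' Quantify bands in a gel lane
#'
#' For each band window the baseline is the straight line between the
#' window-edge minima (each taken on the lightly smoothed trace over a
#' small edge neighborhood); the integrated OD is the trapezoidal area
#' above that baseline, and the band's molecular weight is estimated from
#' its OD-weighted centroid migration via the calibration. In auto mode the
#' windows are derived from detected peaks: each window extends
#' \code{windowHalfSigmas} estimated band SDs around the peak, clipped at
#' the midpoint to the neighboring peak. Labels are assigned by calibrated
#' MW proximity to a lane template (expected band MWs); detected bands
#' matching no template entry within the tolerance are labeled
#' \code{"other"}. A run of >= 5 samples at the lane's OD maximum raises a
#' saturation warning on that band.
#'
#' @param lane a [GelLaneProfile-class].
#' @param calibration a [MobilityCalibration-class].
#' @param bandWindows optional data.frame (label, from_mm, to_mm) of
#'   explicit windows; when NULL windows are auto-detected.
#' @param template named numeric vector of expected band MWs (kDa) used for
#'   label assignment in auto mode.
#' @param templateLogTol maximum |log10 MW| distance for a template match
#'   (default 0.06, i.e. ~15% in MW).
#' @param windowHalfSigmas window half-width in estimated band SDs
#'   (default 4).
#' @param edgePx edge-neighborhood size (samples) for the baseline minima
#'   (default 9).
#' @param baselineSmoothPx running-mean window (samples) applied to the
#'   trace before taking the edge minima (default 15); heavier smoothing
#'   here suppresses the downward bias of the minimum statistic under read
#'   noise without touching the integrated trace itself.
#' @return data.frame with columns \code{label}, \code{from_mm},
#'   \code{to_mm}, \code{integrated_od}, \code{centroid_mm},
#'   \code{estimated_mw_kda}, \code{saturated}.
#' @export
quantifyLane <- function(lane, calibration, bandWindows = NULL,
                         template = c(N2BA = 3700, N2B = 3000,
                                      T2 = 2300, MyHC = 223),
                         templateLogTol = 0.06,
                         windowHalfSigmas = 4, edgePx = 9L,
                         baselineSmoothPx = 15L) {
  stopifnot(is(lane, "GelLaneProfile"))
  x <- lane@migrationMm
  y <- lane@od
  dx <- diff(x[1:2])
  if (is.null(bandWindows)) {
    pk <- .detectLanePeaks(x, y)
    if (!length(pk)) return(data.frame())
    ys <- .smooth3(y, 5L)
    # per-peak SD estimate from the half-height width
    sigma <- vapply(pk, function(i) {
      h <- ys[i]
      base <- min(ys)
      half <- base + (h - base) / 2
      l <- i; while (l > 1L && ys[l] > half) l <- l - 1L
      r <- i; while (r < length(ys) && ys[r] > half) r <- r + 1L
      (x[r] - x[l]) / (2 * sqrt(2 * log(2)))
    }, 0)
    from <- x[pk] - windowHalfSigmas * sigma
    to <- x[pk] + windowHalfSigmas * sigma
    if (length(pk) > 1L) {
      mid <- (x[pk[-length(pk)]] + x[pk[-1L]]) / 2
      to[-length(to)] <- pmin(to[-length(to)], mid)
      from[-1L] <- pmax(from[-1L], mid)
    }
    from <- pmax(from, min(x)); to <- pmin(to, max(x))
    bandWindows <- data.frame(label = NA_character_, from_mm = from,
                              to_mm = to, peak_mm = x[pk])
  } else {
    if (any(bandWindows$from_mm < min(x)) || any(bandWindows$to_mm > max(x)))
      stop("band windows must lie inside the lane grid")
    bandWindows$peak_mm <- (bandWindows$from_mm + bandWindows$to_mm) / 2
  }

  ysm <- .smooth3(y, as.integer(baselineSmoothPx))
  odMax <- max(y)
  rows <- lapply(seq_len(nrow(bandWindows)), function(i) {
    sel <- which(x >= bandWindows$from_mm[i] & x <= bandWindows$to_mm[i])
    if (length(sel) < 3L) return(NULL)
    eL <- sel[seq_len(min(edgePx, length(sel)))]
    eR <- sel[seq(max(1L, length(sel) - edgePx + 1L), length(sel))]
    bL <- min(ysm[eL]); bR <- min(ysm[eR])
    xl <- x[eL[which.min(ysm[eL])]]; xr <- x[eR[which.min(ysm[eR])]]
    baseline <- bL + (bR - bL) * (x[sel] - xl) / max(xr - xl, dx)
    above <- pmax(y[sel] - baseline, 0)
    area <- sum((above[-1L] + above[-length(above)]) / 2) * dx
    centroid <- if (sum(above) > 0) sum(x[sel] * above) / sum(above) else
      bandWindows$peak_mm[i]
    satRun <- rle(y[sel] >= odMax - 1e-12)
    saturated <- any(satRun$values & satRun$lengths >= 5L)
    data.frame(label = bandWindows$label[i],
               from_mm = bandWindows$from_mm[i],
               to_mm = bandWindows$to_mm[i],
               integrated_od = area, centroid_mm = centroid,
               estimated_mw_kda = migrationToMw(calibration, centroid),
               saturated = saturated)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  if (all(is.na(out$label)) && length(template)) {
    lgMw <- log10(out$estimated_mw_kda)
    lab <- rep("other", nrow(out))
    free <- rep(TRUE, nrow(out))
    # greedy best-first assignment of template labels to detected bands
    cand <- expand.grid(t = seq_along(template), b = seq_len(nrow(out)))
    cand$d <- abs(log10(template[cand$t]) - lgMw[cand$b])
    cand <- cand[order(cand$d), ]
    usedT <- rep(FALSE, length(template))
    for (r in seq_len(nrow(cand))) {
      ti <- cand$t[r]; bi <- cand$b[r]
      if (usedT[ti] || !free[bi] || cand$d[r] > templateLogTol) next
      lab[bi] <- names(template)[ti]
      usedT[ti] <- TRUE; free[bi] <- FALSE
    }
    out$label <- lab
  }
  if (any(out$saturated))
    warning("saturated plateau detected in band(s): ",
            paste(out$label[out$saturated], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Titin stoichiometry ratios from quantified bands
#'
#' T1 is computed as N2BA + N2B; T2 and the truncated band are optional and
#' treated as zero when absent. Ratios are invariant to global OD scaling.
#'
#' @param bands data.frame from [quantifyLane()] (needs labels N2BA, N2B,
#'   MyHC; optionally T2 and truncated).
#' @return list with \code{n2ba_over_n2b}, \code{t1_over_myhc},
#'   \code{t2_over_t1}, \code{trunc_over_t1}, \code{t1t2_over_myhc} and
#'   \code{integrated_titin_over_myhc} ((T1 + T2 + truncated)/MyHC).
#' @export
computeTitinRatios <- function(bands) {
  get <- function(lab) {
    v <- bands$integrated_od[bands$label == lab]
    if (!length(v)) 0 else sum(v)
  }
  for (need in c("N2BA", "N2B", "MyHC"))
    if (!need %in% bands$label)
      stop("bands must include ", need)
  n2ba <- get("N2BA"); n2b <- get("N2B"); myhc <- get("MyHC")
  t2 <- get("T2"); tr <- get("truncated")
  if (myhc <= 0) stop("undefined ratio: MyHC area is zero")
  if (n2b <= 0) stop("undefined ratio: N2B area is zero")
  t1 <- n2ba + n2b
  list(
    n2ba_over_n2b = n2ba / n2b,
    t1_over_myhc = t1 / myhc,
    t2_over_t1 = t2 / t1,
    trunc_over_t1 = tr / t1,
    t1t2_over_myhc = (t1 + t2) / myhc,
    integrated_titin_over_myhc = (t1 + t2 + tr) / myhc)
}

#' Match an observed band mass against a predicted truncated-titin mass
#'
#' @param estimatedMwKda band mass estimated from the gel.
#' @param predictedMwKda mass predicted from the truncation position.
#' @param toleranceFrac relative tolerance (default 0.10).
#' @return logical: |estimated - predicted| / predicted <= tolerance.
#' @export
matchTruncatedBand <- function(estimatedMwKda, predictedMwKda,
                               toleranceFrac = 0.10) {
  if (any(estimatedMwKda <= 0) || any(predictedMwKda <= 0))
    stop("masses must be positive")
  abs(estimatedMwKda - predictedMwKda) / predictedMwKda <= toleranceFrac
}

#' Label an unassigned band as truncated titin when its mass matches
#'
#' Requires both conditions of the disambiguation rule: the band is not
#' assigned to a template entry AND its calibrated mass matches a
#' model-predicted truncated-titin mass within the tolerance.
#'
#' @param bands data.frame from [quantifyLane()].
#' @param predictedMwKda predicted truncated-protein mass(es) in kDa.
#' @param toleranceFrac relative mass tolerance (default 0.10).
#' @return the band table with matching \code{"other"} bands relabeled
#'   \code{"truncated"}.
#' @export
identifyTruncatedBand <- function(bands, predictedMwKda,
                                  toleranceFrac = 0.10) {
  if (!nrow(bands)) return(bands)
  for (i in which(bands$label == "other")) {
    if (any(matchTruncatedBand(bands$estimated_mw_kda[i], predictedMwKda,
                               toleranceFrac)))
      bands$label[i] <- "truncated"
  }
  bands
}
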