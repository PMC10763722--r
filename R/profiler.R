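# STED line-profile analysis: peak detection, multi-Gaussian fitting,
# sarcomere assignment by epitope grammar, the 20% intensity-fluctuation QC
# rule, and the per-sarcomere nanostructure metrics.

#' Fit and quality-control settings for the epitope profiler
#'
#' @param prominenceK candidate peaks must have prominence >= k x the robust
#'   noise SD (default 3).
#' @param minProminenceFrac additional floor on the prominence as a fraction
#'   of the channel maximum (default 0.08); guards against noise maxima on
#'   band flanks where the Poisson noise scale varies.
#' @param fwhmGuessNm initial FWHM for fits and scale for the minimum peak
#'   separation (default 45 nm: PSF broadened by typical registration
#'   jitter).
#' @param clusterGapNm maxima closer than this are fitted jointly as a
#'   multi-Gaussian neighborhood (default 300 nm).
#' @param windowHalfWidthNm half-width added around a cluster to form the
#'   fit window (default 3 x fwhmGuessNm).
#' @param doubletWindowNm admissible A170 doublet separation (default
#'   60-260 nm).
#' @param qcThreshold maximum tolerated cross-M-line intensity fluctuation
#'   (default 0.20).
#' @param expectedFwhmNm expected single-epitope FWHM; when given, fitted
#'   peaks wider than \code{maxFwhmFactor} times it are flagged
#'   \code{"wide"} (unresolved) and excluded from sarcomere assignment.
#'   Default \code{NA} (no width flagging).
#' @param maxFwhmFactor width-flag factor (default 1.2).
#' @param splitShoulders if TRUE, a single detected peak is refitted with
#'   two Gaussian components and split when the two-component fit reduces
#'   the residual variance at the \code{splitFAlpha} F-criterion (default
#'   FALSE: unresolved doublets are rejected, not force-deconvolved).
#' @param splitFAlpha significance level of the shoulder-splitting F test.
#' @return settings list of class \code{fitSettings}.
#' @export
fitSettings <- function(prominenceK = 3, minProminenceFrac = 0.08,
                        fwhmGuessNm = 45, clusterGapNm = 300,
                        windowHalfWidthNm = NULL,
                        doubletWindowNm = c(60, 260),
                        qcThreshold = 0.20,
                        expectedFwhmNm = NA_real_, maxFwhmFactor = 1.2,
                        splitShoulders = FALSE, splitFAlpha = 0.01) {
  if (is.null(windowHalfWidthNm)) windowHalfWidthNm <- 3 * fwhmGuessNm
  structure(list(
    prominenceK = prominenceK, minProminenceFrac = minProminenceFrac,
    fwhmGuessNm = fwhmGuessNm, clusterGapNm = clusterGapNm,
    windowHalfWidthNm = windowHalfWidthNm,
    doubletWindowNm = doubletWindowNm, qcThreshold = qcThreshold,
    expectedFwhmNm = expectedFwhmNm, maxFwhmFactor = maxFwhmFactor,
    splitShoulders = splitShoulders, splitFAlpha = splitFAlpha
  ), class = "fitSettings")
}

# running mean with edge padding
.smooth3 <- function(y, k = 3L) {
  if (k <= 1L) return(y)
  n <- length(y)
  pad <- (k - 1L) %/% 2L
  yp <- c(rep(y[1L], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, rep(1 / k, k), sides = 2L))[(pad + 1L):(pad + n)]
}

# prominence of local maximum at index i: height minus the higher of the two
# valley floors between the peak and the nearest higher terrain (or edge).
.prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  right <- if (i < length(y)) y[(i + 1L):length(y)] else numeric()
  sideMin <- function(v, rev = FALSE) {
    if (!length(v)) return(h)
    if (rev) v <- rev(v)
    higher <- which(v > h)          # nearest higher terrain
    if (length(higher)) v <- v[seq(higher[length(higher)] + 1L, length(v))]
    min(v)
  }
  h - max(sideMin(left), sideMin(right, rev = TRUE))
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

# Robust noise SD of a trace: successive-difference MAD.
.noiseSd <- function(y) stats::mad(diff(y)) / sqrt(2)

# Sum-of-Gaussians + constant baseline model and its nls.lm fit.
.gaussSum <- function(par, x, k) {
  b <- par[1L]
  out <- rep(b, length(x))
  for (j in seq_len(k)) {
    A <- par[1L + j]; c0 <- par[1L + k + j]; s <- par[1L + 2L * k + j]
    out <- out + A * exp(-(x - c0)^2 / (2 * s^2))
  }
  out
}

.fitGaussians <- function(x, y, centers0, fwhmGuess) {
  k <- length(centers0)
  b0 <- min(y)
  A0 <- pmax(y[vapply(centers0, function(c0) which.min(abs(x - c0)), 1L)] - b0,
             1e-6)
  s0 <- rep(fwhmGuess / (2 * sqrt(2 * log(2))), k)
  par0 <- c(b0, A0, centers0, s0)
  lower <- c(-Inf, rep(0, k), rep(min(x), k), rep(diff(x[1:2]) / 2, k))
  upper <- c(Inf, rep(Inf, k), rep(max(x), k), rep(diff(range(x)), k))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) y - .gaussSum(par, x, k),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(par0)))
  list(fit = fit, par = fit$par, se = se, k = k,
       rss = sum(fit$fvec^2), n = length(x),
       converged = fit$info %in% 1:4)
}

#' Detect and fit Gaussian epitope peaks in one profile channel
#'
#' Candidate peaks are local maxima of the lightly smoothed trace whose
#' prominence exceeds both \code{prominenceK} x the robust noise SD and
#' \code{minProminenceFrac} x the channel maximum. Nearby candidates are
#' fitted jointly as a sum of Gaussians plus a constant baseline
#' (Levenberg-Marquardt least squares, initialised at the detected maxima).
#' Non-converged fits are flagged and excluded (reported in the
#' \code{"excluded"} attribute, never silently dropped). With
#' \code{expectedFwhmNm} set, overly wide peaks are flagged
#' \code{"wide"}; with \code{splitShoulders = TRUE}, single peaks are
#' refitted with two components and split when an F test on the residual
#' variance reduction passes.
#'
#' @param profile an [IntensityProfile-class] (>= 20 samples).
#' @param channel channel name (e.g. \code{"mir"}).
#' @param config a [fitSettings()] list.
#' @return data.frame sorted by center with columns \code{channel},
#'   \code{center_nm}, \code{height} (amplitude above baseline),
#'   \code{fwhm_nm}, \code{center_se_nm}, \code{baseline}, \code{flag}
#'   (\code{""}, \code{"wide"}); attribute \code{"excluded"} holds flagged
#'   non-converged fits.
#' @export
detectAndFitPeaks <- function(profile, channel, config = fitSettings()) {
  stopifnot(is(profile, "IntensityProfile"))
  x <- profile@positionsNm
  if (length(x) < 20L) stop("profile must have at least 20 samples")
  y <- channelIntensity(profile, channel)
  ys <- .smooth3(y)
  noise <- .noiseSd(y)
  thr <- max(config$prominenceK * noise,
             config$minProminenceFrac * max(ys))
  cand <- .localMaxima(ys)
  cand <- cand[vapply(cand, function(i) .prominence(ys, i), 0) >= thr]
  if (!length(cand)) {
    out <- data.frame(channel = character(), center_nm = numeric(),
                      height = numeric(), fwhm_nm = numeric(),
                      center_se_nm = numeric(), baseline = numeric(),
                      flag = character())
    attr(out, "excluded") <- out
    return(out)
  }
  # merge candidates closer than ~ one PSF width, keeping the higher
  minSep <- 0.8 * config$fwhmGuessNm
  cand <- cand[order(x[cand])]
  keep <- cand[1L]
  for (i in cand[-1L]) {
    if (x[i] - x[keep[length(keep)]] < minSep) {
      if (ys[i] > ys[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  centers <- x[keep]
  cluster <- cumsum(c(1, diff(centers) > config$clusterGapNm))

  rows <- list(); excluded <- list()
  for (cl in unique(cluster)) {
    c0 <- centers[cluster == cl]
    w <- config$windowHalfWidthNm
    sel <- x >= min(c0) - w & x <= max(c0) + w
    fit <- .fitGaussians(x[sel], y[sel], c0, config$fwhmGuessNm)
    if (config$splitShoulders && fit$k == 1L) fit <- .maybeSplit(
      x[sel], y[sel], fit, config)
    k <- fit$k
    for (j in seq_len(k)) {
      row <- data.frame(
        channel = channel,
        center_nm = fit$par[1L + k + j],
        height = fit$par[1L + j],
        fwhm_nm = 2 * sqrt(2 * log(2)) * fit$par[1L + 2L * k + j],
        center_se_nm = unname(fit$se[1L + k + j]),
        baseline = fit$par[1L],
        flag = "")
      if (!fit$converged) {
        row$flag <- "nonconverged"
        excluded[[length(excluded) + 1L]] <- row
        next
      }
      if (is.finite(config$expectedFwhmNm) &&
          row$fwhm_nm > config$maxFwhmFactor * config$expectedFwhmNm)
        row$flag <- "wide"
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(), center_nm = numeric(),
               height = numeric(), fwhm_nm = numeric(),
               center_se_nm = numeric(), baseline = numeric(),
               flag = character())
  out <- out[order(out$center_nm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    out[0, , drop = FALSE]
  out
}

# Two-component refit of a single-peak window; split only if the F test on
# the residual-variance reduction is significant.
.maybeSplit <- function(x, y, fit1, config) {
  c0 <- fit1$par[3L]
  s0 <- fit1$par[4L]
  fit2 <- .fitGaussians(x, y, c(c0 - s0, c0 + s0), config$fwhmGuessNm)
  if (!fit2$converged) return(fit1)
  df1 <- fit1$n - 4L; df2 <- fit2$n - 7L
  if (df2 <= 0 || fit2$rss <= 0) return(fit1)
  f <- ((fit1$rss - fit2$rss) / 3) / (fit2$rss / df2)
  p <- stats::pf(f, 3, df2, lower.tail = FALSE)
  if (is.finite(p) && p < config$splitFAlpha) fit2 else fit1
}

#' Assign sarcomeres from fitted MIR and A170 peaks
#'
#' Scans the peak lists for the grammar \code{[MIR, A170, A170, MIR]}: a
#' consecutive MIR pair (no other MIR between) bounding exactly two A170
#' peaks whose separation falls within the doublet window. The M-line is
#' the A170 doublet midpoint; the A-band titin length is the MIR-to-MIR
#' distance; the M-to-TK distance is half the A170 separation. The
#' sarcomere length is the distance between consecutive M-lines (interior
#' sarcomeres average their two neighbor gaps; terminal sarcomeres use
#' their single neighbor), so at least two complete matches are required.
#' Peaks carrying a non-empty flag (wide/unresolved) are excluded before
#' matching. Candidate conflicts are resolved by smallest MIR-to-MIR span,
#' then leftmost.
#'
#' @param mirPeaks,a170Peaks peak data.frames from [detectAndFitPeaks()],
#'   sorted by center.
#' @param config a [fitSettings()] list (doublet window).
#' @return data.frame with one row per matched sarcomere: \code{sl_nm},
#'   \code{sl_um}, \code{aband_titin_len_nm}, \code{m_position_nm},
#'   \code{dtk_nm}, \code{a170_separation_nm}, \code{mir_fwhm_nm},
#'   \code{a170_fwhm_nm}, per-peak heights, and placeholders for QC columns;
#'   attribute \code{"diagnostics"} records why candidates were rejected.
#'   Empty (zero rows) with a diagnostic when fewer than two matches exist.
#' @export
assignSarcomeres <- function(mirPeaks, a170Peaks, config = fitSettings()) {
  diag <- character()
  empty <- function(reason) {
    out <- data.frame()
    attr(out, "diagnostics") <- c(diag, reason)
    out
  }
  mir <- mirPeaks[mirPeaks$flag == "", , drop = FALSE]
  a170 <- a170Peaks[a170Peaks$flag == "", , drop = FALSE]
  if (nrow(mir) < 2L || nrow(a170) < 2L)
    return(empty("need at least 2 MIR and 2 A170 peaks"))
  mir <- mir[order(mir$center_nm), , drop = FALSE]
  a170 <- a170[order(a170$center_nm), , drop = FALSE]

  matches <- list()
  for (i in seq_len(nrow(mir) - 1L)) {
    l <- mir$center_nm[i]; r <- mir$center_nm[i + 1L]
    inside <- which(a170$center_nm > l & a170$center_nm < r)
    if (length(inside) != 2L) {
      if (length(inside) > 0L)
        diag <- c(diag, sprintf(
          "MIR pair %.0f-%.0f: %d A170 peak(s) inside, need 2", l, r,
          length(inside)))
      next
    }
    sep <- diff(a170$center_nm[inside])
    if (sep < config$doubletWindowNm[1L] || sep > config$doubletWindowNm[2L]) {
      diag <- c(diag, sprintf(
        "MIR pair %.0f-%.0f: doublet separation %.0f nm outside window",
        l, r, sep))
      next
    }
    if (r - l <= sep) {
      diag <- c(diag, sprintf(
        "MIR pair %.0f-%.0f: span not larger than A170 separation", l, r))
      next
    }
    matches[[length(matches) + 1L]] <- list(mir = i, a170 = inside,
                                            span = r - l, left = l)
  }
  if (length(matches) < 2L)
    return(empty(sprintf("only %d complete grammar match(es); need >= 2",
                         length(matches))))
  # resolve overlaps: smallest span, then leftmost
  ord <- order(vapply(matches, `[[`, 0, "span"),
               vapply(matches, `[[`, 0, "left"))
  used <- rep(FALSE, nrow(mir))
  chosen <- list()
  for (m in matches[ord]) {
    ii <- c(m$mir, m$mir + 1L)
    if (any(used[ii])) next
    used[ii] <- TRUE
    chosen[[length(chosen) + 1L]] <- m
  }
  if (length(chosen) < 2L)
    return(empty("fewer than 2 non-overlapping matches"))

  rows <- lapply(chosen, function(m) {
    ml <- mir[m$mir, ]; mr <- mir[m$mir + 1L, ]
    al <- a170[m$a170[1L], ]; ar <- a170[m$a170[2L], ]
    sep <- ar$center_nm - al$center_nm
    data.frame(
      m_position_nm = (al$center_nm + ar$center_nm) / 2,
      mir_left_nm = ml$center_nm, mir_right_nm = mr$center_nm,
      aband_titin_len_nm = mr$center_nm - ml$center_nm,
      a170_separation_nm = sep,
      dtk_nm = sep / 2,
      mir_fwhm_nm = mean(c(ml$fwhm_nm, mr$fwhm_nm)),
      a170_fwhm_nm = mean(c(al$fwhm_nm, ar$fwhm_nm)),
      mir_height_l = ml$height, mir_height_r = mr$height,
      a170_height_l = al$height, a170_height_r = ar$height)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$m_position_nm), , drop = FALSE]
  gaps <- diff(out$m_position_nm)
  n <- nrow(out)
  sl <- numeric(n)
  sl[1L] <- gaps[1L]
  sl[n] <- gaps[length(gaps)]
  if (n > 2L) for (i in 2:(n - 1L)) sl[i] <- mean(gaps[c(i - 1L, i)])
  out$sl_nm <- sl
  out$sl_um <- sl / 1000
  out$sarcomere_id <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag
  out
}

#' The cross-M-line intensity-fluctuation quality-control rule
#'
#' For each channel the fluctuation is \code{|h_left - h_right| /
#' mean(h_left, h_right)}; a sarcomere fails when the fluctuation of either
#' the MIR or the A170 epitope pair exceeds the threshold (default 20% of
#' the average intensity). A missing or non-positive height fails with
#' reason \code{"incomplete"}.
#'
#' @param measurement one-row data.frame from [assignSarcomeres()] (needs
#'   the four height columns).
#' @param threshold maximum tolerated fluctuation (default 0.20).
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector naming the failing channel(s), empty when passing).
#' @examples
#' m <- data.frame(mir_height_l = 100, mir_height_r = 130,
#'                 a170_height_l = 50, a170_height_r = 50)
#' qcFilter(m)  # fails: MIR fluctuation 30/115 = 0.261
#' @export
qcFilter <- function(measurement, threshold = 0.20) {
  h <- unlist(measurement[1L, c("mir_height_l", "mir_height_r",
                                "a170_height_l", "a170_height_r")])
  if (any(is.na(h)) || any(h <= 0))
    return(list(pass = FALSE, reasons = "incomplete"))
  fl <- function(a, b) abs(a - b) / mean(c(a, b))
  reasons <- character()
  if (fl(h[1L], h[2L]) > threshold) reasons <- c(reasons, "MIR")
  if (fl(h[3L], h[4L]) > threshold) reasons <- c(reasons, "A170")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# vectorised QC over a measurement table
applyQc <- function(measurements, threshold = 0.20) {
  if (!nrow(measurements)) {
    measurements$qc_pass <- logical()
    measurements$qc_reasons <- character()
    return(measurements)
  }
  res <- lapply(seq_len(nrow(measurements)), function(i)
    qcFilter(measurements[i, , drop = FALSE], threshold))
  measurements$qc_pass <- vapply(res, `[[`, TRUE, "pass")
  measurements$qc_reasons <- vapply(res, function(r)
    paste(r$reasons, collapse = ";"), "")
  measurements
}

#' A170 epitope intensity normalised to the MIR epitope
#'
#' \code{mean(A170 left/right heights) / mean(MIR left/right heights)};
#' heights are the baseline-corrected fitted Gaussian amplitudes.
#'
#' @param measurement one-row data.frame with the four height columns.
#' @return numeric ratio.
#' @export
normalizeA170Intensity <- function(measurement) {
  mirMean <- mean(c(measurement$mir_height_l, measurement$mir_height_r))
  if (!is.finite(mirMean) || mirMean <= 0)
    stop("undefined ratio: MIR mean height is zero or missing")
  mean(c(measurement$a170_height_l, measurement$a170_height_r)) / mirMean
}

#' Full per-profile analysis: detect, fit, assign, QC, normalise
#'
#' Convenience wrapper running [detectAndFitPeaks()] on the \code{mir} and
#' \code{a170} channels, [assignSarcomeres()], the QC rule and the A170/MIR
#' intensity ratio. Rejected sarcomeres are retained with
#' \code{qc_pass = FALSE} and a reason code (auditable discards).
#'
#' @param profile an [IntensityProfile-class].
#' @param config a [fitSettings()] list.
#' @param genotype optional genotype label attached to the rows (defaults
#'   to profile metadata when present).
#' @return measurement data.frame (possibly zero rows) with QC columns,
#'   \code{a170_over_mir_intensity}, \code{genotype} and (when known)
#'   \code{sl_nominal_um}; attributes \code{"diagnostics"} and
#'   \code{"excluded_peaks"}.
#' @export
profileSarcomeres <- function(profile, config = fitSettings(),
                              genotype = NULL) {
  mir <- detectAndFitPeaks(profile, "mir", config)
  a170 <- detectAndFitPeaks(profile, "a170", config)
  meas <- assignSarcomeres(mir, a170, config)
  if (!nrow(meas)) {
    out <- data.frame()
    attr(out, "diagnostics") <- attr(meas, "diagnostics")
    attr(out, "excluded_peaks") <- rbind(attr(mir, "excluded"),
                                         attr(a170, "excluded"))
    return(out)
  }
  meas <- applyQc(meas, config$qcThreshold)
  meas$a170_over_mir_intensity <- vapply(seq_len(nrow(meas)), function(i)
    normalizeA170Intensity(meas[i, , drop = FALSE]), 0)
  if (is.null(genotype))
    genotype <- profile@metadata$genotype %||% NA_character_
  meas$genotype <- genotype
  slNom <- profile@metadata$sl_nominal_um
  meas$sl_nominal_um <- if (is.null(slNom)) NA_real_ else slNom
  attr(meas, "diagnostics") <- attr(meas, "diagnostics")
  attr(meas, "excluded_peaks") <- rbind(attr(mir, "excluded"),
                                        attr(a170, "excluded"))
  meas
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the profiler over a list of simulated or ingested profiles
#'
#' @param sims list of [simulateProfile()] results or
#'   [IntensityProfile-class] objects.
#' @param config a [fitSettings()] list.
#' @return combined measurement data.frame with a \code{profile_id} column.
#' @export
profileDataset <- function(sims, config = fitSettings()) {
  rows <- list()
  for (i in seq_along(sims)) {
    p <- sims[[i]]
    if (!is(p, "IntensityProfile")) p <- p$profile
    m <- profileSarcomeres(p, config)
    if (nrow(m)) {
      m$profile_id <- i
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract an averaged line profile from a 2D image
#'
#' Samples the image along a straight line at one-pixel steps, averaging
#' \code{widthPx} bilinearly interpolated samples taken perpendicular to
#' the line at each position (thick-line averaging compensates labeling
#' inhomogeneity along epitope lines). A rolling-window minimum background
#' estimate is stored in the profile metadata.
#'
#' @param images a matrix or named list of matrices (one per channel),
#'   rows/columns in pixel units.
#' @param pixelNm physical pixel size (nm).
#' @param start,end line endpoints as \code{c(row, col)}, 1-based pixel
#'   coordinates.
#' @param widthPx number of perpendicular samples to average (>= 1).
#' @param backgroundWindowPx rolling-minimum window for the background
#'   estimate (default 51).
#' @return an [IntensityProfile-class]; positions are arc length (nm) from
#'   \code{start}.
#' @export
extractLineProfile <- function(images, pixelNm, start, end, widthPx = 1L,
                               backgroundWindowPx = 51L) {
  if (is.matrix(images)) images <- list(intensity = images)
  stopifnot(widthPx >= 1L)
  dims <- dim(images[[1L]])
  v <- c(end[1L] - start[1L], end[2L] - start[2L])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("line endpoints coincide")
  u <- v / len                      # unit vector along the line
  pvec <- c(-u[2L], u[1L])          # perpendicular unit vector
  ts <- seq(0, len, by = 1)
  offs <- seq_len(widthPx) - (widthPx + 1) / 2
  samplePts <- function(t) {
    r <- start[1L] + t * u[1L] + offs * pvec[1L]
    c <- start[2L] + t * u[2L] + offs * pvec[2L]
    cbind(r, c)
  }
  allPts <- do.call(rbind, lapply(ts, samplePts))
  if (any(allPts[, 1L] < 1 - 1e-9) || any(allPts[, 1L] > dims[1L] + 1e-9) ||
      any(allPts[, 2L] < 1 - 1e-9) || any(allPts[, 2L] > dims[2L] + 1e-9))
    stop("line (with its width) exits the image bounds")
  bilinear <- function(m, r, c) {
    r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
    r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
    fr <- r - r0; fc <- c - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
      m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  }
  channels <- lapply(images, function(m) {
    vals <- bilinear(m, allPts[, 1L], allPts[, 2L])
    rowMeans(matrix(vals, ncol = widthPx, byrow = TRUE))
  })
  bg <- lapply(channels, function(ch) .rollingMin(ch, backgroundWindowPx))
  new("IntensityProfile",
      positionsNm = ts * pixelNm,
      channels = channels,
      metadata = list(pixel_nm = pixelNm, source = "extractLineProfile",
                      width_px = widthPx, background = bg))
}

.rollingMin <- function(y, k) {
  n <- length(y)
  half <- k %/% 2L
  vapply(seq_len(n), function(i)
    min(y[max(1L, i - half):min(n, i + half)]), 0)
}
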