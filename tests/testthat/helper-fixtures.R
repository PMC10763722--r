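# Shared fixtures and independent oracles, built in code at test time.

# Natural amino-acid composition (UniProtKB/Swiss-Prot frequencies); random
# sequences drawn from it have a realistic mean residue mass (~111 Da).
aaNaturalFreq <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
  E = 0.0675, Q = 0.0393, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0657, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

randomProteinSequence <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(names(aaNaturalFreq), n, replace = TRUE,
               prob = aaNaturalFreq), collapse = "")
}

# Noiseless sum-of-Gaussians profile on a uniform grid: the independent
# construction used to feed the fitter known peaks.
makeGaussianProfile <- function(peaks, xmin = 0, xmax = 2000, pixel = 10,
                                baseline = 0, channel = "mir") {
  x <- seq(xmin, xmax, by = pixel)
  y <- rep(baseline, length(x))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$fwhm[i] / (2 * sqrt(2 * log(2)))
    y <- y + peaks$height[i] * exp(-(x - peaks$center[i])^2 / (2 * s^2))
  }
  chans <- list(y)
  names(chans) <- channel
  new("IntensityProfile", positionsNm = x, channels = chans,
      metadata = list(pixel_nm = pixel, source = "test"))
}

# Two-channel noiseless profile placed at the exact generative layout of a
# genotype, for end-to-end exactness tests.
makeLayoutProfile <- function(params, slUm, nSarc = 3, fwhm = 40,
                              height = 100, pixel = 10) {
  slNm <- slUm * 1000
  mir <- data.frame(center = numeric(), height = numeric(), fwhm = numeric())
  a170 <- mir
  for (k in seq_len(nSarc)) {
    lay <- expectedPositions(params, slUm, originNm = (k - 1) * slNm)
    mir <- rbind(mir, data.frame(center = lay@mirFullNm, height = height,
                                 fwhm = fwhm))
    a170 <- rbind(a170, data.frame(center = lay@a170PositionsNm,
                                   height = height, fwhm = fwhm))
  }
  x <- seq(-slNm / 2, nSarc * slNm + slNm / 2, by = pixel)
  render <- function(pk) {
    y <- numeric(length(x))
    for (i in seq_len(nrow(pk))) {
      s <- pk$fwhm[i] / (2 * sqrt(2 * log(2)))
      y <- y + pk$height[i] * exp(-(x - pk$center[i])^2 / (2 * s^2))
    }
    y
  }
  new("IntensityProfile", positionsNm = x,
      channels = list(mir = render(mir), a170 = render(a170)),
      metadata = list(pixel_nm = pixel, source = "test",
                      genotype = params@label, sl_nominal_um = slUm))
}

# Synthetic peak tables for grammar tests (bypassing the fitter).
peakTable <- function(centers, channel, height = 100, fwhm = 45) {
  data.frame(channel = channel, center_nm = centers, height = height,
             fwhm_nm = fwhm, center_se_nm = 0.1, baseline = 0, flag = "")
}

# Small cohort TSV written to a temp file.
writeCohortTsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
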