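# Generative kinematic model of anti-titin epitope positions versus
# sarcomere length and genotype. Purely affine: no force-extension mechanics.

.GENOTYPE_DEFAULTS <- list(
  TTNTV_NEG = list(
    abandLenSlackNm = 1400, abandSlopeNmPerUm = 236,
    dtkSlackNm = 70, dtkSlopeNmPerUm = 25,
    truncFraction = 0, truncMirShiftSlackNm = 0, truncShiftRelaxNmPerUm = 0
  ),
  TTNTV_POS = list(
    abandLenSlackNm = 1400, abandSlopeNmPerUm = 150,
    dtkSlackNm = 80, dtkSlopeNmPerUm = -12,
    truncFraction = 0.5, truncMirShiftSlackNm = 30, truncShiftRelaxNmPerUm = 35
  ),
  CONTROL = list(
    abandLenSlackNm = 1444, abandSlopeNmPerUm = 236,
    dtkSlackNm = 70, dtkSlopeNmPerUm = 0,
    truncFraction = 0, truncMirShiftSlackNm = 0, truncShiftRelaxNmPerUm = 0
  )
)

.SLACK_SL_UM <- 1.8
.SL_RANGE_UM <- c(1.6, 3.0)

#' Genotype parameter sets for the sarcomere geometry model
#'
#' Returns the default parameter set for a genotype label, with any field
#' overridable. Defaults (all lengths nm, slopes nm per um of SL, slack
#' reference SL 1.8 um):
#' \itemize{
#'   \item \code{TTNTV_NEG}: A-band titin length 1,400 + 236/um; M-to-TK
#'     70 + 25/um (a 20 nm rise over the 1.8-2.6 um range); no truncation.
#'   \item \code{TTNTV_POS}: half of the molecules truncated (heterozygous,
#'     3 of 6 per half thick filament on average); M-to-TK starts 10 nm
#'     further from the M-line (80 nm) and closes with stretch (-12/um);
#'     A-band lengthening is blunted (150/um); truncated-molecule MIR
#'     epitopes sit 30 nm further Z-ward at slack, a displacement that
#'     relaxes by 35 nm/um of stretch (clamped at zero).
#'   \item \code{CONTROL}: M-to-TK flat (slope 0); A-band titin length
#'     offset +44 nm (1,444 nm at slack).
#' }
#'
#' @param label \code{"TTNTV_NEG"}, \code{"TTNTV_POS"} or \code{"CONTROL"}.
#' @param ... named overrides of any [GenotypeParams-class] field (e.g.
#'   \code{truncFraction = 0.3}).
#' @return a validated [GenotypeParams-class] object.
#' @examples
#' genotypeParams("TTNTV_NEG")
#' genotypeParams("TTNTV_POS", truncFraction = 0.25)
#' @export
genotypeParams <- function(label = c("TTNTV_NEG", "TTNTV_POS", "CONTROL"),
                           ...) {
  label <- match.arg(label)
  p <- .GENOTYPE_DEFAULTS[[label]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown GenotypeParams field(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  new("GenotypeParams", label = label,
      abandLenSlackNm = p$abandLenSlackNm,
      abandSlopeNmPerUm = p$abandSlopeNmPerUm,
      dtkSlackNm = p$dtkSlackNm,
      dtkSlopeNmPerUm = p$dtkSlopeNmPerUm,
      truncFraction = p$truncFraction,
      truncMirShiftSlackNm = p$truncMirShiftSlackNm,
      truncShiftRelaxNmPerUm = p$truncShiftRelaxNmPerUm)
}

# Affine submodels, exposed for oracles and the simulator.

#' A-band titin length (nm) at a sarcomere length
#' @param params a [GenotypeParams-class].
#' @param slUm sarcomere length in um (vectorised).
#' @export
abandLengthAt <- function(params, slUm) {
  params@abandLenSlackNm + params@abandSlopeNmPerUm * (slUm - .SLACK_SL_UM)
}

#' M-line-to-titin-kinase distance (nm) at a sarcomere length
#' @inheritParams abandLengthAt
#' @export
dtkAt <- function(params, slUm) {
  params@dtkSlackNm + params@dtkSlopeNmPerUm * (slUm - .SLACK_SL_UM)
}

#' Z-ward displacement (nm) of truncated-molecule MIR epitopes
#'
#' Non-negative and non-increasing in SL: \code{max(0, slack - relax *
#' (SL - 1.8))}.
#' @inheritParams abandLengthAt
#' @export
truncMirShiftAt <- function(params, slUm) {
  pmax(0, params@truncMirShiftSlackNm -
         params@truncShiftRelaxNmPerUm * (slUm - .SLACK_SL_UM))
}

#' Expected epitope layout of one sarcomere
#'
#' Places the Z-disks at 0 and SL, the M-line at SL/2, full-length MIR
#' epitopes at M +/- L_A(SL)/2, A170 epitopes at M +/- d_TK(SL), and (for
#' genotypes with a truncated fraction) truncated-molecule MIR epitopes
#' displaced Z-ward from the full-length MIR positions. Exactly
#' mirror-symmetric about the M-line.
#'
#' @param params a [GenotypeParams-class].
#' @param slUm sarcomere length in micrometres, within [1.6, 3.0].
#' @param originNm axial position (nm) of the left Z-disk (default 0).
#' @return an [EpitopeLayout-class].
#' @examples
#' lay <- expectedPositions(genotypeParams("TTNTV_NEG"), 1.8)
#' a170Separation(lay)  # 140 nm
#' @export
expectedPositions <- function(params, slUm, originNm = 0) {
  stopifnot(is(params, "GenotypeParams"))
  if (length(slUm) != 1L || is.na(slUm) ||
      slUm < .SL_RANGE_UM[1L] || slUm > .SL_RANGE_UM[2L])
    stop(sprintf("sarcomere length must lie in [%.1f, %.1f] um",
                 .SL_RANGE_UM[1L], .SL_RANGE_UM[2L]))
  slNm <- slUm * 1000
  la <- abandLengthAt(params, slUm)
  if (la >= slNm)
    stop(sprintf(
      "model error: A-band titin length (%.0f nm) >= sarcomere length (%.0f nm)",
      la, slNm))
  dk <- dtkAt(params, slUm)
  m <- originNm + slNm / 2
  mirFull <- c(m - la / 2, m + la / 2)
  mirTrunc <- numeric()
  if (params@truncFraction > 0) {
    shift <- truncMirShiftAt(params, slUm)
    # Z-ward: away from the M-line on both sides
    mirTrunc <- c(mirFull[1L] - shift, mirFull[2L] + shift)
  }
  new("EpitopeLayout",
      slNm = slNm,
      zPositionsNm = c(originNm, originNm + slNm),
      mPositionNm = m,
      mirFullNm = mirFull,
      mirTruncNm = mirTrunc,
      a170PositionsNm = c(m - dk, m + dk))
}
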