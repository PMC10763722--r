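#' @import methods
NULL

# ---------------------------------------------------------------------------
# TitinIsoformModel
# ---------------------------------------------------------------------------

#' Residue-coordinate model of a titin isoform
#'
#' Maps the primary structure of a titin isoform (by default the IC isoform,
#' 35,991 residues) onto sarcomeric band regions and antibody epitope ranges.
#' Region intervals are inclusive integer ranges \code{[first, last]} that are
#' contiguous, non-overlapping and jointly cover every residue exactly once;
#' a boundary residue belongs to the region whose interval contains it (the
#' earlier region, since intervals do not share residues).
#'
#' @slot totalResidues integer(1). Number of residues in the isoform.
#' @slot regions data.frame with columns \code{label}, \code{first},
#'   \code{last}; ordered, contiguous, covering \code{1..totalResidues}.
#' @slot epitopes data.frame with columns \code{name}, \code{first},
#'   \code{last}; each range must lie inside exactly one region.
#' @slot sequence character(0) or character(1); optional one-letter amino
#'   acid sequence of length \code{totalResidues}.
#'
#' @seealso [titinIsoformModel()], [defaultTitinModel()],
#'   [classifyVariantRegion()], [predictTruncatedMass()]
#' @exportClass TitinIsoformModel
setClass("TitinIsoformModel",
  representation(
    totalResidues = "integer",
    regions = "data.frame",
    epitopes = "data.frame",
    sequence = "character"
  )
)

setValidity("TitinIsoformModel", function(object) {
  msgs <- character()
  n <- object@totalResidues
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("totalResidues must be a single positive integer")
  r <- object@regions
  if (!all(c("label", "first", "last") %in% names(r)))
    return("regions must have columns label, first, last")
  if (nrow(r) < 1L) return("at least one region is required")
  if (r$first[1L] != 1L)
    msgs <- c(msgs, "first region must start at residue 1")
  if (r$last[nrow(r)] != n)
    msgs <- c(msgs, sprintf("last region must end at residue %d", n))
  if (any(r$last < r$first))
    msgs <- c(msgs, "region intervals must satisfy first <= last")
  if (nrow(r) > 1L && any(r$first[-1L] != r$last[-nrow(r)] + 1L))
    msgs <- c(msgs, "regions must be contiguous and non-overlapping")
  e <- object@epitopes
  if (nrow(e) > 0L) {
    if (!all(c("name", "first", "last") %in% names(e)))
      return("epitopes must have columns name, first, last")
    for (i in seq_len(nrow(e))) {
      hit <- which(r$first <= e$first[i] & e$last[i] <= r$last)
      if (length(hit) != 1L)
        msgs <- c(msgs, sprintf(
          "epitope '%s' (%d-%d) does not lie inside exactly one region",
          e$name[i], e$first[i], e$last[i]))
    }
  }
  if (length(object@sequence) > 1L)
    msgs <- c(msgs, "sequence must be absent or a single string")
  if (length(object@sequence) == 1L && nchar(object@sequence) != n)
    msgs <- c(msgs, sprintf("sequence length (%d) != totalResidues (%d)",
                            nchar(object@sequence), n))
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TitinIsoformModel", function(object) {
  cat("TitinIsoformModel:", object@totalResidues, "residues\n")
  r <- object@regions
  cat("regions:\n")
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-14s %6d - %6d\n", r$label[i], r$first[i], r$last[i]))
  if (nrow(object@epitopes))
    cat("epitopes:", paste(object@epitopes$name, collapse = ", "), "\n")
  cat("sequence:", if (length(object@sequence)) "present" else "absent", "\n")
})

#' @describeIn TitinIsoformModel total number of residues in the isoform.
#' @param model a \code{TitinIsoformModel}.
#' @export
totalResidues <- function(model) model@totalResidues

#' @describeIn TitinIsoformModel region table (label, first, last).
#' @export
regionTable <- function(model) model@regions

#' @describeIn TitinIsoformModel epitope table (name, first, last).
#' @export
epitopeTable <- function(model) model@epitopes

# ---------------------------------------------------------------------------
# GenotypeParams
# ---------------------------------------------------------------------------

#' Genotype-level parameters of the sarcomere epitope geometry model
#'
#' Kinematic (affine-in-sarcomere-length) model of where the MIR (I/A
#' junction) and A170 (titin kinase region) anti-titin epitopes sit along
#' the half-sarcomere, and how truncated titin molecules are displaced.
#' All lengths in nm; slopes in nm per micrometre of sarcomere length (SL);
#' slack reference SL is 1.8 um.
#'
#' @slot label character(1): one of \code{"TTNTV_NEG"}, \code{"TTNTV_POS"},
#'   \code{"CONTROL"}.
#' @slot abandLenSlackNm A-band titin length (MIR-to-MIR) at SL 1.8 um.
#' @slot abandSlopeNmPerUm change of A-band titin length per um SL.
#' @slot dtkSlackNm M-line-to-titin-kinase distance at SL 1.8 um.
#' @slot dtkSlopeNmPerUm change of the M-to-TK distance per um SL.
#' @slot truncFraction fraction of molecules that are truncated (0 for
#'   TTNTV_NEG and CONTROL).
#' @slot truncMirShiftSlackNm extra Z-ward displacement of truncated-molecule
#'   MIR epitopes at slack.
#' @slot truncShiftRelaxNmPerUm rate at which that displacement closes with
#'   stretch; the shift is clamped at zero.
#'
#' @seealso [genotypeParams()], [expectedPositions()]
#' @exportClass GenotypeParams
setClass("GenotypeParams",
  representation(
    label = "character",
    abandLenSlackNm = "numeric",
    abandSlopeNmPerUm = "numeric",
    dtkSlackNm = "numeric",
    dtkSlopeNmPerUm = "numeric",
    truncFraction = "numeric",
    truncMirShiftSlackNm = "numeric",
    truncShiftRelaxNmPerUm = "numeric"
  )
)

setValidity("GenotypeParams", function(object) {
  msgs <- character()
  if (!object@label %in% c("TTNTV_NEG", "TTNTV_POS", "CONTROL"))
    msgs <- c(msgs, "label must be TTNTV_NEG, TTNTV_POS or CONTROL")
  for (s in c("abandLenSlackNm", "dtkSlackNm", "truncMirShiftSlackNm")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < 0)
      msgs <- c(msgs, paste(s, "must be a single non-negative number"))
  }
  tf <- object@truncFraction
  if (length(tf) != 1L || is.na(tf) || tf < 0 || tf > 1)
    msgs <- c(msgs, "truncFraction must lie in [0, 1]")
  if (object@label %in% c("TTNTV_NEG", "CONTROL") && isTRUE(tf > 0))
    msgs <- c(msgs, "truncFraction must be 0 for TTNTV_NEG and CONTROL")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenotypeParams", function(object) {
  cat(sprintf(
    paste0("GenotypeParams '%s': A-band len %.0f nm + %.0f nm/um, ",
           "M-to-TK %.0f nm %+.0f nm/um, trunc fraction %.2f\n"),
    object@label, object@abandLenSlackNm, object@abandSlopeNmPerUm,
    object@dtkSlackNm, object@dtkSlopeNmPerUm, object@truncFraction))
})

# ---------------------------------------------------------------------------
# EpitopeLayout
# ---------------------------------------------------------------------------

#' Expected epitope positions of one sarcomere at a given length
#'
#' Noise-free axial positions (nm) of the Z-disks, M-line, MIR and A170
#' epitope bands for a single sarcomere, as produced by
#' [expectedPositions()]. The layout is mirror-symmetric about the M-line;
#' truncated-molecule MIR positions are present only when the genotype
#' carries a non-zero truncated fraction.
#'
#' @slot slNm sarcomere length in nm.
#' @slot zPositionsNm numeric(2): left/right Z-disk positions.
#' @slot mPositionNm numeric(1): M-line position.
#' @slot mirFullNm numeric(2): full-length-molecule MIR band positions.
#' @slot mirTruncNm numeric(2) or numeric(0): truncated-molecule MIR bands.
#' @slot a170PositionsNm numeric(2): A170 band positions (full-length only).
#' @exportClass EpitopeLayout
setClass("EpitopeLayout",
  representation(
    slNm = "numeric",
    zPositionsNm = "numeric",
    mPositionNm = "numeric",
    mirFullNm = "numeric",
    mirTruncNm = "numeric",
    a170PositionsNm = "numeric"
  )
)

setValidity("EpitopeLayout", function(object) {
  msgs <- character()
  tol <- 1e-6
  m <- object@mPositionNm
  if (abs(diff(object@zPositionsNm) - object@slNm) > tol)
    msgs <- c(msgs, "Z-to-Z distance must equal the sarcomere length")
  symm <- function(p, what) {
    if (length(p) == 2L && abs((m - p[1L]) - (p[2L] - m)) > tol)
      sprintf("%s pair is not mirror-symmetric about the M-line", what)
  }
  msgs <- c(msgs,
            symm(object@zPositionsNm, "Z"),
            symm(object@mirFullNm, "MIR"),
            symm(object@a170PositionsNm, "A170"))
  if (length(object@mirTruncNm) == 2L)
    msgs <- c(msgs, symm(object@mirTruncNm, "truncated MIR"))
  msgs <- msgs[!vapply(msgs, is.null, logical(1L))]
  if (length(msgs)) unlist(msgs) else TRUE
})

setMethod("show", "EpitopeLayout", function(object) {
  cat(sprintf("EpitopeLayout @ SL %.0f nm: M %.1f, MIR %.1f/%.1f, A170 %.1f/%.1f\n",
              object@slNm, object@mPositionNm,
              object@mirFullNm[1L], object@mirFullNm[2L],
              object@a170PositionsNm[1L], object@a170PositionsNm[2L]))
  if (length(object@mirTruncNm) == 2L)
    cat(sprintf("  truncated MIR %.1f/%.1f\n",
                object@mirTruncNm[1L], object@mirTruncNm[2L]))
})

#' @describeIn EpitopeLayout A170 doublet separation (nm).
#' @param layout an \code{EpitopeLayout}.
#' @export
a170Separation <- function(layout) diff(layout@a170PositionsNm)

#' @describeIn EpitopeLayout M-line-to-TK distance, i.e. half the A170
#'   doublet separation (nm).
#' @export
dtk <- function(layout) diff(layout@a170PositionsNm) / 2

#' @describeIn EpitopeLayout A-band titin length, i.e. the MIR-to-MIR
#'   distance of full-length molecules (nm).
#' @export
abandTitinLength <- function(layout) diff(layout@mirFullNm)

# ---------------------------------------------------------------------------
# IntensityProfile
# ---------------------------------------------------------------------------

#' Two-channel 1D fluorescence intensity profile
#'
#' A uniform axial position grid (nm) with one intensity trace per channel
#' (conventionally \code{"mir"} and \code{"a170"}).
#'
#' @slot positionsNm strictly increasing, uniformly spaced grid (nm).
#' @slot channels named list of numeric vectors, one per channel, each the
#'   same length as the grid.
#' @slot metadata list; at least \code{pixel_nm} and \code{source}.
#' @seealso [simulateProfile()], [detectAndFitPeaks()], [readProfileCsv()]
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(
    positionsNm = "numeric",
    channels = "list",
    metadata = "list"
  )
)

setValidity("IntensityProfile", function(object) {
  msgs <- character()
  x <- object@positionsNm
  if (length(x) < 2L) return("position grid needs at least 2 samples")
  d <- diff(x)
  if (any(d <= 0)) msgs <- c(msgs, "position grid must be strictly increasing")
  if (max(abs(d - d[1L])) > 1e-6 * abs(d[1L]))
    msgs <- c(msgs, "position grid must be uniformly spaced")
  if (length(object@channels) < 1L || is.null(names(object@channels)) ||
      any(!nzchar(names(object@channels))))
    msgs <- c(msgs, "channels must be a non-empty named list")
  bad <- vapply(object@channels, function(ch) length(ch) != length(x), logical(1L))
  if (any(bad))
    msgs <- c(msgs, "every channel must have the same length as the grid")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d samples, %.1f-%.1f nm (pixel %.1f nm), channels: %s\n",
              length(object@positionsNm), min(object@positionsNm),
              max(object@positionsNm), diff(object@positionsNm[1:2]),
              paste(names(object@channels), collapse = ", ")))
})

#' @describeIn IntensityProfile position grid in nm.
#' @param profile an \code{IntensityProfile}.
#' @export
positionsNm <- function(profile) profile@positionsNm

#' @describeIn IntensityProfile channel names.
#' @export
channelNames <- function(profile) names(profile@channels)

#' @describeIn IntensityProfile one channel's intensity trace.
#' @param channel channel name.
#' @export
channelIntensity <- function(profile, channel) {
  if (!channel %in% names(profile@channels))
    stop("unknown channel '", channel, "'; available: ",
         paste(names(profile@channels), collapse = ", "))
  profile@channels[[channel]]
}

#' @describeIn IntensityProfile pixel size of the grid in nm.
#' @export
pixelNm <- function(profile) diff(profile@positionsNm[1:2])

# ---------------------------------------------------------------------------
# GelLaneProfile
# ---------------------------------------------------------------------------

#' Densitometric gel lane trace
#'
#' Optical density versus migration distance for one SDS-agarose lane.
#'
#' @slot migrationMm uniform, strictly increasing grid (mm).
#' @slot od optical density values, same length as the grid.
#' @slot laneId character(1) lane identifier.
#' @seealso [simulateGelLane()], [quantifyLane()]
#' @exportClass GelLaneProfile
setClass("GelLaneProfile",
  representation(
    migrationMm = "numeric",
    od = "numeric",
    laneId = "character"
  )
)

setValidity("GelLaneProfile", function(object) {
  msgs <- character()
  x <- object@migrationMm
  if (length(x) < 2L) return("migration grid needs at least 2 samples")
  d <- diff(x)
  if (any(d <= 0)) msgs <- c(msgs, "migration grid must be strictly increasing")
  if (max(abs(d - d[1L])) > 1e-6 * abs(d[1L]))
    msgs <- c(msgs, "migration grid must be uniformly spaced")
  if (length(object@od) != length(x))
    msgs <- c(msgs, "od must have the same length as the migration grid")
  if (any(!is.finite(object@od)))
    msgs <- c(msgs, "od values must be finite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GelLaneProfile", function(object) {
  cat(sprintf("GelLaneProfile '%s': %d samples, %.1f-%.1f mm, OD max %.3f\n",
              object@laneId, length(object@migrationMm),
              min(object@migrationMm), max(object@migrationMm),
              max(object@od)))
})

# ---------------------------------------------------------------------------
# MobilityCalibration
# ---------------------------------------------------------------------------

#' Gel mobility calibration (migration vs log10 molecular weight)
#'
#' Least-squares line \code{migration = intercept + slope * log10(MW_kDa)}
#' fitted to molecular-weight standards; invertible in both directions.
#'
#' @slot intercept numeric(1), mm.
#' @slot slope numeric(1), mm per decade of MW (negative for ordinary gels).
#' @slot standards data.frame of the standards used (mw_kda, migration_mm).
#' @seealso [calibrateMobility()], [mwToMigration()], [migrationToMw()]
#' @exportClass MobilityCalibration
setClass("MobilityCalibration",
  representation(
    intercept = "numeric",
    slope = "numeric",
    standards = "data.frame"
  )
)

setValidity("MobilityCalibration", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope == 0)
    "slope must be a single non-zero number" else TRUE
})

setMethod("show", "MobilityCalibration", function(object) {
  cat(sprintf("MobilityCalibration: migration = %.2f %+.2f * log10(MW kDa)  (%d standards)\n",
              object@intercept, object@slope, nrow(object@standards)))
})
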