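# Residue-coordinate model of the titin IC isoform: region classification,
# consequence typing and truncated-protein mass prediction.

# Average (isotope-abundance weighted) residue masses in Da, monomer minus
# water, standard one-letter codes.
.AA_AVERAGE_MASS_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS_DA <- 18.02

#' Construct a titin isoform residue-coordinate model
#'
#' @param totalResidues number of residues of the isoform (default 35,991,
#'   the IC isoform).
#' @param regions data.frame with columns \code{label}, \code{first},
#'   \code{last}: ordered, contiguous inclusive intervals covering
#'   \code{1..totalResidues}. Defaults to the packaged band-region table
#'   (Z-disk, I-band, I/A junction, A-band, M-band) anchored to the antibody
#'   epitope residue ranges.
#' @param epitopes data.frame with columns \code{name}, \code{first},
#'   \code{last}; each range must lie inside exactly one region. Defaults to
#'   the T12, MIR, A170 and M8M10 antibody epitopes.
#' @param sequence optional one-letter amino-acid string of length
#'   \code{totalResidues}; enables sequence-based mass prediction.
#' @return a validated [TitinIsoformModel-class] object.
#' @examples
#' m <- titinIsoformModel()
#' classifyVariantRegion(m, 33600)
#' @export
titinIsoformModel <- function(totalResidues = 35991L,
                              regions = NULL,
                              epitopes = NULL,
                              sequence = character()) {
  if (is.null(regions) || is.null(epitopes)) {
    def <- .readIsoformFixture()
    if (is.null(regions)) regions <- def$regions
    if (is.null(epitopes)) epitopes <- def$epitopes
  }
  regions$first <- as.integer(regions$first)
  regions$last <- as.integer(regions$last)
  if (nrow(epitopes)) {
    epitopes$first <- as.integer(epitopes$first)
    epitopes$last <- as.integer(epitopes$last)
  }
  new("TitinIsoformModel",
      totalResidues = as.integer(totalResidues),
      regions = regions, epitopes = epitopes,
      sequence = as.character(sequence))
}

.readIsoformFixture <- function() {
  path <- system.file("extdata", "titin_isoform_ic.json",
                      package = "TitinScope", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(regions = as.data.frame(raw$regions),
       epitopes = as.data.frame(raw$epitopes))
}

#' Default titin IC isoform model
#'
#' Reads the packaged region/epitope fixture. Optionally attaches an isoform
#' sequence from a FASTA file.
#'
#' @param fasta optional path to a FASTA file holding the isoform sequence;
#'   the first record is used and must match \code{totalResidues}.
#' @return a [TitinIsoformModel-class].
#' @export
defaultTitinModel <- function(fasta = NULL) {
  seq <- character()
  if (!is.null(fasta)) seq <- readFastaSequence(fasta)
  titinIsoformModel(sequence = seq)
}

#' Read the first sequence of a FASTA file as a plain string
#'
#' Minimal reader for optional isoform sequences (single-record protein
#' FASTA); returns the concatenated upper-case residue string.
#'
#' @param path FASTA file path.
#' @return character(1).
#' @export
readFastaSequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("not a FASTA file: ", path)
  headers <- which(startsWith(lines, ">"))
  end <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
  toupper(paste(lines[2:end], collapse = ""))
}

#' Classify a titin residue into its sarcomeric band region
#'
#' Total over the valid residue domain: every residue belongs to exactly one
#' region of the model.
#'
#' @param model a [TitinIsoformModel-class].
#' @param residue 1-based residue index (vectorised).
#' @return character vector of region labels.
#' @examples
#' m <- titinIsoformModel()
#' classifyVariantRegion(m, c(33600, 35800))  # "A-band", "M-band"
#' @export
classifyVariantRegion <- function(model, residue) {
  stopifnot(is(model, "TitinIsoformModel"))
  residue <- as.numeric(residue)
  if (any(is.na(residue)) || any(residue < 1) ||
      any(residue > model@totalResidues) || any(residue != floor(residue)))
    stop(sprintf("residue out of range: valid interval is [1, %d]",
                 model@totalResidues))
  idx <- findInterval(residue, model@regions$first)
  model@regions$label[idx]
}

#' Predict the molecular mass of a truncated titin protein
#'
#' If the model carries a sequence, the mass is the sum of average residue
#' masses over residues \code{1..truncationResidue} plus one water;
#' otherwise the approximation \code{truncationResidue * meanResidueMassDa +
#' 18.02} Da is used. Strictly increasing in the truncation position.
#'
#' @param model a [TitinIsoformModel-class].
#' @param truncationResidue last translated residue (1-based, vectorised).
#' @param meanResidueMassDa mean residue mass for the approximate mode
#'   (default 111.1 Da, a typical protein average).
#' @return predicted mass in kDa.
#' @examples
#' m <- titinIsoformModel()
#' predictTruncatedMass(m, 10000)  # 1111.018 kDa
#' @export
predictTruncatedMass <- function(model, truncationResidue,
                                 meanResidueMassDa = 111.1) {
  stopifnot(is(model, "TitinIsoformModel"))
  r <- as.numeric(truncationResidue)
  if (any(is.na(r)) || any(r < 1) || any(r != floor(r)))
    stop("truncationResidue must be a positive integer (>= 1)")
  if (any(r > model@totalResidues))
    stop(sprintf("truncationResidue exceeds the isoform length (%d)",
                 model@totalResidues))
  if (length(model@sequence) == 1L) {
    masses <- residueMasses(model@sequence)
    cum <- cumsum(masses)
    (cum[r] + .WATER_MASS_DA) / 1000
  } else {
    (r * meanResidueMassDa + .WATER_MASS_DA) / 1000
  }
}

#' Per-residue average masses of an amino-acid string
#'
#' @param sequence one-letter amino-acid string.
#' @return numeric vector of average residue masses (Da), one per residue.
#' @export
residueMasses <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  m <- .AA_AVERAGE_MASS_DA[aa]
  if (any(is.na(m)))
    stop("unknown amino-acid code(s): ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Classify a variant consequence from an HGVS-protein-like description
#'
#' Pattern rules: \code{fs} anywhere marks a frameshift; a termination token
#' (\code{Ter}, \code{*} or trailing \code{X}) without a frameshift marks a
#' nonsense variant; splice-site keywords mark splice variants; anything
#' else is \code{other}.
#'
#' @param description HGVS protein notation (e.g. \code{"p.Arg17000Ter"}) or
#'   a keyword string; vectorised.
#' @return factor with levels frameshift, nonsense, splice, other.
#' @examples
#' classifyConsequence(c("p.Arg17000Ter", "p.Gly20000ValfsTer12"))
#' @export
classifyConsequence <- function(description) {
  description <- as.character(description)
  if (any(is.na(description)) || any(!nzchar(trimws(description))))
    stop("cannot classify an empty consequence description")
  d <- trimws(description)
  dl <- tolower(d)
  out <- rep("other", length(d))
  out[grepl("splice|splicing|[+-][12]\\s*$|donor|acceptor", dl)] <- "splice"
  nonsense <- grepl("Ter", d, fixed = TRUE) | grepl("\\*", d) |
    grepl("[A-Za-z]\\d+X$", d) | dl %in% c("nonsense", "stop_gained", "stop gained")
  out[nonsense] <- "nonsense"
  fs <- grepl("fs", d) | dl %in% c("frameshift", "frameshift_variant")
  out[fs] <- "frameshift"
  factor(out, levels = c("frameshift", "nonsense", "splice", "other"))
}

#' Map each epitope of a model to its band region
#'
#' @param model a [TitinIsoformModel-class].
#' @return named character vector, epitope name to region label.
#' @export
epitopeRegions <- function(model) {
  stopifnot(is(model, "TitinIsoformModel"))
  e <- model@epitopes
  out <- classifyVariantRegion(model, e$first)
  names(out) <- e$name
  out
}
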