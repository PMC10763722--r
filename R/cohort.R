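# Cohort-level ingestion of per-sample variant tables and the sample-level
# TTNtv / DCM-gene summaries.

#' Default DCM-associated gene set
#'
#' The dilated-cardiomyopathy genes used for the DCM-gene-positive count;
#' editable via the \code{dcmGenes} argument of [summarizeCohort()].
#'
#' @return character vector of gene symbols.
#' @export
dcmGeneDefaults <- function() {
  c("TTN", "LMNA", "DSP", "BAG3", "FKTN", "LAMA2", "MYBPC3",
    "MYH6", "MYH7", "PLN", "RBM20", "TNNI3")
}

.QUALIFYING_PATHOGENICITY <- c("pathogenic", "likely_pathogenic",
                               "novel_truncating")
.TRUNCATING_CONSEQUENCES <- c("frameshift", "nonsense", "splice")

#' Load a per-sample variant table (TSV)
#'
#' Expected header columns: \code{sample_id}, \code{gene},
#' \code{protein_position}, \code{consequence}, \code{pathogenicity}.
#' Variant-free samples may be listed with \code{gene = "."} (their row
#' contributes the sample but no variant). Rows failing validation are
#' reported with their line numbers; exact duplicate variant rows are
#' removed with a warning.
#'
#' @param path TSV file path.
#' @param samples optional character vector of all cohort sample ids
#'   (defaults to the ids present in the file).
#' @return list of class \code{cohortTable}: \code{samples} (character),
#'   \code{variants} (data.frame).
#' @export
loadVariantTable <- function(path, samples = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "gene", "protein_position", "consequence",
            "pathogenicity")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("variant table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  lineNo <- seq_len(nrow(raw)) + 1L   # 1-based file lines incl. header
  isSampleOnly <- raw$gene %in% c(".", "", NA)
  v <- raw[!isSampleOnly, , drop = FALSE]
  vLines <- lineNo[!isSampleOnly]
  pos <- suppressWarnings(as.integer(v$protein_position))
  badPos <- is.na(pos) & !(v$protein_position %in% c(".", "", "NA"))
  if (any(badPos))
    stop("row error: non-integer protein_position at line(s) ",
         paste(vLines[badPos], collapse = ", "))
  v$protein_position <- pos
  dup <- duplicated(v[, need])
  if (any(dup)) {
    warning(sum(dup), " duplicated variant row(s) removed (line(s) ",
            paste(vLines[dup], collapse = ", "), ")")
    v <- v[!dup, , drop = FALSE]
  }
  if (is.null(samples)) samples <- unique(raw$sample_id)
  unknown <- setdiff(v$sample_id, samples)
  if (length(unknown))
    stop("variant rows reference unknown sample id(s): ",
         paste(unique(unknown), collapse = ", "))
  rownames(v) <- NULL
  structure(list(samples = samples, variants = v), class = "cohortTable")
}

#' @export
print.cohortTable <- function(x, ...) {
  cat(sprintf("cohortTable: %d samples, %d variant rows\n",
              length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' Summarise a variant cohort at the sample level
#'
#' A sample counts as TTNtv-positive when it carries at least one TTN
#' variant with a truncating consequence (frameshift, nonsense or splice)
#' and qualifying pathogenicity (pathogenic, likely_pathogenic or
#' novel_truncating); it counts as DCM-gene-positive when it carries at
#' least one qualifying variant in the DCM gene set. Each sample is counted
#' at most once per category, whatever its number of variants, and the
#' summary is invariant to row order and row duplication.
#'
#' @param table a \code{cohortTable} from [loadVariantTable()].
#' @param dcmGenes DCM gene set (default [dcmGeneDefaults()]).
#' @param model optional [TitinIsoformModel-class]: when given, TTN variant
#'   band regions and predicted truncated masses are tabulated.
#' @return list of class \code{cohortSummary}: \code{n_samples},
#'   \code{n_ttntv_pos}, \code{pct_ttntv}, \code{n_dcm_gene_pos},
#'   \code{pct_dcm_gene}, \code{consequence_counts} (TTNtv carriers'
#'   truncating TTN variants), \code{per_gene_counts} (qualifying variants
#'   per DCM gene), and optionally \code{ttn_variant_detail}.
#' @export
summarizeCohort <- function(table, dcmGenes = dcmGeneDefaults(),
                            model = NULL) {
  stopifnot(inherits(table, "cohortTable"))
  if (!length(table$samples)) stop("empty cohort table")
  v <- table$variants
  v <- v[!duplicated(v[, c("sample_id", "gene", "protein_position",
                           "consequence", "pathogenicity")]), , drop = FALSE]
  nS <- length(table$samples)
  qual <- v$pathogenicity %in% .QUALIFYING_PATHOGENICITY
  cons <- as.character(classifyConsequence0(v$consequence))
  ttnTrunc <- v$gene == "TTN" & cons %in% .TRUNCATING_CONSEQUENCES & qual
  dcmQual <- v$gene %in% dcmGenes & qual
  ttnSamples <- unique(v$sample_id[ttnTrunc])
  dcmSamples <- unique(v$sample_id[dcmQual])
  consequenceCounts <- table(factor(cons[ttnTrunc],
                                    levels = c("frameshift", "nonsense",
                                               "splice")))
  perGene <- table(factor(v$gene[dcmQual], levels = sort(unique(
    v$gene[dcmQual]))))
  out <- list(
    n_samples = nS,
    n_ttntv_pos = length(ttnSamples),
    pct_ttntv = 100 * length(ttnSamples) / nS,
    n_dcm_gene_pos = length(dcmSamples),
    pct_dcm_gene = 100 * length(dcmSamples) / nS,
    consequence_counts = as.list(consequenceCounts),
    per_gene_counts = as.list(perGene),
    ttntv_samples = sort(ttnSamples))
  if (!is.null(model)) {
    tv <- v[ttnTrunc, , drop = FALSE]
    out$ttn_variant_detail <- data.frame(
      sample_id = tv$sample_id,
      protein_position = tv$protein_position,
      consequence = cons[ttnTrunc],
      region = classifyVariantRegion(model, tv$protein_position),
      predicted_mass_kda = predictTruncatedMass(model, tv$protein_position))
  }
  structure(out, class = "cohortSummary")
}

# consequence classifier tolerant of pre-classified labels
classifyConsequence0 <- function(x) {
  known <- c("frameshift", "nonsense", "splice", "other")
  x <- as.character(x)
  out <- character(length(x))
  pre <- tolower(x) %in% known
  out[pre] <- tolower(x)[pre]
  if (any(!pre)) out[!pre] <- as.character(classifyConsequence(x[!pre]))
  out
}

#' @export
print.cohortSummary <- function(x, ...) {
  cat(sprintf("cohortSummary: %d samples; TTNtv+ %d (%.1f%%); DCM-gene+ %d (%.1f%%)\n",
              x$n_samples, x$n_ttntv_pos, x$pct_ttntv,
              x$n_dcm_gene_pos, x$pct_dcm_gene))
  cc <- x$consequence_counts
  cat(sprintf("  TTN truncating consequences: %s\n",
              paste(names(cc), unlist(cc), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Path of the packaged synthetic DCM cohort fixture
#'
#' A synthetic stand-in variant table emulating the published cohort-level
#' counts (127 samples; 19 TTNtv carriers, 8 frameshift / 11 nonsense;
#' 35 DCM-gene-positive samples). Individual sample ids, positions and
#' non-headline assignments are fabricated.
#'
#' @return file path of the TSV.
#' @export
syntheticCohortPath <- function() {
  system.file("extdata", "dcm_cohort_synthetic.tsv",
              package = "TitinScope", mustWork = TRUE)
}
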