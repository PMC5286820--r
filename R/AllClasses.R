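#' @include AllGenerics.R
NULL

.ECOTYPES <- c("Col-0", "WS")
.ANGLES <- c(45L, 90L, 135L)
.CATEGORY_LEVELS <- c("I", "II", "III", "IV", "V", "VI",
                      "OTHER", "REMOVED_INHERENT", "NONE")

#' Set of traced roots
#'
#' Holds ordered 2-D root traces (one polyline per primary root, from the
#' position at gravistimulation to the tip) together with per-root metadata:
#' ecotype (Col-0 or WS), growth-plate angle (45, 90 or 135 degrees),
#' replicate and whether the image was taken through the media
#' (`view_flipped`, which mirrors the apparent x axis). Coordinates are in
#' mm on the plate face, with y increasing in the direction of gravity.
#'
#' @slot points named list of two-column numeric matrices, one per trace.
#' @slot traceData [S4Vectors::DataFrame] with columns `trace_id`,
#'   `ecotype`, `angle_gp`, `replicate`, `view_flipped`.
#' @seealso [RootTraceSet()] for construction, [morphoMetrics()].
#' @export
setClass("RootTraceSet",
         slots = c(points = "list", traceData = "DataFrame"))

setValidity("RootTraceSet", function(object) {
  td <- object@traceData
  need <- c("trace_id", "ecotype", "angle_gp", "replicate", "view_flipped")
  miss <- setdiff(need, colnames(td))
  if (length(miss))
    return(paste("traceData lacks columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(td$trace_id))
    return("duplicate trace_id")
  if (length(object@points) != nrow(td) ||
      !identical(names(object@points), as.character(td$trace_id)))
    return("points list must be named by trace_id, in traceData order")
  if (!all(td$ecotype %in% .ECOTYPES))
    return("ecotype must be one of Col-0, WS")
  if (!all(td$angle_gp %in% .ANGLES))
    return("angle_gp must be one of 45, 90, 135")
  for (i in seq_along(object@points)) {
    p <- object@points[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
      return(sprintf("trace '%s': points must be a 2-column numeric matrix",
                     names(object@points)[i]))
    if (nrow(p) < 2L)
      return(sprintf("trace '%s': fewer than 2 points", names(object@points)[i]))
    if (!all(is.finite(p)))
      return(sprintf("trace '%s': non-finite coordinates", names(object@points)[i]))
    seg <- sqrt(rowSums(diff(p)^2))
    if (any(seg == 0))
      return(sprintf("trace '%s': consecutive duplicate points", names(object@points)[i]))
  }
  TRUE
})

#' Expression study: log2 matrix bound to a factorial design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' (`"log2"`) holds gene x sample log2 intensities and whose `colData`
#' carries the factorial design: `ecotype` (Col-0 or WS), `angle_gp`
#' (growth-plate angle, 45/90/135 degrees) and `replicate`.
#'
#' @seealso [ExpressionStudy()] for construction, [contrastStats()],
#'   [comparisonMatrix()].
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2' is required")
  m <- SummarizedExperiment::assay(object, "log2")
  if (!all(is.finite(m)))
    return("expression values must be finite")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(c("ecotype", "angle_gp", "replicate"), colnames(cd))
  if (length(miss))
    return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
  if (!all(cd$ecotype %in% .ECOTYPES))
    return("ecotype must be one of Col-0, WS")
  if (!all(cd$angle_gp %in% .ANGLES))
    return("angle_gp must be one of 45, 90, 135")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    return("gene (row) names must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    return("sample (column) names must be present and unique")
  TRUE
})

#' Differential-expression result for one named contrast
#'
#' Per-gene statistics for a two-group comparison: log2 fold change (test
#' minus reference), (moderated) t statistic, two-sided p-value,
#' Benjamini-Hochberg q-value, and the significance calls `sig`
#' (|log2FC| > 1 and p < 0.05, both strict) and `sig_fdr` (`sig` and
#' q < 0.05).
#'
#' @slot contrastId character, e.g. `"WS_135_vs_90"`.
#' @slot testGroup,refGroup character labels of the compared groups.
#' @slot nTest,nRef integer group sizes.
#' @slot moderation list with elements `moderated`, `d0` (prior df),
#'   `s0sq` (prior variance) and `df` (total df of the t statistic).
#' @slot stats [S4Vectors::DataFrame] with row names = gene ids and columns
#'   `log2fc`, `t`, `p`, `q`, `sig`, `sig_fdr`, `direction`.
#' @seealso [contrastStats()], [callDE()].
#' @export
setClass("ContrastResult",
         slots = c(contrastId = "character", testGroup = "character",
                   refGroup = "character", nTest = "integer", nRef = "integer",
                   moderation = "list", stats = "DataFrame"))

setValidity("ContrastResult", function(object) {
  st <- object@stats
  need <- c("log2fc", "t", "p", "q", "sig", "sig_fdr", "direction")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    return(paste("stats lacks columns:", paste(miss, collapse = ", ")))
  if (is.null(rownames(st)) || anyDuplicated(rownames(st)))
    return("stats row names (gene ids) must be present and unique")
  bad <- st$sig & !(abs(st$log2fc) > 1 & st$p < 0.05)
  if (any(bad, na.rm = TRUE))
    return("sig flag inconsistent with |log2fc| > 1 & p < 0.05")
  if (any(st$sig_fdr & !st$sig, na.rm = TRUE))
    return("sig_fdr implies sig")
  TRUE
})

#' Candidate-gene report of the skew screening pipeline
#'
#' The end product of the pattern analysis: per-gene category assignments
#' (I-VI, OTHER, REMOVED_INHERENT, NONE), the physiology (within-WS
#' angle-responsive) and genotype (Categories IV-VI) candidate sets, their
#' overlap, and the highly probable skew gene candidates (HPSGC) anchored
#' at the 135 degree plate angle on both sides, with per-gene provenance.
#'
#' @slot categories [S4Vectors::DataFrame], one row per gene in the
#'   between-ecotype universe: significance flags and log2FCs at each angle
#'   plus the assigned `category`.
#' @slot physiology,genotype,overlap,hpsgc character vectors of gene ids.
#' @slot provenance [S4Vectors::DataFrame], one row per overlap gene:
#'   which within-WS contrasts and which category admitted it, and whether
#'   the 135-degree anchor held on each side.
#' @slot counts named list of count tables (per-contrast up/down/total,
#'   per-category sizes, Venn counts).
#' @seealso [candidateReport()], [overlapHpsgc()].
#' @export
setClass("CandidateReport",
         slots = c(categories = "DataFrame", physiology = "character",
                   genotype = "character", overlap = "character",
                   hpsgc = "character", provenance = "DataFrame",
                   counts = "list"))

setValidity("CandidateReport", function(object) {
  if (!all(object@hpsgc %in% object@overlap))
    return("hpsgc must be a subset of overlap")
  if (!all(object@overlap %in% object@physiology) ||
      !all(object@overlap %in% object@genotype))
    return("overlap must be a subset of both physiology and genotype sets")
  if (!"category" %in% colnames(object@categories))
    return("categories must have a 'category' column")
  if (!all(object@categories$category %in% .CATEGORY_LEVELS))
    return("unknown category label")
  TRUE
})
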