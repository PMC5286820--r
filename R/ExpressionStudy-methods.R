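#' @include AllClasses.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

#' Construct an ExpressionStudy
#'
#' @param values genes x samples numeric matrix of log2 intensities, with
#'   unique row (gene) and column (sample) names.
#' @param design data.frame or DataFrame, one row per sample (in column
#'   order of `values` or matched by a `sample_id` column), with columns
#'   `ecotype` (Col-0/WS), `angle_gp` (45/90/135) and `replicate`.
#' @return an [ExpressionStudy-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' des <- data.frame(ecotype = rep(c("Col-0", "WS"), each = 3),
#'                   angle_gp = 90, replicate = rep(1:3, 2))
#' ExpressionStudy(m, des)
#' @export
ExpressionStudy <- function(values, design) {
  values <- as.matrix(values)
  design <- as.data.frame(design)
  if ("sample_id" %in% colnames(design)) {
    if (!setequal(design$sample_id, colnames(values)))
      stop("design sample_id does not match matrix columns: ",
           paste(c(setdiff(colnames(values), design$sample_id),
                   setdiff(design$sample_id, colnames(values))), collapse = ", "))
    design <- design[match(colnames(values), design$sample_id), ]
  }
  if (nrow(design) != ncol(values))
    stop("design must have one row per sample column")
  cd <- S4Vectors::DataFrame(design, row.names = colnames(values))
  cd$angle_gp <- as.integer(cd$angle_gp)
  cd$replicate <- as.integer(cd$replicate)
  se <- SummarizedExperiment(assays = list(log2 = values), colData = cd)
  new("ExpressionStudy", se)
}

#' Log2 expression matrix of a study
#' @param study an [ExpressionStudy-class].
#' @return numeric matrix, genes x samples.
#' @export
exprValues <- function(study) assay(study, "log2")

#' Sample design table of a study
#' @param study an [ExpressionStudy-class].
#' @return data.frame with `sample_id`, `ecotype`, `angle_gp`, `replicate`.
#' @export
studyDesign <- function(study) {
  cd <- as.data.frame(colData(study))
  data.frame(sample_id = rownames(cd),
             cd[c("ecotype", "angle_gp", "replicate")], row.names = NULL)
}

#' Sample ids of one (ecotype, angle) cell
#' @param study an [ExpressionStudy-class].
#' @param ecotype `"Col-0"` or `"WS"`.
#' @param angle_gp growth-plate angle (45, 90 or 135).
#' @return character vector of sample ids.
#' @export
cellSamples <- function(study, ecotype, angle_gp) {
  cd <- colData(study)
  rownames(cd)[cd$ecotype == ecotype & cd$angle_gp == as.integer(angle_gp)]
}

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(colData(object)$ecotype, colData(object)$angle_gp)
  cat("replicates per (ecotype x angle_gp) cell:\n")
  print(tab)
  invisible(NULL)
})
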