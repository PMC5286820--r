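#' @include synthetic-data.R
#' @importFrom utils read.delim write.table
NULL

.readTable <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "#")
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read root traces from a long-format table
#'
#' Expects a TSV (or CSV, by extension) with header columns `trace_id`,
#' `ecotype`, `angle_gp`, `replicate`, `point_index`, `x_mm`, `y_mm` and
#' optionally `view_flipped`; points are ordered by `point_index` within
#' each trace.
#'
#' @param path file path.
#' @return a [RootTraceSet-class].
#' @export
readTraceTable <- function(path) {
  df <- .readTable(path)
  need <- c("trace_id", "ecotype", "angle_gp", "replicate", "point_index",
            "x_mm", "y_mm")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("trace table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("no traces in ", path)
  ids <- unique(df$trace_id)  # keep file order of first appearance
  pts <- lapply(ids, function(id) {
    d <- df[df$trace_id == id, ]
    d <- d[order(d$point_index), ]
    if (is.unsorted(d$point_index, strictly = TRUE))
      stop("trace '", id, "': point_index not strictly increasing")
    cbind(d$x_mm, d$y_mm)
  })
  names(pts) <- ids
  meta_cols <- intersect(c("trace_id", "ecotype", "angle_gp", "replicate",
                           "view_flipped"), colnames(df))
  td <- unique(df[meta_cols])
  if (nrow(td) != length(ids))
    stop("inconsistent per-trace metadata in ", path)
  RootTraceSet(pts, td)
}

#' Write root traces to a long-format TSV
#' @param traces a [RootTraceSet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTraceTable <- function(traces, path) {
  td <- as.data.frame(traceData(traces))
  rows <- lapply(seq_len(nrow(td)), function(i) {
    p <- tracePoints(traces)[[i]]
    data.frame(td[i, c("trace_id", "ecotype", "angle_gp", "replicate",
                       "view_flipped")],
               point_index = seq_len(nrow(p)), x_mm = p[, 1], y_mm = p[, 2],
               row.names = NULL)
  })
  .writeTSV(do.call(rbind, rows), path)
}

#' Read an expression study from matrix + design TSVs
#'
#' The matrix TSV has `gene_id` as its first column and one column per
#' sample; the design TSV has columns `sample_id`, `ecotype`, `angle_gp`,
#' `replicate`.
#'
#' @param matrix_path,design_path file paths.
#' @return an [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(matrix_path, design_path) {
  md <- .readTable(matrix_path)
  if (colnames(md)[1] != "gene_id")
    stop("expression matrix must have 'gene_id' as its first column")
  if (anyDuplicated(md$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(md$gene_id[duplicated(md$gene_id)]), collapse = ", "))
  m <- as.matrix(md[, -1, drop = FALSE])
  rownames(m) <- md$gene_id
  des <- .readTable(design_path)
  need <- c("sample_id", "ecotype", "angle_gp", "replicate")
  miss <- setdiff(need, colnames(des))
  if (length(miss))
    stop("design table lacks columns: ", paste(miss, collapse = ", "))
  ExpressionStudy(m, des)
}

#' Write an expression study to matrix + design TSVs
#' @param study an [ExpressionStudy-class].
#' @param matrix_path,design_path output files.
#' @return invisibly, the two paths.
#' @export
writeExpressionStudy <- function(study, matrix_path, design_path) {
  m <- exprValues(study)
  .writeTSV(data.frame(gene_id = rownames(m), m, check.names = FALSE),
            matrix_path)
  .writeTSV(studyDesign(study), design_path)
  invisible(c(matrix_path, design_path))
}

#' Write a contrast result to TSV
#'
#' One row per gene; the contrast id, group sizes and moderation
#' parameters are stored in `#`-prefixed header lines so the file
#' round-trips through [readContrastResult()].
#'
#' @param result a [ContrastResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeContrastResult <- function(result, path) {
  mod <- moderationParams(result)
  hdr <- c(paste0("#contrast_id=", contrastId(result)),
           paste0("#test_group=", result@testGroup),
           paste0("#ref_group=", result@refGroup),
           paste0("#n_test=", result@nTest), paste0("#n_ref=", result@nRef),
           paste0("#moderated=", mod$moderated),
           paste0("#d0=", format(mod$d0, digits = 17)),
           paste0("#s0_sq=", format(mod$s0_sq, digits = 17)),
           paste0("#df=", format(mod$df, digits = 17)))
  st <- as.data.frame(resultTable(result))
  df <- data.frame(gene_id = rownames(st), st, row.names = NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contrast result written by [writeContrastResult()]
#' @param path file path.
#' @return a [ContrastResult-class].
#' @export
readContrastResult <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  df <- .readTable(path)
  st <- S4Vectors::DataFrame(
    log2fc = as.numeric(df$log2fc), t = as.numeric(df$t),
    p = as.numeric(df$p), q = as.numeric(df$q),
    sig = as.logical(df$sig), sig_fdr = as.logical(df$sig_fdr),
    direction = as.character(df$direction), row.names = df$gene_id)
  new("ContrastResult", contrastId = unname(meta["contrast_id"]),
      testGroup = unname(meta["test_group"]),
      refGroup = unname(meta["ref_group"]),
      nTest = as.integer(meta["n_test"]), nRef = as.integer(meta["n_ref"]),
      moderation = list(moderated = as.logical(meta["moderated"]),
                        d0 = as.numeric(meta["d0"]),
                        s0_sq = as.numeric(meta["s0_sq"]),
                        df = as.numeric(meta["df"])),
      stats = st)
}

#' Read a GEO series-matrix file
#'
#' Parses the tab-delimited series-matrix format: `!`-prefixed metadata
#' lines, with the expression table between `!series_matrix_table_begin`
#' and `!series_matrix_table_end` (first column `ID_REF`, one column per
#' sample).
#'
#' @param path file path.
#' @return list with `values` (numeric matrix, probes x samples) and
#'   `metadata` (named list of the sample-level `!Sample_*` fields).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series matrix table found in ", path)
  tab <- read.delim(text = lines[(beg + 1L):(end - 1L)], header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "ID_REF")
    stop("series matrix table must start with ID_REF")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$ID_REF
  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  meta <- lapply(strsplit(meta_lines, "\t"), function(x)
    gsub('^"|"$', "", x[-1]))
  names(meta) <- sub("^!", "", vapply(strsplit(meta_lines, "\t"), `[`,
                                      character(1), 1L))
  list(values = m, metadata = meta)
}

#' Write a candidate report to files
#'
#' @param report a [CandidateReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: `categories.tsv` (per-gene
#'   pattern and category), `candidates.tsv` (overlap genes with
#'   provenance), `venn.json` (set sizes and per-contrast counts) and
#'   `heatmap_log2fc.tsv` (genes x between-contrasts log2FC matrix).
#' @export
writeCandidateReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("categories.tsv", "candidates.tsv", "venn.json",
                            "heatmap_log2fc.tsv"))
  .writeTSV(as.data.frame(categories(report)), paths[1])
  .writeTSV(as.data.frame(candidateProvenance(report)), paths[2])
  cnt <- candidateCounts(report)
  venn <- list(venn = as.list(cnt$venn),
               within_ws = as.list(cnt$within_ws),
               categories = stats::setNames(as.list(cnt$categories),
                                            cnt$category_names))
  if (!is.null(cnt$per_contrast)) venn$per_contrast <- cnt$per_contrast
  jsonlite::write_json(venn, paths[3], auto_unbox = TRUE, digits = NA)
  cats <- as.data.frame(categories(report))
  hm <- cats[c("gene_id", "fc45", "fc90", "fc135")]
  .writeTSV(hm[cats$category %in% c("I", "II", "III", "IV", "V", "VI"), ],
            paths[4])
  invisible(paths)
}
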