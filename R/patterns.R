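#' @include diffexpr.R
NULL

#' The seven-contrast comparison matrix
#'
#' Runs every contrast of the study design: within each ecotype, the tilted
#' plate angles against the vertical control (45 vs 90 and 135 vs 90), and
#' between ecotypes at each angle with WS as the reference (log2FC =
#' Col-0 minus WS). Within-ecotype contrast ids are
#' `"<ecotype>_45_vs_90"` / `"<ecotype>_135_vs_90"`; between-ecotype ids
#' are `"Col0_vs_WS_at_<angle>"`.
#'
#' @param study an [ExpressionStudy-class] with all six (ecotype x angle)
#'   cells at n >= 2.
#' @param moderated use the moderated t (default) or the ordinary pooled t.
#' @param fc_cut,p_cut,q_cut significance cutoffs passed to
#'   [contrastStats()].
#' @return a [ComparisonMatrix-class]: slots `within` (4 contrasts) and
#'   `between` (3 contrasts, named "45", "90", "135").
#' @export
comparisonMatrix <- function(study, moderated = TRUE, fc_cut = 1.0,
                             p_cut = 0.05, q_cut = 0.05) {
  stopifnot(is(study, "ExpressionStudy"))
  run <- function(test_eco, test_ang, ref_eco, ref_ang, id)
    contrastStats(study,
                  cellSamples(study, test_eco, test_ang),
                  cellSamples(study, ref_eco, ref_ang),
                  contrast_id = id, moderated = moderated,
                  fc_cut = fc_cut, p_cut = p_cut, q_cut = q_cut)
  within <- list()
  for (eco in .ECOTYPES) for (ang in c(45L, 135L)) {
    id <- paste0(sub("-", "", eco), "_", ang, "_vs_90")
    within[[id]] <- run(eco, ang, eco, 90L, id)
  }
  between <- list()
  for (ang in .ANGLES) {
    id <- paste0("Col0_vs_WS_at_", ang)
    between[[as.character(ang)]] <- run("Col-0", ang, "WS", ang, id)
  }
  new("ComparisonMatrix", within = within, between = between)
}

#' Seven within/between contrasts of one study
#'
#' @slot within named list of four within-ecotype [ContrastResult-class]
#'   objects (tilted angle vs the 90 degree control, per ecotype).
#' @slot between named list ("45", "90", "135") of Col-0 vs WS contrasts
#'   (WS = reference).
#' @export
setClass("ComparisonMatrix", slots = c(within = "list", between = "list"))

setValidity("ComparisonMatrix", function(object) {
  if (length(object@within) != 4L || length(object@between) != 3L)
    return("need 4 within- and 3 between-ecotype contrasts")
  if (!identical(names(object@between), c("45", "90", "135")))
    return("between contrasts must be named 45, 90, 135")
  all_cr <- c(object@within, object@between)
  if (!all(vapply(all_cr, is, logical(1), "ContrastResult")))
    return("all elements must be ContrastResult objects")
  uni <- rownames(resultTable(all_cr[[1]]))
  for (cr in all_cr[-1])
    if (!identical(rownames(resultTable(cr)), uni))
      return("gene universe differs across contrasts")
  TRUE
})

setMethod("show", "ComparisonMatrix", function(object) {
  cat("ComparisonMatrix:",
      length(rownames(resultTable(object@within[[1]]))), "genes\n")
  for (cr in c(object@within, object@between)) {
    st <- resultTable(cr)
    cat(sprintf("  %-18s %4d significant\n", contrastId(cr), sum(st$sig)))
  }
  invisible(NULL)
})

#' Set algebra of the within-ecotype angle-responsive gene sets
#'
#' Combines the DE sets of the two tilted angles of one ecotype: union
#' (all angle-responsive genes), intersection (shared between 45 and 135
#' degrees) and the per-angle unique sets, with counts.
#'
#' @param set45,set135 character vectors of gene ids (DE at 45 vs 90 and
#'   at 135 vs 90).
#' @return list with `union`, `shared`, `unique45`, `unique135` and a
#'   `counts` vector.
#' @examples
#' withinCandidates(c("a", "b", "c"), c("b", "d"))$counts
#' @export
withinCandidates <- function(set45, set135) {
  set45 <- unique(as.character(set45)); set135 <- unique(as.character(set135))
  u <- union(set45, set135)
  sh <- intersect(set45, set135)
  list(union = u, shared = sh,
       unique45 = setdiff(set45, set135),
       unique135 = setdiff(set135, set45),
       counts = c(n45 = length(set45), n135 = length(set135),
                  shared = length(sh), union = length(u)))
}

.betweenTable <- function(between, fc_cut = 1.0, p_cut = 0.05) {
  uni <- rownames(resultTable(between[["45"]]))
  out <- data.frame(gene_id = uni, row.names = uni)
  for (ang in c("45", "90", "135")) {
    st <- resultTable(between[[ang]])
    out[[paste0("fc", ang)]] <- st$log2fc
    out[[paste0("sig", ang)]] <- abs(st$log2fc) > fc_cut & st$p < p_cut
  }
  out
}

#' Inherent ecotype-difference filter
#'
#' Genes that differ between Col-0 and WS at all three plate angles by
#' near-equal magnitude are constitutive ecotype differences, not
#' angle-responsive, and are removed before pattern classification: a gene
#' is removed iff it is significant at all three angles, the three log2FCs
#' share one sign, and their span (max - min) does not exceed `span` log2
#' units.
#'
#' @param between named list ("45", "90", "135") of between-ecotype
#'   [ContrastResult-class] objects, or a [ComparisonMatrix-class].
#' @param span maximal log2FC span counted as "the same level" (default 1).
#' @param fc_cut,p_cut significance cutoffs.
#' @return character vector of removed gene ids.
#' @export
inherentFilter <- function(between, span = 1.0, fc_cut = 1.0, p_cut = 0.05) {
  if (is(between, "ComparisonMatrix")) between <- between@between
  if (span <= 0) stop("span must be positive")
  bt <- .betweenTable(between, fc_cut, p_cut)
  fcs <- as.matrix(bt[c("fc45", "fc90", "fc135")])
  all_sig <- bt$sig45 & bt$sig90 & bt$sig135
  same_sign <- apply(sign(fcs), 1L, function(s) all(s == s[1]))
  spans <- apply(fcs, 1L, function(v) max(v) - min(v))
  bt$gene_id[all_sig & same_sign & spans <= span]
}

#' Six-category expression-pattern classification
#'
#' Assigns every gene of the between-ecotype universe to one of the six
#' Col-0-vs-WS significance patterns across the plate angles
#' (45, 90, 135):
#' \itemize{
#'   \item I: significant at 90 only;
#'   \item II: 45 and 90, same direction;
#'   \item III: 90 and 135, same direction;
#'   \item IV: 45 only;
#'   \item V: 45 and 135, same direction;
#'   \item VI: 135 only;
#' }
#' plus `NONE` (nowhere significant), `REMOVED_INHERENT` (caught by
#' [inherentFilter()]) and `OTHER` (significant at all three angles but
#' escaping the filter, or a two-angle pattern with discordant directions).
#'
#' @inheritParams inherentFilter
#' @param removed gene ids removed by the inherent filter; computed from
#'   `between` when `NULL`.
#' @return data.frame, one row per gene: `gene_id`, per-angle `fc`/`sig`
#'   columns, and `category`.
#' @export
categorizeGenes <- function(between, removed = NULL, span = 1.0,
                            fc_cut = 1.0, p_cut = 0.05) {
  if (is(between, "ComparisonMatrix")) between <- between@between
  if (is.null(removed))
    removed <- inherentFilter(between, span = span, fc_cut = fc_cut,
                              p_cut = p_cut)
  bt <- .betweenTable(between, fc_cut, p_cut)
  pat <- function(s45, s90, s135, fc45, fc135, fc90) {
    key <- paste0(as.integer(s45), as.integer(s90), as.integer(s135))
    switch(key,
           "010" = "I",
           "110" = if (sign(fc45) == sign(fc90)) "II" else "OTHER",
           "011" = if (sign(fc90) == sign(fc135)) "III" else "OTHER",
           "100" = "IV",
           "101" = if (sign(fc45) == sign(fc135)) "V" else "OTHER",
           "001" = "VI",
           "000" = "NONE",
           "111" = "OTHER")
  }
  bt$category <- vapply(seq_len(nrow(bt)), function(i)
    pat(bt$sig45[i], bt$sig90[i], bt$sig135[i],
        bt$fc45[i], bt$fc135[i], bt$fc90[i]), character(1))
  bt$category[bt$gene_id %in% removed] <- "REMOVED_INHERENT"
  rownames(bt) <- NULL
  bt
}

#' Genotype-track candidate set: Categories IV, V and VI
#'
#' The union of the between-ecotype categories whose pattern implicates
#' skewing (significance only under tilted growth, or at both tilted
#' angles), with per-gene provenance.
#'
#' @param assignments data.frame from [categorizeGenes()].
#' @return data.frame with `gene_id` and `category` for genes in IV-VI.
#' @export
genotypeCandidates <- function(assignments) {
  keep <- assignments$category %in% c("IV", "V", "VI")
  assignments[keep, c("gene_id", "category")]
}

#' Overlap of the physiology and genotype candidate tracks, and HPSGC
#'
#' Intersects the within-WS angle-responsive set (physiology) with the
#' Categories IV-VI set (genotype) and extracts the highly probable skew
#' gene candidates (HPSGC): overlap genes whose evidence involves the
#' 135 degree plate angle on both sides, i.e. DE in WS at 135 vs 90 and in
#' Category V or VI (between-ecotype significance at 135).
#'
#' @param ws45,ws135 character vectors: within-WS DE gene sets at 45 vs 90
#'   and 135 vs 90.
#' @param assignments data.frame from [categorizeGenes()].
#' @return a [CandidateReport-class].
#' @export
overlapHpsgc <- function(ws45, ws135, assignments) {
  phys <- withinCandidates(ws45, ws135)
  geno <- genotypeCandidates(assignments)
  overlap <- intersect(phys$union, geno$gene_id)
  cat_of <- structure(assignments$category, names = assignments$gene_id)
  anchor <- overlap %in% ws135 & cat_of[overlap] %in% c("V", "VI")
  hpsgc <- overlap[anchor]
  prov <- S4Vectors::DataFrame(
    gene_id = overlap,
    in_ws45 = overlap %in% ws45,
    in_ws135 = overlap %in% ws135,
    category = unname(cat_of[overlap]),
    anchor_135 = unname(anchor),
    row.names = overlap)
  cat_sizes <- table(factor(assignments$category, levels = .CATEGORY_LEVELS))
  counts <- list(
    within_ws = withinCandidates(ws45, ws135)$counts,
    categories = as.vector(cat_sizes), category_names = names(cat_sizes),
    venn = c(physiology = length(phys$union), genotype = nrow(geno),
             overlap = length(overlap), hpsgc = length(hpsgc)))
  new("CandidateReport",
      categories = as(assignments, "DataFrame"),
      physiology = phys$union, genotype = geno$gene_id,
      overlap = overlap, hpsgc = hpsgc, provenance = prov, counts = counts)
}

#' End-to-end candidate screen from a comparison matrix
#'
#' Chains [inherentFilter()], [categorizeGenes()] and [overlapHpsgc()]:
#' within-WS DE sets form the physiology track, filtered between-ecotype
#' categories IV-VI the genotype track, and their intersection is narrowed
#' to the HPSGC by the 135-degree anchor.
#'
#' @param cm a [ComparisonMatrix-class].
#' @param span inherent-filter log2FC span (default 1).
#' @param fc_cut,p_cut significance cutoffs.
#' @return a [CandidateReport-class].
#' @examples
#' sim <- simulateExpression(exprSimConfig(n_genes = 300, seed = 7))
#' cm <- comparisonMatrix(sim$study)
#' candidateReport(cm)
#' @export
candidateReport <- function(cm, span = 1.0, fc_cut = 1.0, p_cut = 0.05) {
  stopifnot(is(cm, "ComparisonMatrix"))
  assignments <- categorizeGenes(cm@between, span = span, fc_cut = fc_cut,
                                 p_cut = p_cut)
  ws45 <- callDE(cm@within[["WS_45_vs_90"]], fc_cut, p_cut)$gene_id
  ws135 <- callDE(cm@within[["WS_135_vs_90"]], fc_cut, p_cut)$gene_id
  rep <- overlapHpsgc(ws45, ws135, assignments)
  rep@counts$per_contrast <- countSummary(cm, fc_cut = fc_cut, p_cut = p_cut)
  rep
}

#' Up/down/total counts per contrast
#'
#' @param cm a [ComparisonMatrix-class], or a named list of
#'   [ContrastResult-class] objects.
#' @param fc_cut,p_cut cutoffs (strict).
#' @return data.frame with `contrast`, `up`, `down`, `total`.
#' @export
countSummary <- function(cm, fc_cut = 1.0, p_cut = 0.05) {
  crs <- if (is(cm, "ComparisonMatrix")) c(cm@within, cm@between) else cm
  out <- do.call(rbind, lapply(crs, function(cr) {
    de <- callDE(cr, fc_cut, p_cut)
    data.frame(contrast = contrastId(cr),
               up = sum(de$direction == "up"),
               down = sum(de$direction == "down"),
               total = nrow(de))
  }))
  rownames(out) <- NULL
  out
}

#' @export
setMethod("categories", "CandidateReport", function(x) x@categories)

#' @export
setMethod("physiologySet", "CandidateReport", function(x) x@physiology)

#' @export
setMethod("genotypeSet", "CandidateReport", function(x) x@genotype)

#' @export
setMethod("overlapSet", "CandidateReport", function(x) x@overlap)

#' @export
setMethod("hpsgcSet", "CandidateReport", function(x) x@hpsgc)

#' Provenance of the overlap genes
#' @param x a [CandidateReport-class].
#' @return [S4Vectors::DataFrame], one row per overlap gene.
#' @export
candidateProvenance <- function(x) x@provenance

#' Count tables of a candidate report
#' @param x a [CandidateReport-class].
#' @return named list (within-WS counts, category sizes, Venn counts,
#'   per-contrast up/down/total when built via [candidateReport()]).
#' @export
candidateCounts <- function(x) x@counts

setMethod("show", "CandidateReport", function(object) {
  v <- object@counts$venn
  cat("CandidateReport:", nrow(object@categories), "genes in universe\n")
  cat(sprintf("  physiology (within-WS union): %d\n", v[["physiology"]]))
  cat(sprintf("  genotype (Categories IV-VI):  %d\n", v[["genotype"]]))
  cat(sprintf("  overlap:                      %d\n", v[["overlap"]]))
  cat(sprintf("  HPSGC (135-degree anchor):    %d\n", v[["hpsgc"]]))
  invisible(NULL)
})
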