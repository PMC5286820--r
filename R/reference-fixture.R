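#' @include patterns.R
NULL

# Printed per-gene anchors of the GSE83242 skewing study: the 11 HPSGC with
# their reported within-WS 135-vs-90 log2 fold changes, plus HIS1-3 (an
# overlap gene whose evidence fails the 135-degree anchor: Category IV).
.HPSGC_TABLE <- data.frame(
  gene_id = c("At4g26260", "At4g24890", "At3g47340", "At2g25150",
              "At5g02020", "At5g66780", "At3g28310", "At3g60140",
              "At4g35770", "At3g48740", "At4g10310"),
  symbol = c("MIOX4", "PAP24", "ASN1", "", "SIS", "", "", "DIN2",
             "SEN1", "SWEET11", "HKT1"),
  log2fc_ws135 = c(1.570, 1.414, 2.080, 1.839, 1.200, 1.556, 1.430,
                   2.214, 2.100, 1.804, 1.021),
  category = c("VI", "VI", "V", "VI", "VI", "VI", "VI", "VI", "VI",
               "V", "VI"))

.mkContrast <- function(id, gene_id, log2fc, sig) {
  p <- ifelse(sig, 1e-4, 0.5)
  q <- bhFdr(p)
  st <- S4Vectors::DataFrame(
    log2fc = log2fc, t = log2fc / 0.2, p = p, q = q,
    sig = abs(log2fc) > 1 & p < 0.05,
    sig_fdr = abs(log2fc) > 1 & p < 0.05 & q < 0.05,
    direction = ifelse(log2fc >= 0, "up", "down"),
    row.names = gene_id)
  new("ContrastResult", contrastId = id, testGroup = "Col-0",
      refGroup = "WS", nTest = 3L, nRef = 3L,
      moderation = list(moderated = FALSE, d0 = 0, s0_sq = NA_real_, df = 4),
      stats = st)
}

#' Synthetic reconstruction of the published candidate-set structure
#'
#' A fully synthetic, deterministic gene-membership fixture that encodes
#' every printed count of the GSE83242 root-skewing analysis, so the
#' pattern-classification and intersection stages can be exercised at
#' their published scale without the study's supplementary gene lists:
#' within-WS DE sets of sizes 66 (45 vs 90; 9 up, 57 down) and 40
#' (135 vs 90) sharing 14 genes; within-Col-0 sets of sizes 22 (3 up, 19
#' down) and 6 sharing 4; between-ecotype categories I-VI of sizes
#' 61/24/43/38/26/64 (with the printed up/down splits, e.g. Category VI:
#' 14 up, 50 down), 30 inherent-difference genes and a small OTHER/NONE
#' remainder. The 11 HPSGC carry their real gene identifiers and reported
#' log2 fold changes; all other members are synthetic placeholders
#' (`SYN*` ids). Per-gene log2FCs and p-values in the between contrasts
#' are synthetic values consistent with the encoded significance pattern.
#'
#' @return list with `within` (data.frames `ws45`, `ws135`, `col0_45`,
#'   `col0_135`: gene_id, log2fc, direction), `between` (named list
#'   "45"/"90"/"135" of [ContrastResult-class] objects over the
#'   between-ecotype universe) and `hpsgc_reference` (the 11-gene anchor
#'   table).
#' @export
referenceSkewFixture <- function() {
  syn <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  hp <- .HPSGC_TABLE
  his13 <- "At2g18050"

  ## ---- between-ecotype universe, category by category -------------------
  mk <- function(ids, category, n_up, n_down, fc_sig = 1.8) {
    stopifnot(length(ids) == n_up + n_down)
    data.frame(gene_id = ids, category = category,
               sign = rep(c(1, -1), c(n_up, n_down)), fc_sig = fc_sig)
  }
  cat_iv_overlap <- c(his13, syn("SYNIV", 4))   # overlap genes failing anchor
  blocks <- list(
    mk(syn("SYNI", 61), "I", 19, 42),
    mk(syn("SYNII", 24), "II", 15, 9),
    mk(syn("SYNIII", 43), "III", 20, 23),
    mk(c(cat_iv_overlap, syn("SYNIVx", 33)), "IV", 30, 8),
    # V: 20 up, 6 down; ASN1 and SWEET11 are WS-higher (down in Col-0 vs WS)
    mk(c(syn("SYNV", 20), hp$gene_id[hp$category == "V"], syn("SYNVd", 4)),
       "V", 20, 6),
    # VI: 14 up, 50 down; the nine VI-side HPSGC are among the 50 down
    mk(c(syn("SYNVI", 14), hp$gene_id[hp$category == "VI"],
         syn("SYNVId", 41)), "VI", 14, 50),
    mk(syn("SYNINH", 30), "REMOVED_INHERENT", 30, 0),
    mk(syn("SYNOTH", 2), "OTHER", 2, 0),
    mk(syn("SYNNONE", 20), "NONE", 20, 0))
  uni <- do.call(rbind, blocks)
  stopifnot(!anyDuplicated(uni$gene_id))

  # per-angle significance defined by the category pattern
  sig_at <- list("45" = c("II", "IV", "V"),
                 "90" = c("I", "II", "III"),
                 "135" = c("III", "V", "VI"))
  between <- list()
  for (ang in c("45", "90", "135")) {
    sig <- uni$category %in% sig_at[[ang]] |
      uni$category %in% c("REMOVED_INHERENT", "OTHER")
    fc <- ifelse(sig, uni$sign * uni$fc_sig, 0.1 * uni$sign)
    # inherent genes: near-equal magnitude across angles (span 0.4);
    # OTHER genes: span 1.4, escaping the filter
    inh <- uni$category == "REMOVED_INHERENT"
    fc[inh] <- uni$sign[inh] * c("45" = 1.6, "90" = 1.8, "135" = 2.0)[ang]
    oth <- uni$category == "OTHER"
    fc[oth] <- uni$sign[oth] * c("45" = 1.2, "90" = 1.5, "135" = 2.6)[ang]
    between[[ang]] <- .mkContrast(paste0("Col0_vs_WS_at_", ang),
                                  uni$gene_id, fc, sig)
  }

  ## ---- within-ecotype DE sets ------------------------------------------
  # WS 135 vs 90: 40 genes, the 11 HPSGC (printed log2FCs) + HIS1-3 + 28
  # synthetic, all up except ASN1's 45-degree counterpart (ASN1 flips:
  # down at 45, up at 135)
  ws135 <- data.frame(
    gene_id = c(hp$gene_id, his13, syn("SYNWSB", 12), syn("SYNWSL", 16)),
    log2fc = c(hp$log2fc_ws135, rep(1.7, 29)))
  # shared 14 between the WS sets: ASN1, SWEET11 + 12 synthetic
  shared_ws <- c("At3g47340", "At3g48740", syn("SYNWSB", 12))
  # WS 45 vs 90: 66 genes = 14 shared + SYNIV overlap genes + 48 unique;
  # 9 up (SWEET11 + 8 synthetic), 57 down (ASN1 flips down at 45)
  ws45_ids <- c(shared_ws, cat_iv_overlap[-1], syn("SYNWSA", 48))
  ws45_up <- c("At3g48740", syn("SYNWSA", 8))
  ws45 <- data.frame(gene_id = ws45_ids,
                     log2fc = ifelse(ws45_ids %in% ws45_up, 1.5, -1.5))
  # Col-0 sets: 22 at 45 (3 up, 19 down) and 6 at 135, sharing 4; exactly
  # DIN2, ASN1 and SWEET11 of the HPSGC appear in the 45-degree set
  col0_45_ids <- c("At3g48740", syn("SYNC45u", 2),           # up
                   "At3g60140", "At3g47340", his13, syn("SYNC45", 16)) # down
  col0_45 <- data.frame(gene_id = col0_45_ids,
                        log2fc = rep(c(1.4, -1.4), c(3, 19)))
  col0_shared <- c(his13, syn("SYNC45", 3))
  col0_135 <- data.frame(gene_id = c(col0_shared, syn("SYNC135", 2)),
                         log2fc = rep(-1.4, 6))
  dirify <- function(d) { d$direction <- ifelse(d$log2fc >= 0, "up", "down"); d }
  list(within = list(ws45 = dirify(ws45), ws135 = dirify(ws135),
                     col0_45 = dirify(col0_45), col0_135 = dirify(col0_135)),
       between = between,
       hpsgc_reference = hp)
}
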