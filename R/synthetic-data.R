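#' @include patterns.R
#' @importFrom stats rnorm runif rchisq
NULL

.defaultTraceCells <- function() {
  # phenotype defaults: WS skews strongly on tilted plates, Col-0 barely;
  # both wave at the 45-degree angle; vertical controls are longest
  data.frame(
    ecotype = rep(.ECOTYPES, each = 3L),
    angle_gp = rep(.ANGLES, 2L),
    length_mm = c(17, 26, 22, 20, 30, 25),
    skew_angle_deg = c(2, 0, 2, 20, 0, 20),
    wave_count = c(4L, 1L, 1L, 4L, 1L, 1L))
}

#' Configuration of the root-trace simulator
#'
#' @param n_roots roots per (ecotype x angle) cell (default 43, a typical
#'   per-cell sample size for plate assays of this kind).
#' @param wave_amplitude_mm lateral wave amplitude (default 0.5 mm).
#' @param noise_sd_mm Gaussian positional jitter per coordinate (default
#'   0.05 mm, i.e. sub-pixel tracing error).
#' @param n_points points sampled per trace (default 200).
#' @param seed mandatory integer seed.
#' @param cells optional data.frame overriding the per-cell phenotype
#'   defaults; columns `ecotype`, `angle_gp`, `length_mm`,
#'   `skew_angle_deg`, `wave_count`.
#' @return a list of class `traceSimConfig`.
#' @export
traceSimConfig <- function(n_roots = 43L, wave_amplitude_mm = 0.5,
                           noise_sd_mm = 0.05, n_points = 200L,
                           seed, cells = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_roots < 1L || wave_amplitude_mm < 0 || noise_sd_mm < 0 ||
      n_points < 10L)
    stop("invalid trace simulation config")
  if (is.null(cells)) cells <- .defaultTraceCells()
  need <- c("ecotype", "angle_gp", "length_mm", "skew_angle_deg", "wave_count")
  if (!all(need %in% colnames(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (any(cells$length_mm <= 0) || any(cells$wave_count < 0))
    stop("invalid trace simulation config")
  structure(list(n_roots = as.integer(n_roots),
                 wave_amplitude_mm = wave_amplitude_mm,
                 noise_sd_mm = noise_sd_mm, n_points = as.integer(n_points),
                 seed = as.integer(seed), cells = cells),
            class = "traceSimConfig")
}

#' Simulate traced roots with planted skew and waving
#'
#' Each root is sampled along a straight growth direction tilted
#' `skew_angle_deg` from vertical (toward +x), with a sinusoidal lateral
#' component of the planted integer number of full periods and Gaussian
#' positional jitter on both coordinates. The returned truth table records
#' the planted skew angle, wave count, the expected HGI of the noiseless
#' straight path (sin of the skew angle) and the expected wave density.
#'
#' @param cfg a [traceSimConfig()].
#' @return list with `traces` (a [RootTraceSet-class]) and `truth`
#'   (data.frame, one row per root).
#' @examples
#' sim <- simulateTraces(traceSimConfig(n_roots = 3, seed = 1))
#' sim$traces
#' @export
simulateTraces <- function(cfg) {
  if (!inherits(cfg, "traceSimConfig")) stop("cfg must be a traceSimConfig")
  set.seed(cfg$seed)
  pts <- list(); td <- list(); truth <- list()
  for (ci in seq_len(nrow(cfg$cells))) {
    cell <- cfg$cells[ci, ]
    theta <- cell$skew_angle_deg * pi / 180
    dir <- c(sin(theta), cos(theta))       # y increases with gravity
    perp <- c(cos(theta), -sin(theta))
    for (r in seq_len(cfg$n_roots)) {
      id <- sprintf("%s_%d_r%02d", sub("-", "", cell$ecotype),
                    cell$angle_gp, r)
      t <- seq(0, cell$length_mm, length.out = cfg$n_points)
      lat <- cfg$wave_amplitude_mm *
        sin(2 * pi * cell$wave_count * t / cell$length_mm)
      p <- cbind(t * dir[1] + lat * perp[1], t * dir[2] + lat * perp[2])
      if (cfg$noise_sd_mm > 0) {
        # tracing error is locally correlated, not white: smooth the
        # jitter so it displaces the path without inflating its arc length
        jit <- matrix(rnorm(2L * cfg$n_points), ncol = 2L)
        jit <- apply(jit, 2L, .movingAverage, w = 9L)
        p <- p + jit * (cfg$noise_sd_mm / sd(jit))
      }
      pts[[id]] <- p
      td[[id]] <- data.frame(trace_id = id, ecotype = cell$ecotype,
                             angle_gp = cell$angle_gp, replicate = r,
                             view_flipped = FALSE)
      truth[[id]] <- data.frame(
        trace_id = id, ecotype = cell$ecotype, angle_gp = cell$angle_gp,
        skew_angle_deg = cell$skew_angle_deg,
        wave_count = cell$wave_count,
        expected_hgi = sin(theta),
        expected_wd = cell$wave_count / cell$length_mm)
    }
  }
  list(traces = RootTraceSet(pts, do.call(rbind, td)),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

.EXPR_CLASSES <- c("NULL", "INHERENT", paste0("CAT_", c("I", "II", "III",
                   "IV", "V", "VI")), "WS_ANGLE_45", "WS_ANGLE_135",
                   "HPSGC_LIKE")

.defaultClassCounts <- function(n_genes) {
  # planted fractions sized so the 2000-gene default carries 40 inherent,
  # 20 per category, 30 per WS-angle class and 20 HPSGC-like genes
  frac <- c(INHERENT = 0.02, CAT_I = 0.01, CAT_II = 0.01, CAT_III = 0.01,
            CAT_IV = 0.01, CAT_V = 0.01, CAT_VI = 0.01,
            WS_ANGLE_45 = 0.015, WS_ANGLE_135 = 0.015, HPSGC_LIKE = 0.01)
  planted <- round(n_genes * frac)
  planted[planted < 1] <- 1
  if (sum(planted) >= n_genes)
    stop("n_genes too small for the default planted classes")
  c("NULL" = n_genes - sum(planted), planted)
}

#' Configuration of the expression simulator
#'
#' @param n_genes total genes (default 2000).
#' @param reps replicates per (ecotype x angle) cell (default 3 chips per
#'   condition).
#' @param baseline_range range of the per-gene baseline log2 mean,
#'   drawn uniformly (default 6-12).
#' @param sigma residual log2 sd (default 0.25).
#' @param effect planted shift in log2 units (default 2.0).
#' @param class_counts optional named integer vector over
#'   `NULL, INHERENT, CAT_I..CAT_VI, WS_ANGLE_45, WS_ANGLE_135, HPSGC_LIKE`
#'   summing to `n_genes`; the default plants 40 inherent, 20 per category,
#'   30 per WS-angle class and 20 HPSGC-like genes, the rest null.
#' @param variance_mixture draw per-gene variances from a scaled
#'   inverse-chi-square mixture (prior df 4) instead of a single sigma, to
#'   exercise moderated-t shrinkage.
#' @param seed mandatory integer seed.
#' @return a list of class `exprSimConfig`.
#' @export
exprSimConfig <- function(n_genes = 2000L, reps = 3L,
                          baseline_range = c(6, 12), sigma = 0.25,
                          effect = 2.0, class_counts = NULL,
                          variance_mixture = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (sigma <= 0 || reps < 2L || n_genes < 1L)
    stop("invalid expression simulation config")
  if (is.null(class_counts)) class_counts <- .defaultClassCounts(n_genes)
  if (!setequal(names(class_counts), .EXPR_CLASSES))
    stop("class_counts must be named over: ",
         paste(.EXPR_CLASSES, collapse = ", "))
  class_counts <- class_counts[.EXPR_CLASSES]
  if (sum(class_counts) != n_genes)
    stop("class counts must sum to n_genes")
  structure(list(n_genes = as.integer(n_genes), reps = as.integer(reps),
                 baseline_range = baseline_range, sigma = sigma,
                 effect = effect, class_counts = class_counts,
                 variance_mixture = isTRUE(variance_mixture),
                 seed = as.integer(seed)),
            class = "exprSimConfig")
}

# Which (ecotype, angle) cells get the +effect shift for each planted class.
.classShiftCells <- function(class) {
  switch(class,
         "NULL" = NULL,
         INHERENT = list(c("Col-0", "45"), c("Col-0", "90"), c("Col-0", "135")),
         CAT_I = list(c("Col-0", "90")),
         CAT_II = list(c("Col-0", "45"), c("Col-0", "90")),
         CAT_III = list(c("Col-0", "90"), c("Col-0", "135")),
         CAT_IV = list(c("Col-0", "45")),
         CAT_V = list(c("Col-0", "45"), c("Col-0", "135")),
         CAT_VI = list(c("Col-0", "135")),
         WS_ANGLE_45 = list(c("Col-0", "45"), c("WS", "45")),
         WS_ANGLE_135 = list(c("Col-0", "135"), c("WS", "135")),
         HPSGC_LIKE = list(c("WS", "135")))
}

#' Simulate an expression study with planted effect classes
#'
#' Generates a 2-ecotype x 3-angle x n-replicate log2 expression matrix:
#' value = baseline + class shift + N(0, sigma^2). Planted classes mirror
#' the stages of the candidate pipeline: `INHERENT` genes shift Col-0
#' equally at all angles (caught by the inherent filter); `CAT_I` ..
#' `CAT_VI` shift Col-0 at the angle combinations defining the six
#' between-ecotype patterns; `WS_ANGLE_45`/`WS_ANGLE_135` shift both
#' ecotypes at the tilted angle (purely angle-responsive, so they enter
#' the physiology track only); `HPSGC_LIKE` genes shift WS at 135 degrees
#' only, which makes them DE within WS at 135 vs 90 and Category VI
#' between ecotypes — the HPSGC signature.
#'
#' @param cfg an [exprSimConfig()].
#' @return list with `study` (an [ExpressionStudy-class]) and `truth`
#'   (data.frame: `gene_id`, `class`).
#' @examples
#' sim <- simulateExpression(exprSimConfig(n_genes = 250, seed = 1))
#' table(sim$truth$class)
#' @export
simulateExpression <- function(cfg) {
  if (!inherits(cfg, "exprSimConfig")) stop("cfg must be an exprSimConfig")
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  classes <- rep(names(cfg$class_counts), cfg$class_counts)
  design <- expand.grid(replicate = seq_len(cfg$reps),
                        angle_gp = .ANGLES, ecotype = .ECOTYPES,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[c("ecotype", "angle_gp", "replicate")]
  design$sample_id <- sprintf("%s_%d_rep%d", sub("-", "", design$ecotype),
                              design$angle_gp, design$replicate)
  baseline <- runif(n, cfg$baseline_range[1], cfg$baseline_range[2])
  sigma_g <- if (cfg$variance_mixture)
    sqrt(4 * cfg$sigma^2 / rchisq(n, df = 4)) else rep(cfg$sigma, n)
  shift <- matrix(0, n, nrow(design))
  for (cl in unique(classes)) {
    cells <- .classShiftCells(cl)
    if (is.null(cells)) next
    rows <- which(classes == cl)
    for (cell in cells) {
      cols <- which(design$ecotype == cell[1] &
                      design$angle_gp == as.integer(cell[2]))
      shift[rows, cols] <- shift[rows, cols] + cfg$effect
    }
  }
  noise <- matrix(rnorm(n * nrow(design), 0, rep(sigma_g, nrow(design))),
                  n, nrow(design))
  values <- baseline + shift + noise
  dimnames(values) <- list(gene_ids, design$sample_id)
  study <- ExpressionStudy(values, design)
  list(study = study,
       truth = data.frame(gene_id = gene_ids, class = classes))
}
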