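#' @include RootTraceSet-methods.R
NULL

.checkTraceMatrix <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || !is.numeric(p))
    stop("a trace must be a 2-column numeric matrix of (x, y) in mm")
  if (nrow(p) < 2L) stop("invalid trace: fewer than 2 points")
  if (!all(is.finite(p))) stop("invalid trace: non-finite coordinates")
  if (any(rowSums(diff(p)^2) == 0))
    stop("invalid trace: consecutive duplicate points")
  p
}

.arcLength <- function(p) sum(sqrt(rowSums(diff(p)^2)))

#' @export
setMethod("arcLength", "matrix", function(x, ...) {
  .arcLength(.checkTraceMatrix(x))
})

#' @export
setMethod("arcLength", "RootTraceSet", function(x, ...) {
  vapply(tracePoints(x), .arcLength, numeric(1))
})

.growthIndex <- function(p, axis, flipped = FALSE) {
  L <- .arcLength(p)
  if (L <= 0) stop("invalid trace: zero length")
  g <- (p[nrow(p), axis] - p[1L, axis]) / L
  if (axis == 1L && flipped) g <- -g
  unname(g)
}

#' @export
setMethod("horizontalGrowthIndex", "matrix", function(x, flipped = FALSE, ...) {
  .growthIndex(.checkTraceMatrix(x), 1L, flipped)
})

#' @export
setMethod("horizontalGrowthIndex", "RootTraceSet", function(x, ...) {
  mapply(.growthIndex, tracePoints(x), flipped = traceData(x)$view_flipped,
         MoreArgs = list(axis = 1L))
})

#' @export
setMethod("verticalGrowthIndex", "matrix", function(x, ...) {
  .growthIndex(.checkTraceMatrix(x), 2L)
})

#' @export
setMethod("verticalGrowthIndex", "RootTraceSet", function(x, ...) {
  vapply(tracePoints(x), .growthIndex, numeric(1), axis = 2L)
})

.straightness <- function(p) {
  chord <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  chord / .arcLength(p)
}

#' @export
setMethod("straightness", "matrix", function(x, ...) {
  .straightness(.checkTraceMatrix(x))
})

#' @export
setMethod("straightness", "RootTraceSet", function(x, ...) {
  vapply(tracePoints(x), .straightness, numeric(1))
})

#' Configuration for wave counting
#'
#' @param window_frac fraction of the trace's points used as the centred
#'   moving-average smoothing window (at least 3 points).
#' @param amplitude_mm minimum absolute chord deviation, in mm, for an
#'   extremum to count as a wave crest or trough.
#' @return a list of class `waveConfig`.
#' @export
waveConfig <- function(window_frac = 0.05, amplitude_mm = 0.1) {
  if (!is.numeric(window_frac) || window_frac <= 0)
    stop("window_frac must be positive")
  if (!is.numeric(amplitude_mm) || amplitude_mm <= 0)
    stop("amplitude_mm must be positive")
  structure(list(window_frac = window_frac, amplitude_mm = amplitude_mm),
            class = "waveConfig")
}

# Signed perpendicular deviation of each point from the start-to-tip chord.
.chordDeviation <- function(p) {
  v <- p[nrow(p), ] - p[1L, ]
  len <- sqrt(sum(v^2))
  if (len == 0) return(rep(0, nrow(p)))
  u <- v / len
  rel <- sweep(p, 2L, p[1L, ])
  rel[, 1L] * u[2L] - rel[, 2L] * u[1L]  # cross product with unit chord
}

.movingAverage <- function(d, w) {
  # centred window of w points (w odd); ends use the shrunken window
  half <- (w - 1L) %/% 2L
  n <- length(d)
  cs <- cumsum(c(0, d))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.waveCount <- function(p, cfg) {
  n <- nrow(p)
  d <- .chordDeviation(p)
  w <- max(3L, ceiling(cfg$window_frac * n))
  if (w %% 2L == 0L) w <- w + 1L
  s <- .movingAverage(d, w)
  # local extrema via sign changes of the first difference (plateaus collapsed)
  ds <- sign(diff(s))
  ds <- ds[ds != 0]
  idx <- which(diff(s) != 0)
  if (length(idx) < 2L) return(0L)
  turn <- which(diff(ds) != 0)
  ext_idx <- idx[turn] + 1L
  ext_val <- s[ext_idx]
  keep <- abs(ext_val) >= cfg$amplitude_mm
  ext_val <- ext_val[keep]
  if (!length(ext_val)) return(0L)
  # count the longest run of sign-alternating extrema; consecutive
  # same-sign extrema (a split crest) collapse to one
  sgn <- sign(ext_val)
  alt <- 1L
  for (i in seq_along(sgn)[-1L]) if (sgn[i] != sgn[i - 1L]) alt <- alt + 1L
  alt %/% 2L
}

#' @export
setMethod("waveDensity", "matrix", function(x, cfg = waveConfig(), ...) {
  p <- .checkTraceMatrix(x)
  wc <- .waveCount(p, cfg)
  c(wave_count = wc, wd = wc / .arcLength(p))
})

#' @export
setMethod("waveDensity", "RootTraceSet", function(x, cfg = waveConfig(), ...) {
  res <- t(vapply(tracePoints(x), function(p) {
    wc <- .waveCount(p, cfg)
    c(wc, wc / .arcLength(p))
  }, numeric(2)))
  data.frame(trace_id = traceData(x)$trace_id,
             wave_count = as.integer(res[, 1L]), wd = res[, 2L],
             row.names = NULL)
})

#' Per-root morphometrics
#'
#' Computes all shape statistics for every trace in a set: arc length (mm),
#' signed and absolute horizontal growth index, vertical growth index,
#' straightness, wave count and wave density (waves/mm).
#'
#' @param traces a [RootTraceSet-class].
#' @param cfg a [waveConfig()] for the wave counter.
#' @return a data.frame, one row per trace, carrying the trace metadata and
#'   columns `length_mm`, `hgi`, `abs_hgi`, `vgi`, `str`, `wave_count`, `wd`.
#' @examples
#' tr <- simulateTraces(traceSimConfig(n_roots = 2, seed = 1))
#' head(morphoMetrics(tr$traces))
#' @export
morphoMetrics <- function(traces, cfg = waveConfig()) {
  stopifnot(is(traces, "RootTraceSet"))
  td <- as.data.frame(traceData(traces))
  wv <- waveDensity(traces, cfg)
  data.frame(td[c("trace_id", "ecotype", "angle_gp", "replicate")],
             length_mm = unname(arcLength(traces)),
             hgi = unname(horizontalGrowthIndex(traces)),
             abs_hgi = abs(unname(horizontalGrowthIndex(traces))),
             vgi = unname(verticalGrowthIndex(traces)),
             str = unname(straightness(traces)),
             wave_count = wv$wave_count, wd = wv$wd,
             row.names = NULL)
}
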