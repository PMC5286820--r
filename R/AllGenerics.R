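#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Arc length of a root trace
#'
#' Total path length of a traced root: the sum of Euclidean segment lengths
#' along the ordered polyline.
#'
#' @param x a two-column numeric matrix of (x, y) coordinates in mm, or a
#'   [RootTraceSet].
#' @param ... further arguments passed to methods.
#' @return numeric, in mm; one value per trace for a `RootTraceSet`.
#' @examples
#' arcLength(cbind(c(0, 3), c(0, 4)))  # 3-4-5 triangle -> 5
#' @export
setGeneric("arcLength", function(x, ...) standardGeneric("arcLength"))

#' Horizontal growth index
#'
#' Horizontal displacement of the root tip from the start point divided by
#' the root arc length. For a straight root growing at angle theta from the
#' gravity vector, HGI = sin(theta). Signed: positive toward +x on the plate
#' face; traces imaged through the media (`view_flipped`) are negated so the
#' sign refers to the plate face.
#'
#' @inheritParams arcLength
#' @param flipped logical; `TRUE` when the image was taken through the media,
#'   so the apparent x axis is mirrored. Ignored for a `RootTraceSet`, which
#'   carries a per-trace `view_flipped` flag.
#' @return dimensionless, in \[-1, 1\].
#' @export
setGeneric("horizontalGrowthIndex",
           function(x, ...) standardGeneric("horizontalGrowthIndex"))

#' Vertical growth index
#'
#' Vertical (along-gravity) tip displacement divided by arc length; the
#' cosine analogue of [horizontalGrowthIndex()].
#'
#' @inheritParams arcLength
#' @return dimensionless, in \[0, 1\] for roots that grow downward.
#' @export
setGeneric("verticalGrowthIndex",
           function(x, ...) standardGeneric("verticalGrowthIndex"))

#' Straightness of a root trace
#'
#' Straight-line (chord) distance from the root start point to the tip
#' divided by the arc length of the trace; 1 for a perfectly straight root.
#'
#' @inheritParams arcLength
#' @return dimensionless, in (0, 1\].
#' @export
setGeneric("straightness", function(x, ...) standardGeneric("straightness"))

#' Wave count and wave density
#'
#' Counts full lateral waves along a root and reports waves per millimetre
#' of root length. The deviation of each point from the start-to-tip chord
#' is smoothed with a centred moving average; local extrema of the smoothed
#' profile that exceed an amplitude threshold and alternate in sign are
#' counted, and each pair of alternating extrema is one full wave.
#'
#' @inheritParams arcLength
#' @param cfg a [waveConfig()] list: smoothing window fraction and amplitude
#'   threshold in mm.
#' @return for a matrix, a named numeric vector `c(wave_count, wd)`; for a
#'   `RootTraceSet`, a data.frame with one row per trace.
#' @export
setGeneric("waveDensity", function(x, cfg = waveConfig(), ...)
  standardGeneric("waveDensity"))

#' Per-trace metadata of a RootTraceSet
#' @param x a [RootTraceSet].
#' @return a [S4Vectors::DataFrame] with one row per trace.
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))

#' Coordinate polylines of a RootTraceSet
#' @param x a [RootTraceSet].
#' @return a named list of two-column matrices (mm).
#' @export
setGeneric("tracePoints", function(x) standardGeneric("tracePoints"))

#' Per-gene statistics table of a contrast
#' @param x a [ContrastResult] object.
#' @return a [S4Vectors::DataFrame], one row per gene.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' Identifier of a contrast
#' @param x a [ContrastResult] object.
#' @return character scalar, e.g. `"WS_135_vs_90"`.
#' @export
setGeneric("contrastId", function(x) standardGeneric("contrastId"))

#' Gene category assignments of a candidate report
#' @param x a [CandidateReport].
#' @return a [S4Vectors::DataFrame] with one row per gene.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' Candidate gene sets of a report
#'
#' `physiologySet()` is the union of within-WS angle-responsive genes,
#' `genotypeSet()` the union of between-ecotype Categories IV-VI,
#' `overlapSet()` their intersection, and `hpsgcSet()` the highly probable
#' skew gene candidates (overlap genes whose evidence involves the 135
#' degree plate angle on both sides).
#'
#' @param x a [CandidateReport].
#' @return character vector of gene identifiers.
#' @export
setGeneric("physiologySet", function(x) standardGeneric("physiologySet"))

#' @rdname physiologySet
#' @export
setGeneric("genotypeSet", function(x) standardGeneric("genotypeSet"))

#' @rdname physiologySet
#' @export
setGeneric("overlapSet", function(x) standardGeneric("overlapSet"))

#' @rdname physiologySet
#' @export
setGeneric("hpsgcSet", function(x) standardGeneric("hpsgcSet"))
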