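#' @include AllClasses.R
NULL

#' Construct a RootTraceSet
#'
#' @param points named list of two-column numeric matrices (x, y in mm),
#'   one per trace, ordered from root start to tip.
#' @param traceData data.frame or DataFrame with one row per trace and
#'   columns `trace_id`, `ecotype`, `angle_gp`, `replicate`; an optional
#'   `view_flipped` column defaults to `FALSE`.
#' @return a [RootTraceSet-class] object.
#' @examples
#' pts <- list(r1 = cbind(c(0, 0, 0), c(0, 5, 10)))
#' td <- data.frame(trace_id = "r1", ecotype = "WS", angle_gp = 90,
#'                  replicate = 1)
#' RootTraceSet(pts, td)
#' @export
RootTraceSet <- function(points, traceData) {
  td <- as(traceData, "DataFrame")
  if (!"view_flipped" %in% colnames(td)) td$view_flipped <- FALSE
  td$trace_id <- as.character(td$trace_id)
  td$angle_gp <- as.integer(td$angle_gp)
  td$replicate <- as.integer(td$replicate)
  rownames(td) <- td$trace_id
  points <- lapply(points, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x_mm", "y_mm")
    p
  })
  if (is.null(names(points))) names(points) <- td$trace_id
  points <- points[td$trace_id]
  new("RootTraceSet", points = points, traceData = td)
}

#' @describeIn RootTraceSet number of traces.
#' @param x a RootTraceSet.
#' @export
setMethod("length", "RootTraceSet", function(x) length(x@points))

#' @export
setMethod("traceData", "RootTraceSet", function(x) x@traceData)

#' @export
setMethod("tracePoints", "RootTraceSet", function(x) x@points)

#' @describeIn RootTraceSet subset traces by index, name or logical.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "RootTraceSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@traceData$trace_id)
  new("RootTraceSet", points = x@points[i],
      traceData = x@traceData[i, , drop = FALSE])
})

setMethod("show", "RootTraceSet", function(object) {
  td <- object@traceData
  cat("RootTraceSet with", length(object), "traces\n")
  if (length(object)) {
    tab <- table(ecotype = td$ecotype, angle_gp = td$angle_gp)
    cat("traces per (ecotype x angle_gp) cell:\n")
    print(tab)
    npts <- vapply(object@points, nrow, integer(1))
    cat("points per trace:", min(npts), "-", max(npts), "\n")
  }
  invisible(NULL)
})
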