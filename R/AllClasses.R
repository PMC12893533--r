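## Central S4 containers. Grid convention used throughout the package:
## row 1 is the top (north) row; cell (r, c) has its centre at
## ((c - 0.5) * cellSize, -(r - 0.5) * cellSize) relative to the top-left
## origin. All distances and areas derive from cellSize and grid indices;
## any georeferencing is carried as opaque metadata only.

#' CategoricalRaster: a rectangular grid of integer class codes
#'
#' The universal carrier of the package. Cell values are integer class
#' codes; nodata cells are stored as `NA` in the `codes` matrix, while
#' `nodata` records the reserved integer code used on disk. Cells are
#' square with side `cellSize` metres.
#'
#' @slot codes integer matrix; `NA` marks nodata cells.
#' @slot cellSize positive numeric scalar, cell side length in metres.
#' @slot nodata integer scalar, the reserved on-disk nodata code.
#' @slot legend named character vector mapping code (as name) to label.
#' @slot origin numeric length-2 `(xll, yll)` lower-left corner; purely
#'   informational, never used in computation.
#'
#' @examples
#' r <- categoricalRaster(matrix(c(1L, 2L, 2L, NA), 2, 2), cellSize = 30)
#' dim(r)
#' cellSize(r)
#' @export
setClass("CategoricalRaster",
  representation(
    codes    = "matrix",
    cellSize = "numeric",
    nodata   = "integer",
    legend   = "character",
    origin   = "numeric"
  )
)

setValidity("CategoricalRaster", function(object) {
  msg <- character()
  cd <- object@codes
  if (!is.integer(cd))
    msg <- c(msg, "codes must be an integer matrix")
  if (nrow(cd) < 1L || ncol(cd) < 1L)
    msg <- c(msg, "raster must have at least one row and one column")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@nodata) != 1L)
    msg <- c(msg, "nodata must be a single integer code")
  if (any(cd == object@nodata, na.rm = TRUE))
    msg <- c(msg, "nodata cells must be stored as NA, not as the nodata code")
  if (length(object@legend)) {
    lc <- suppressWarnings(as.integer(names(object@legend)))
    if (anyNA(lc))
      msg <- c(msg, "legend names must be integer codes")
    else {
      if (object@nodata %in% lc)
        msg <- c(msg, "the nodata code must not also be a legend code")
      seen <- unique(cd[!is.na(cd)])
      bad <- setdiff(seen, lc)
      if (length(bad))
        msg <- c(msg, paste0("codes absent from legend: ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be numeric of length 2 (xll, yll)")
  if (length(msg)) msg else TRUE
})

#' Construct a CategoricalRaster
#'
#' @param codes integer matrix (numeric matrices holding whole numbers are
#'   coerced); `NA` marks nodata.
#' @param cellSize cell side length in metres (square cells).
#' @param nodata reserved integer nodata code used when writing to disk.
#' @param legend optional named character vector (names = codes); when
#'   `NULL`, a legend naming each observed code after itself is built.
#' @param origin numeric `(xll, yll)` lower-left corner, informational.
#' @return a [CategoricalRaster-class] object.
#' @export
categoricalRaster <- function(codes, cellSize = 30, nodata = -9999L,
                              legend = NULL, origin = c(0, 0)) {
  if (!is.matrix(codes))
    stop("codes must be a matrix")
  if (!is.integer(codes)) {
    if (any(abs(codes - round(codes)) > 0, na.rm = TRUE))
      stop("categorical rasters must hold integer codes")
    storage.mode(codes) <- "integer"
  }
  nodata <- as.integer(nodata)
  codes[which(codes == nodata)] <- NA_integer_
  if (is.null(legend)) {
    seen <- sort(unique(codes[!is.na(codes)]))
    legend <- stats::setNames(as.character(seen), seen)
  }
  new("CategoricalRaster", codes = codes, cellSize = as.numeric(cellSize),
      nodata = nodata, legend = legend, origin = as.numeric(origin))
}

#' PatchSet: an 8-connected patch delineation of a binary raster
#'
#' @slot labels integer matrix; 0 on background and nodata cells, patch id
#'   (1..N, row-major discovery order) on foreground cells.
#' @slot records data.frame with one row per patch: `patch_id`,
#'   `cell_count`, `area_m2` and `enn_m` (NA until [computeEnn] is run, or
#'   when no other patch exists).
#' @slot landscapeAreaM2 total landscape area A in m2 (non-nodata cells x
#'   cell area) — the denominator of density-type metrics.
#' @slot cellSize cell side length in metres.
#' @export
setClass("PatchSet",
  representation(
    labels          = "matrix",
    records         = "data.frame",
    landscapeAreaM2 = "numeric",
    cellSize        = "numeric"
  )
)

setValidity("PatchSet", function(object) {
  msg <- character()
  lb <- object@labels
  rec <- object@records
  n <- nrow(rec)
  if (!is.integer(lb)) msg <- c(msg, "labels must be an integer matrix")
  need <- c("patch_id", "cell_count", "area_m2", "enn_m")
  if (!all(need %in% names(rec)))
    msg <- c(msg, paste("records must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (n && !identical(rec$patch_id, seq_len(n)))
      msg <- c(msg, "patch ids must be consecutive 1..N")
    if (sum(lb > 0L, na.rm = TRUE) != sum(rec$cell_count))
      msg <- c(msg, "record cell counts must sum to the foreground cell count")
    if (n && any(abs(rec$area_m2 - rec$cell_count * object@cellSize^2) >
                 1e-6))
      msg <- c(msg, "area_m2 must equal cell_count x cellSize^2")
  }
  if (length(msg)) msg else TRUE
})

#' FADRaster: per-pixel forest area density, percent
#'
#' FAD is defined only on foreground (natural-cover) pixels and is `NA`
#' elsewhere. `window` records the moving-window width in pixels, or
#' `"multiscale-average"` for the mean over several scales.
#'
#' @slot values numeric matrix of FAD percentages in `[0, 100]`, `NA` off
#'   the foreground.
#' @slot window character scalar provenance tag.
#' @slot cellSize cell side length in metres.
#' @export
setClass("FADRaster",
  representation(values = "matrix", window = "character",
                 cellSize = "numeric")
)

setValidity("FADRaster", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (any(v < -1e-9 | v > 100 + 1e-9, na.rm = TRUE))
    return("FAD values must lie in [0, 100]")
  if (length(object@window) != 1L) return("window must be a single tag")
  TRUE
})

#' FragClassRaster: per-pixel fragmentation class map
#'
#' Classes are ordered by increasing forest area density; code 0 marks
#' background (non-natural) cells and `NA` marks nodata. The default
#' 6-class scheme is `rare < patchy < transitional < dominant < interior <
#' intact` (see [fadClassScheme]).
#'
#' @slot classes integer matrix over `{0, 1..K}` plus `NA`.
#' @slot scheme data.frame with columns `code`, `name`, `lower` (lower
#'   FAD bound in percent, inclusive).
#' @slot provenance character scalar, e.g. `"window=7 date=1990"`.
#' @slot cellSize cell side length in metres.
#' @export
setClass("FragClassRaster",
  representation(classes = "matrix", scheme = "data.frame",
                 provenance = "character", cellSize = "numeric")
)

setValidity("FragClassRaster", function(object) {
  msg <- character()
  cl <- object@classes
  sc <- object@scheme
  if (!is.integer(cl)) msg <- c(msg, "classes must be an integer matrix")
  if (!all(c("code", "name", "lower") %in% names(sc)))
    msg <- c(msg, "scheme needs columns code, name, lower")
  else {
    if (any(cl < 0L | cl > max(sc$code), na.rm = TRUE))
      msg <- c(msg, "class codes outside the scheme")
    if (is.unsorted(sc$lower, strictly = TRUE))
      msg <- c(msg, "scheme lower bounds must be strictly increasing")
    if (sc$lower[1] != 0)
      msg <- c(msg, "first class must start at FAD 0")
  }
  if (length(msg)) msg else TRUE
})

#' TransitionMatrix: fragmentation-class transitions between two dates
#'
#' Cross-tabulation of per-pixel states between two class maps; state 0
#' ("nonforest") collects all non-natural cells. Cells that are nodata at
#' either date are excluded. Transitions from a higher to a lower class
#' rank mark an increase in fragmentation.
#'
#' @slot counts (K+1)x(K+1) matrix of cell counts, rows = date-1 state,
#'   columns = date-2 state, labelled by class names.
#' @slot rowPercent row-normalised percentages (each non-empty row sums to
#'   100; empty rows are `NA`).
#' @slot cellAreaM2 area of one cell in m2, for hectare conversion.
#' @export
setClass("TransitionMatrix",
  representation(counts = "matrix", rowPercent = "matrix",
                 cellAreaM2 = "numeric")
)

setValidity("TransitionMatrix", function(object) {
  ct <- object@counts
  if (nrow(ct) != ncol(ct)) return("counts must be square")
  if (any(ct < 0)) return("counts must be non-negative")
  rs <- rowSums(object@rowPercent)
  ok <- is.na(rs) | abs(rs - 100) < 1e-6
  if (!all(ok)) return("each non-empty row of rowPercent must sum to 100")
  TRUE
})
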