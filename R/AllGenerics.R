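#' @name accessors
#' @title Accessors for fragscape containers
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with `@`.
#' @param x a fragscape S4 object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("rasterCodes", function(x) standardGeneric("rasterCodes"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("nodataCode", function(x) standardGeneric("nodataCode"))
#' @rdname accessors
#' @export
setGeneric("rasterLegend", function(x) standardGeneric("rasterLegend"))
#' @rdname accessors
#' @export
setGeneric("patchLabels", function(x) standardGeneric("patchLabels"))
#' @rdname accessors
#' @export
setGeneric("patchRecords", function(x) standardGeneric("patchRecords"))
#' @rdname accessors
#' @export
setGeneric("landscapeArea", function(x) standardGeneric("landscapeArea"))
#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setGeneric("fadValues", function(x) standardGeneric("fadValues"))
#' @rdname accessors
#' @export
setGeneric("fragClasses", function(x) standardGeneric("fragClasses"))
#' @rdname accessors
#' @export
setGeneric("classScheme", function(x) standardGeneric("classScheme"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("transitionPercent", function(x)
  standardGeneric("transitionPercent"))

#' @rdname accessors
#' @export
setMethod("rasterCodes", "CategoricalRaster", function(x) x@codes)
#' @rdname accessors
#' @export
setMethod("cellSize", "CategoricalRaster", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("cellSize", "PatchSet", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("cellSize", "FADRaster", function(x) x@cellSize)
#' @rdname accessors
#' @export
setMethod("nodataCode", "CategoricalRaster", function(x) x@nodata)
#' @rdname accessors
#' @export
setMethod("rasterLegend", "CategoricalRaster", function(x) x@legend)
#' @rdname accessors
#' @export
setMethod("patchLabels", "PatchSet", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("patchRecords", "PatchSet", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("landscapeArea", "PatchSet", function(x) x@landscapeAreaM2)
#' @rdname accessors
#' @export
setMethod("nPatches", "PatchSet", function(x) nrow(x@records))
#' @rdname accessors
#' @export
setMethod("fadValues", "FADRaster", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fragClasses", "FragClassRaster", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("classScheme", "FragClassRaster", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("transitionPercent", "TransitionMatrix", function(x) x@rowPercent)

#' @describeIn accessors raster dimensions `(nrows, ncols)`.
#' @export
setMethod("dim", "CategoricalRaster", function(x) dim(x@codes))

setMethod("show", "CategoricalRaster", function(object) {
  cd <- object@codes
  cat(sprintf("CategoricalRaster %d x %d, %g m cells\n",
              nrow(cd), ncol(cd), object@cellSize))
  nd <- sum(is.na(cd))
  tab <- table(cd)
  lab <- object@legend[as.character(names(tab))]
  lab[is.na(lab)] <- names(tab)[is.na(lab)]
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", lab, as.integer(tab)), collapse = ", ")))
  cat(sprintf("  nodata cells: %d (code %d on disk)\n", nd, object@nodata))
})

setMethod("show", "PatchSet", function(object) {
  rec <- object@records
  cat(sprintf("PatchSet: %d patch(es), %g m cells, landscape %.2f ha\n",
              nrow(rec), object@cellSize, object@landscapeAreaM2 / 1e4))
  if (nrow(rec))
    cat(sprintf("  foreground %d cells; largest patch %.2f ha; ENN %s\n",
                sum(rec$cell_count), max(rec$area_m2) / 1e4,
                if (all(is.na(rec$enn_m))) "not computed"
                else sprintf("mean %.1f m", mean(rec$enn_m, na.rm = TRUE))))
})

setMethod("show", "FADRaster", function(object) {
  v <- object@values
  cat(sprintf("FADRaster (window %s): %d x %d, %d foreground pixel(s)\n",
              object@window, nrow(v), ncol(v), sum(!is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  FAD range %.2f - %.2f %%\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "FragClassRaster", function(object) {
  cl <- object@classes
  cat(sprintf("FragClassRaster [%s]: %d x %d\n", object@provenance,
              nrow(cl), ncol(cl)))
  fg <- cl[!is.na(cl) & cl > 0L]
  if (length(fg)) {
    tab <- table(factor(fg, levels = object@scheme$code,
                        labels = object@scheme$name))
    pct <- 100 * as.integer(tab) / length(fg)
    cat(paste(sprintf("  %-13s %6.2f %%", names(tab), pct), collapse = "\n"),
        "\n")
  }
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d states, %d cells\n",
              nrow(object@counts), sum(object@counts)))
  print(object@counts)
})
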