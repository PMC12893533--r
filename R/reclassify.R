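## Legend collapse and zone clipping. The analysis runs on three classes:
##   1 = natural cover (the focus class), 2 = anthropic use, 3 = water.
## Water is background for fragmentation — neither natural foreground nor
## excluded from the landscape — so the landscape area A (the denominator
## of PD, LPI and MESH) is fixed by the zone clip, not by class content.

#' Target class codes of the three-class analysis legend
#' @export
NATURAL <- 1L
#' @rdname NATURAL
#' @export
ANTHROPIC <- 2L
#' @rdname NATURAL
#' @export
WATER <- 3L

CLASS3_LEGEND <- c(`1` = "natural", `2` = "anthropic", `3` = "water")

#' Build a reclassification scheme
#'
#' @param mapping named integer vector: names are source codes, values the
#'   target class in `{1 = natural, 2 = anthropic, 3 = water}`.
#' @param name free-text scheme label, e.g. `"maate-level1"`.
#' @return a `ReclassScheme` (plain list with class attribute).
#' @export
reclassScheme <- function(mapping, name = "unnamed") {
  mapping <- stats::setNames(as.integer(mapping), names(mapping))
  if (is.null(names(mapping)) || anyNA(suppressWarnings(
      as.integer(names(mapping)))))
    stop("mapping must be a named vector with integer source codes as names")
  if (!all(mapping %in% c(NATURAL, ANTHROPIC, WATER)))
    stop("target codes must be exactly in {1 = natural, 2 = anthropic, ",
         "3 = water}")
  structure(list(mapping = mapping, name = name), class = "ReclassScheme")
}

#' Load a reclassification scheme from a two-column CSV
#'
#' Expected columns: `source_code`, `target_code` (header row mandatory).
#' Totality over a raster's legend is checked lazily, at [reclassify]
#' time.
#'
#' @param path CSV file.
#' @param name scheme label; defaults to the file name.
#' @return a `ReclassScheme`.
#' @export
readReclassScheme <- function(path, name = basename(path)) {
  tab <- utils::read.csv(path)
  need <- c("source_code", "target_code")
  if (!all(need %in% names(tab)))
    stop("scheme CSV must have columns source_code, target_code")
  if (anyDuplicated(tab$source_code))
    stop("duplicate source_code in scheme CSV: ",
         tab$source_code[duplicated(tab$source_code)][1L])
  reclassScheme(stats::setNames(tab$target_code, tab$source_code),
                name = name)
}

#' Collapse a source legend into the three analysis classes
#'
#' Every non-nodata code must be covered by the scheme; unmapped codes
#' fail loudly and are never default-assigned. Nodata cells are preserved
#' in place, so the cell partition is conserved.
#'
#' @param raster a [CategoricalRaster-class] with source codes.
#' @param scheme a [reclassScheme] (or named vector coerced to one).
#' @return a [CategoricalRaster-class] with codes in `{1, 2, 3}`.
#' @export
reclassify <- function(raster, scheme) {
  stopifnot(is(raster, "CategoricalRaster"))
  if (!inherits(scheme, "ReclassScheme")) scheme <- reclassScheme(scheme)
  cd <- raster@codes
  src <- as.integer(names(scheme$mapping))
  idx <- match(cd, src)
  unmapped <- !is.na(cd) & is.na(idx)
  if (any(unmapped)) {
    miss <- sort(unique(cd[unmapped]))
    stop(sprintf("scheme '%s' does not map code(s): %s",
                 scheme$name, paste(miss, collapse = ", ")))
  }
  out <- matrix(unname(scheme$mapping)[idx], nrow(cd), ncol(cd))
  new("CategoricalRaster", codes = out, cellSize = raster@cellSize,
      nodata = raster@nodata, legend = CLASS3_LEGEND,
      origin = raster@origin)
}

#' Construct a zone mask
#'
#' @param raster a [CategoricalRaster-class] whose codes are only 0, 1
#'   (and nodata).
#' @param zoneName zone label.
#' @return a `ZoneMask`.
#' @export
zoneMask <- function(raster, zoneName = "zone") {
  stopifnot(is(raster, "CategoricalRaster"))
  if (!all(raster@codes %in% c(0L, 1L) | is.na(raster@codes)))
    stop("zone mask rasters may contain only codes 0 and 1 (plus nodata)")
  structure(list(raster = raster, zone_name = zoneName), class = "ZoneMask")
}

#' Clip a raster to a study zone
#'
#' Cells where the mask is 1 keep their code; all other cells (mask 0 or
#' mask nodata) become nodata. The downstream landscape area A is the
#' count of non-nodata cells times the cell area, so the clip — not class
#' content — defines A.
#'
#' @param raster a [CategoricalRaster-class].
#' @param mask a [zoneMask] or a 0/1 [CategoricalRaster-class].
#' @return the clipped [CategoricalRaster-class].
#' @export
clipToZone <- function(raster, mask) {
  if (inherits(mask, "ZoneMask")) mask <- mask$raster
  assertAligned(raster, mask)
  keep <- !is.na(mask@codes) & mask@codes == 1L
  out <- raster@codes
  out[!keep] <- NA_integer_
  new("CategoricalRaster", codes = out, cellSize = raster@cellSize,
      nodata = raster@nodata, legend = raster@legend,
      origin = raster@origin)
}

#' Binary natural-cover layer
#'
#' Natural cover becomes foreground (1); anthropic use and water become
#' background (0); nodata stays nodata. This layer feeds both the patch
#' metrics and the FAD analysis.
#'
#' @param raster a three-class [CategoricalRaster-class].
#' @return a binary [CategoricalRaster-class].
#' @export
naturalBinary <- function(raster) {
  stopifnot(is(raster, "CategoricalRaster"))
  cd <- raster@codes
  bad <- !is.na(cd) & !(cd %in% c(NATURAL, ANTHROPIC, WATER))
  if (any(bad))
    stop("unexpected code(s) for a three-class raster: ",
         paste(sort(unique(cd[bad])), collapse = ", "))
  out <- ifelse(is.na(cd), NA_integer_,
                ifelse(cd == NATURAL, 1L, 0L))
  out <- matrix(as.integer(out), nrow(cd), ncol(cd))
  new("CategoricalRaster", codes = out, cellSize = raster@cellSize,
      nodata = raster@nodata,
      legend = c(`0` = "non-natural", `1` = "natural"),
      origin = raster@origin)
}
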