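## Raster I/O. Two on-disk dialects:
##  * ESRI ASCII grid (.asc) — 6-line header, self-contained, the
##    interchange and fixture format.
##  * single-band integer TIFF (.tif/.tiff, 16-bit, deflate) with a JSON
##    sidecar `<path>.aux.json` holding cell size, nodata code, legend and
##    origin; in-file nodata is always sample value 65535.
## Neither reader ever remaps codes; nodata round-trips bit-exactly.

TIFF_NODATA <- 65535L

rasterFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext %in% c("asc", "txt")) "ascii"
  else stop("cannot infer raster format from extension: ", path)
}

#' Read a categorical raster (TIFF or ESRI ASCII grid)
#'
#' Dispatches on the file extension: `.asc`/`.txt` to [readAsciiGrid],
#' `.tif`/`.tiff` to the TIFF reader. Only square-cell, single-band
#' integer rasters are accepted; rasters with unequal x/y resolution are
#' rejected rather than resampled.
#'
#' @param path file to read.
#' @param expectedCodes optional integer vector; if given, any non-nodata
#'   value outside this set raises an error naming the code and the
#'   (row, col) of its first occurrence.
#' @param cellSize,nodata fallbacks for a TIFF with no sidecar file.
#' @return a [CategoricalRaster-class].
#' @export
readCategoricalRaster <- function(path, expectedCodes = NULL,
                                  cellSize = NULL, nodata = NULL) {
  if (!file.exists(path))
    stop("raster file does not exist: ", path)
  r <- switch(rasterFormat(path),
    ascii = readAsciiGrid(path),
    tiff  = readTiffRaster(path, cellSize = cellSize, nodata = nodata)
  )
  if (!is.null(expectedCodes)) {
    bad <- !is.na(r@codes) & !(r@codes %in% as.integer(expectedCodes))
    if (any(bad)) {
      idx <- which(bad)[1L]
      rc <- arrayInd(idx, dim(r@codes))
      stop(sprintf(
        "unexpected code %d at cell (row %d, col %d) in %s",
        r@codes[idx], rc[1L], rc[2L], path))
    }
  }
  r
}

#' Read an ESRI ASCII grid
#'
#' Expects the 6-line header `ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value` (case-insensitive) followed by `nrows`
#' whitespace-separated rows, top row first. `cellsize` becomes the cell
#' size in metres. Non-integer cell values are an error: categorical
#' rasters hold class codes.
#'
#' @param path file to read.
#' @return a [CategoricalRaster-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7L)
    stop("ASCII grid too short for a 6-line header plus body: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header line: '", lines[i], "'")
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  if (length(body) != nr)
    stop(sprintf("ASCII grid body has %d row(s) but header declares nrows=%d",
                 length(body), nr))
  vals <- strsplit(trimws(body), "\\s+")
  lens <- lengths(vals)
  if (any(lens != nc))
    stop(sprintf("ASCII grid row %d has %d value(s), expected ncols=%d",
                 which(lens != nc)[1L], lens[lens != nc][1L], nc))
  num <- suppressWarnings(as.numeric(unlist(vals)))
  if (anyNA(num))
    stop("non-numeric cell value in ASCII grid body")
  if (any(abs(num - round(num)) > 0))
    stop("non-integer cell value in ASCII grid body: categorical rasters ",
         "must hold integer codes (first offender: ",
         num[abs(num - round(num)) > 0][1L], ")")
  codes <- matrix(as.integer(num), nrow = nr, ncol = nc, byrow = TRUE)
  categoricalRaster(codes, cellSize = hdr$cellsize,
                    nodata = as.integer(hdr$nodata_value),
                    origin = c(hdr$xllcorner, hdr$yllcorner))
}

readTiffRaster <- function(path, cellSize = NULL, nodata = NULL) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L)
    stop("TIFF raster must be single-band: ", path)
  storage.mode(m) <- "integer"
  aux <- paste0(path, ".aux.json")
  legend <- NULL; origin <- c(0, 0)
  if (file.exists(aux)) {
    meta <- jsonlite::read_json(aux, simplifyVector = TRUE)
    cellSize <- meta$cell_size_m
    nodata <- as.integer(meta$nodata_code)
    if (!is.null(meta$legend))
      legend <- stats::setNames(as.character(unlist(meta$legend)),
                                names(meta$legend))
    if (!is.null(meta$origin)) origin <- as.numeric(unlist(meta$origin))
  }
  if (is.null(cellSize) || is.null(nodata))
    stop("TIFF raster has no sidecar ", aux,
         "; supply cellSize and nodata explicitly")
  m[m == TIFF_NODATA] <- NA_integer_
  categoricalRaster(m, cellSize = cellSize, nodata = as.integer(nodata),
                    legend = legend, origin = origin)
}

#' Write a categorical raster
#'
#' The emitted file round-trips to an identical raster (codes, dimensions,
#' cell size, nodata code) under the matching reader. TIFF output is a
#' single 16-bit band (codes must lie in 0..65534) with deflate
#' compression and a `<path>.aux.json` sidecar carrying the metadata that
#' plain TIFF cannot.
#'
#' @param raster a [CategoricalRaster-class].
#' @param path destination; parent directory must exist.
#' @param format `"ascii"` or `"tiff"`; default inferred from extension.
#' @return `path`, invisibly.
#' @export
writeCategoricalRaster <- function(raster, path,
                                   format = rasterFormat(path)) {
  stopifnot(is(raster, "CategoricalRaster"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  format <- match.arg(format, c("ascii", "tiff", "geotiff"))
  if (format == "geotiff") format <- "tiff"
  cd <- raster@codes
  if (format == "ascii") {
    out <- cd
    out[is.na(out)] <- raster@nodata
    hdr <- c(
      sprintf("ncols %d", ncol(cd)),
      sprintf("nrows %d", nrow(cd)),
      sprintf("xllcorner %.10g", raster@origin[1L]),
      sprintf("yllcorner %.10g", raster@origin[2L]),
      sprintf("cellsize %.10g", raster@cellSize),
      sprintf("NODATA_value %d", raster@nodata)
    )
    body <- apply(out, 1L, paste, collapse = " ")
    writeLines(c(hdr, body), path)
  } else {
    rng <- range(cd, na.rm = TRUE)
    if (sum(!is.na(cd)) && (rng[1L] < 0L || rng[2L] >= TIFF_NODATA))
      stop("TIFF output supports codes 0..65534 only; use ASCII format")
    out <- cd
    out[is.na(out)] <- TIFF_NODATA
    tiff::writeTIFF(out / 65535, path, bits.per.sample = 16L,
                    compression = "deflate")
    legend <- as.list(raster@legend)
    meta <- list(cell_size_m = raster@cellSize,
                 nodata_code = raster@nodata,
                 origin = raster@origin,
                 legend = if (length(legend)) legend else NULL)
    jsonlite::write_json(meta, paste0(path, ".aux.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Assert that two rasters are mutually aligned
#'
#' Every two-raster operation (change, transitions, pairing) requires the
#' operands to share grid dimensions and cell size. Returns silently when
#' aligned; otherwise raises an error naming the first differing field.
#'
#' @param a,b [CategoricalRaster-class] objects.
#' @return `TRUE`, invisibly.
#' @export
assertAligned <- function(a, b) {
  stopifnot(is(a, "CategoricalRaster"), is(b, "CategoricalRaster"))
  if (nrow(a@codes) != nrow(b@codes))
    stop(sprintf("rasters are misaligned: nrows differ (%d vs %d)",
                 nrow(a@codes), nrow(b@codes)))
  if (ncol(a@codes) != ncol(b@codes))
    stop(sprintf("rasters are misaligned: ncols differ (%d vs %d)",
                 ncol(a@codes), ncol(b@codes)))
  if (abs(a@cellSize - b@cellSize) > 1e-9 * max(a@cellSize, b@cellSize))
    stop(sprintf("rasters are misaligned: cell_size_m differs (%g vs %g)",
                 a@cellSize, b@cellSize))
  invisible(TRUE)
}
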