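## Spatially explicit fragmentation: per-pixel forest area density (FAD)
## at one or several moving-window scales, ordered fragmentation classes,
## and between-date change/transition accounting.
##
## Border policy: windows are clipped at the grid edge and the FAD
## denominator is the count of in-grid, non-nodata window cells, so a
## border pixel of an all-forest raster still scores 100.

#' Default FAD observation scales (window widths in pixels)
#' @export
FAD_SCALES <- c(7L, 13L, 27L, 81L, 243L)

#' Fragmentation class scheme for FAD values
#'
#' The canonical 6-class scheme ranks pixels by forest area density with
#' lower-inclusive bounds: rare `[0,10)`, patchy `[10,40)`, transitional
#' `[40,60)`, dominant `[60,90)`, interior `[90,100)`, intact `= 100`.
#' The 5-class variant merges intact into interior; the 2-class variant
#' splits at 60 into fragmented/connected.
#'
#' @param classes 6 (default), 5 or 2; or supply `lower` and `name`
#'   directly for a custom scheme.
#' @param lower,name optional custom strictly-increasing lower bounds
#'   (first must be 0, all < 100 except an optional final 100) and class
#'   names.
#' @return `data.frame` with columns `code`, `name`, `lower`.
#' @export
fadClassScheme <- function(classes = 6, lower = NULL, name = NULL) {
  if (is.null(lower)) {
    sch <- switch(as.character(classes),
      "6" = list(lower = c(0, 10, 40, 60, 90, 100),
                 name = c("rare", "patchy", "transitional", "dominant",
                          "interior", "intact")),
      "5" = list(lower = c(0, 10, 40, 60, 90),
                 name = c("rare", "patchy", "transitional", "dominant",
                          "interior")),
      "2" = list(lower = c(0, 60), name = c("fragmented", "connected")),
      stop("no built-in scheme with ", classes, " classes; supply lower/name")
    )
    lower <- sch$lower; name <- sch$name
  }
  if (length(lower) != length(name))
    stop("lower and name must have equal length")
  if (lower[1] != 0 || is.unsorted(lower, strictly = TRUE) ||
      any(lower > 100))
    stop("lower bounds must be strictly increasing, start at 0, and not ",
         "exceed 100")
  data.frame(code = seq_along(lower), name = name, lower = lower)
}

## Clipped moving-window sums via a summed-area table: O(cells) per scale.
boxSum <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- matrix(apply(x, 2L, cumsum), nr, nc)
  cs <- rbind(0, cs)
  r1 <- pmax(seq_len(nr) - r, 1L); r2 <- pmin(seq_len(nr) + r, nr)
  rows <- cs[r2 + 1L, , drop = FALSE] - cs[r1, , drop = FALSE]
  cs2 <- t(matrix(apply(rows, 1L, cumsum), nc, nr))
  cs2 <- cbind(0, cs2)
  c1 <- pmax(seq_len(nc) - r, 1L); c2 <- pmin(seq_len(nc) + r, nc)
  cs2[, c2 + 1L, drop = FALSE] - cs2[, c1, drop = FALSE]
}

#' Per-pixel forest area density
#'
#' For each foreground (forest) pixel, FAD is 100 times the proportion of
#' forest among the non-nodata cells of the `window` x `window`
#' neighbourhood centred on it, with the neighbourhood clipped at the
#' grid border. Background and nodata pixels are undefined (`NA`).
#'
#' @param binary a [CategoricalRaster-class] with codes `{0, 1}` plus
#'   nodata.
#' @param window odd window width >= 3, in pixels.
#' @return a [FADRaster-class].
#' @export
computeFAD <- function(binary, window) {
  stopifnot(is(binary, "CategoricalRaster"))
  window <- as.integer(window)
  if (length(window) != 1L || window < 3L || window %% 2L == 0L)
    stop("window must be a single odd integer >= 3, got ", window)
  cd <- binary@codes
  if (!all(cd %in% c(0L, 1L) | is.na(cd)))
    stop("computeFAD needs a binary raster (codes 0/1 plus nodata)")
  r <- (window - 1L) %/% 2L
  valid <- !is.na(cd)
  forest <- valid & cd == 1L
  fs <- boxSum(forest + 0, r)
  vs <- boxSum(valid + 0, r)
  vals <- matrix(NA_real_, nrow(cd), ncol(cd))
  vals[forest] <- 100 * fs[forest] / vs[forest]
  new("FADRaster", values = vals, window = as.character(window),
      cellSize = binary@cellSize)
}

#' Classify FAD values into fragmentation classes
#'
#' Intervals are half-open and lower-inclusive: a pixel takes the highest
#' class whose lower bound it reaches, so FAD 10 is patchy and only FAD
#' 100 is intact under the default scheme.
#'
#' @param fad a [FADRaster-class].
#' @param scheme a class scheme from [fadClassScheme].
#' @param binary optional source binary [CategoricalRaster-class]; when
#'   given, its nodata cells become nodata (`NA`) in the class map.
#'   Without it, all undefined FAD pixels map to background (0).
#' @param provenance optional provenance tag; defaults to the FAD window.
#' @return a [FragClassRaster-class]; background pixels are 0.
#' @export
classifyFAD <- function(fad, scheme = fadClassScheme(), binary = NULL,
                        provenance = paste0("window=", fad@window)) {
  stopifnot(is(fad, "FADRaster"))
  v <- fad@values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("FAD values outside [0, 100]")
  cls <- matrix(0L, nrow(v), ncol(v))
  def <- !is.na(v)
  cls[def] <- findInterval(v[def], scheme$lower)
  if (!is.null(binary)) {
    stopifnot(is(binary, "CategoricalRaster"),
              identical(dim(binary@codes), dim(v)))
    cls[is.na(binary@codes)] <- NA_integer_
  }
  new("FragClassRaster", classes = cls, scheme = scheme,
      provenance = provenance, cellSize = fad@cellSize)
}

#' Multiscale FAD fragmentation analysis
#'
#' Computes FAD at each scale, classifies each scale, then averages the
#' per-pixel FAD values arithmetically across scales and classifies the
#' average once with the same scheme (average-then-classify).
#'
#' @param binary a [CategoricalRaster-class] with codes `{0, 1}` plus
#'   nodata.
#' @param scales odd window widths; default `c(7, 13, 27, 81, 243)`.
#' @param scheme class scheme, see [fadClassScheme].
#' @param tag optional provenance prefix (e.g. a date).
#' @return list with elements `perScaleFad` (named list of
#'   [FADRaster-class]), `perScaleClass` (named list of
#'   [FragClassRaster-class]), `averageFad` and `averageClass`.
#' @export
multiscaleFAD <- function(binary, scales = FAD_SCALES,
                          scheme = fadClassScheme(), tag = "") {
  scales <- as.integer(scales)
  fads <- lapply(scales, function(w) computeFAD(binary, w))
  names(fads) <- scales
  classes <- lapply(fads, function(f)
    classifyFAD(f, scheme, binary = binary,
                provenance = trimws(paste0(tag, " window=", f@window))))
  avg <- Reduce(`+`, lapply(fads, fadValues)) / length(fads)
  avgFad <- new("FADRaster", values = avg, window = "multiscale-average",
                cellSize = binary@cellSize)
  avgClass <- classifyFAD(avgFad, scheme, binary = binary,
                          provenance = trimws(paste0(tag,
                                                     " multiscale-average")))
  list(perScaleFad = fads, perScaleClass = classes,
       averageFad = avgFad, averageClass = avgClass)
}

#' Transition matrix of fragmentation classes between two dates
#'
#' Cross-tabulates per-pixel states (class 0 = nonforest collects all
#' non-natural cells) between two aligned class maps sharing one scheme;
#' cells that are nodata at either date are excluded, so the counts sum
#' to the number of co-valid cells. Movement from a higher class rank to
#' a lower one (below the diagonal when rows are ordered
#' nonforest..intact) is an increase in fragmentation; the reverse is a
#' decrease (see [transitionLong]).
#'
#' @param c1,c2 [FragClassRaster-class] maps for the earlier and later
#'   date.
#' @return a [TransitionMatrix-class].
#' @export
transitionMatrix <- function(c1, c2) {
  stopifnot(is(c1, "FragClassRaster"), is(c2, "FragClassRaster"))
  if (!identical(dim(c1@classes), dim(c2@classes)))
    stop("class rasters are misaligned: dimensions differ")
  if (!isTRUE(all.equal(c1@scheme$lower, c2@scheme$lower)) ||
      !identical(c1@scheme$name, c2@scheme$name))
    stop("class scheme mismatch between dates")
  k <- max(c1@scheme$code)
  lev <- 0:k
  labs <- c("nonforest", c1@scheme$name)
  ok <- !is.na(c1@classes) & !is.na(c2@classes)
  counts <- table(factor(c1@classes[ok], levels = lev, labels = labs),
                  factor(c2@classes[ok], levels = lev, labels = labs))
  counts <- unclass(counts)
  storage.mode(counts) <- "double"
  names(dimnames(counts)) <- NULL
  rs <- rowSums(counts)
  pct <- sweep(counts, 1L, rs, "/") * 100
  pct[rs == 0, ] <- NA_real_
  new("TransitionMatrix", counts = counts, rowPercent = pct,
      cellAreaM2 = c1@cellSize^2)
}

#' Long-form transitions with fragmentation direction
#'
#' @param tm a [TransitionMatrix-class].
#' @return `data.frame` with `from`, `to`, `cells`, `area_ha`,
#'   `row_percent` and `direction` (`"increase"` when moving to a lower
#'   class rank, `"decrease"` to a higher, `"stable"` on the diagonal).
#' @export
transitionLong <- function(tm) {
  stopifnot(is(tm, "TransitionMatrix"))
  ct <- tm@counts
  labs <- rownames(ct)
  grid <- expand.grid(from = labs, to = labs, stringsAsFactors = FALSE)
  fi <- match(grid$from, labs); ti <- match(grid$to, labs)
  data.frame(
    grid,
    cells = as.vector(ct[cbind(fi, ti)]),
    area_ha = as.vector(ct[cbind(fi, ti)]) * tm@cellAreaM2 / 1e4,
    row_percent = as.vector(tm@rowPercent[cbind(fi, ti)]),
    direction = ifelse(fi == ti, "stable",
                       ifelse(fi > ti, "increase", "decrease"))
  )
}

#' Natural-cover loss between two dates, in hectares
#'
#' Counts cells that are foreground at date 1 and background at date 2;
#' the measure is directional (swapping the dates measures gain).
#'
#' @param b1,b2 aligned binary [CategoricalRaster-class] objects.
#' @return hectares lost.
#' @export
naturalLossArea <- function(b1, b2) {
  assertAligned(b1, b2)
  lost <- !is.na(b1@codes) & !is.na(b2@codes) &
    b1@codes == 1L & b2@codes == 0L
  sum(lost) * b1@cellSize^2 / 1e4
}

#' Per-scale class composition change between two dates
#'
#' For each date and scale, the percentage of foreground pixels in each
#' fragmentation class (percentages per (date, scale) sum to 100).
#'
#' @param ms1,ms2 named lists of [FragClassRaster-class] per scale (the
#'   `perScaleClass` element of [multiscaleFAD], optionally with the
#'   average map appended).
#' @param dates length-2 vector of date labels.
#' @return long `data.frame` with columns `date`, `scale`, `class`,
#'   `percent`.
#' @export
changeProfile <- function(ms1, ms2, dates = c("date1", "date2")) {
  if (!identical(names(ms1), names(ms2)))
    stop("scale mismatch between dates: ",
         paste(names(ms1), collapse = "/"), " vs ",
         paste(names(ms2), collapse = "/"))
  oneDate <- function(ms, date) {
    do.call(rbind, lapply(names(ms), function(sc) {
      fc <- ms[[sc]]
      fg <- fc@classes[!is.na(fc@classes) & fc@classes > 0L]
      tab <- tabulate(fg, nbins = max(fc@scheme$code))
      data.frame(date = date, scale = sc, class = fc@scheme$name,
                 percent = if (length(fg)) 100 * tab / length(fg)
                           else NA_real_)
    }))
  }
  rbind(oneDate(ms1, dates[1L]), oneDate(ms2, dates[2L]))
}
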