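## The six class-level landscape metrics for natural cover. Units follow
## the FRAGSTATS conventions: patch areas a_ij and the landscape area A
## are measured in m2 and converted at the report boundary — PA_MN and
## MESH to hectares, PD to patches per 100 ha, LPI to percent of A.

METRIC_COLS <- c("pa_mn_ha", "np", "pd_per100ha", "lpi_pct", "enn_mn_m",
                 "mesh_ha", "total_class_area_ha", "landscape_area_ha")

#' Class-level landscape metrics of a patch delineation
#'
#' Computes, for the foreground class of a [PatchSet-class]:
#' \describe{
#'   \item{pa_mn_ha}{mean patch area, `(sum a_ij / n_i) / 1e4` ha.}
#'   \item{np}{number of patches `n_i`.}
#'   \item{pd_per100ha}{patch density, `(n_i / A) * 1e4 * 100` patches
#'     per 100 ha (A in m2).}
#'   \item{lpi_pct}{largest patch index, `100 * max(a_ij) / A`.}
#'   \item{enn_mn_m}{mean Euclidean nearest-neighbour distance over the
#'     patches for which it is defined; `NA` when `np < 2`.}
#'   \item{mesh_ha}{effective mesh size, `(sum a_ij^2 / A) / 1e4` ha.}
#' }
#' With no patches, `np`, `pd`, `lpi` and `mesh` are 0 and the two mean
#' metrics are `NA` (missing, never zero).
#'
#' @param patches a [PatchSet-class]; run [computeEnn] first if
#'   `enn_mn_m` is wanted.
#' @return one-row `data.frame` with the columns above.
#' @export
computeClassMetrics <- function(patches) {
  stopifnot(is(patches, "PatchSet"))
  A <- patches@landscapeAreaM2
  if (A <= 0)
    stop("landscape area is zero (fully-nodata landscape)")
  rec <- patches@records
  n <- nrow(rec)
  a <- rec$area_m2
  total <- sum(a)
  out <- data.frame(
    pa_mn_ha = if (n) (total / n) / 1e4 else NA_real_,
    np = n,
    pd_per100ha = (n / A) * 1e4 * 100,
    lpi_pct = if (n) 100 * max(a) / A else 0,
    enn_mn_m = if (any(!is.na(rec$enn_m)))
      mean(rec$enn_m, na.rm = TRUE) else NA_real_,
    mesh_ha = sum(a^2) / A / 1e4,
    total_class_area_ha = total / 1e4,
    landscape_area_ha = A / 1e4
  )
  out
}

#' Metric table for a multi-raster series
#'
#' Runs [naturalBinary], [labelPatches], [computeEnn] and
#' [computeClassMetrics] over a series of three-class rasters and returns
#' a long-format table with one row per (source, zone, year).
#'
#' @param rasters list of three-class [CategoricalRaster-class] objects
#'   (binary 0/1 rasters are also accepted).
#' @param source,zone,year vectors recycled against `rasters` labelling
#'   each entry; `(source, zone, year)` keys must be unique.
#' @return `data.frame` with columns `source`, `zone`, `year` and the
#'   eight metric columns. Missing metric values stay `NA` (written as
#'   empty fields by [utils::write.csv]), never 0.
#' @export
metricsTable <- function(rasters, source, zone, year) {
  if (is(rasters, "CategoricalRaster")) rasters <- list(rasters)
  k <- length(rasters)
  keys <- data.frame(source = rep_len(as.character(source), k),
                     zone = rep_len(as.character(zone), k),
                     year = rep_len(as.integer(year), k))
  if (anyDuplicated(keys))
    stop("duplicate (source, zone, year) key: ",
         paste(unlist(keys[duplicated(keys), ][1, ]), collapse = "/"))
  rows <- lapply(seq_len(k), function(i) {
    r <- rasters[[i]]
    b <- if (all(r@codes %in% c(0L, 1L) | is.na(r@codes))) r
         else naturalBinary(r)
    computeClassMetrics(computeEnn(labelPatches(b)))
  })
  cbind(keys, do.call(rbind, rows))
}
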