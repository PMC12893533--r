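#' Delineate 8-connected patches of natural cover
#'
#' Two foreground cells belong to the same patch iff they are connected
#' through a chain of horizontally, vertically or diagonally adjacent
#' foreground cells (the eight-neighbouring-cell rule). Nodata cells are
#' non-foreground and never connect. Labels are assigned in row-major
#' discovery order, so the labeling is deterministic.
#'
#' @param binary a [CategoricalRaster-class] with codes in `{0, 1}` plus
#'   nodata (see [naturalBinary]).
#' @return a [PatchSet-class]; `enn_m` in the records is `NA` until
#'   [computeEnn] is applied.
#' @examples
#' b <- categoricalRaster(matrix(c(1L, 0L, 0L, 1L), 2, 2))
#' nPatches(labelPatches(b))  # diagonal cells connect: one patch
#' @export
labelPatches <- function(binary) {
  stopifnot(is(binary, "CategoricalRaster"))
  cd <- binary@codes
  if (!all(cd %in% c(0L, 1L) | is.na(cd)))
    stop("labelPatches needs a binary raster (codes 0/1 plus nodata); ",
         "found: ", paste(sort(unique(cd[!cd %in% c(0L, 1L) & !is.na(cd)])),
                          collapse = ", "))
  lab <- cpp_label8(cd)
  n <- max(lab)
  counts <- if (n) tabulate(lab[lab > 0L], nbins = n) else integer()
  cell2 <- binary@cellSize^2
  rec <- data.frame(
    patch_id = seq_len(n),
    cell_count = counts,
    area_m2 = counts * cell2,
    enn_m = rep(NA_real_, n)
  )
  new("PatchSet", labels = lab, records = rec,
      landscapeAreaM2 = sum(!is.na(cd)) * cell2,
      cellSize = binary@cellSize)
}

#' Euclidean nearest-neighbour distance per patch
#'
#' For each patch, the minimum over all other patches of the minimum
#' cell-centre-to-cell-centre Euclidean distance between the two patches'
#' cells (so two single cells separated by one empty cell in a row are
#' two cell widths apart). With a single patch the distance is undefined
#' and stays `NA`; with no patches the records are empty.
#'
#' Only patch boundary cells are scanned — the nearest cells of two
#' distinct patches are necessarily boundary cells, so the pruning is
#' distance-preserving.
#'
#' @param patches a [PatchSet-class] from [labelPatches].
#' @return the [PatchSet-class] with `enn_m` filled in.
#' @export
computeEnn <- function(patches) {
  stopifnot(is(patches, "PatchSet"))
  n <- nrow(patches@records)
  patches@records$enn_m <-
    as.numeric(cpp_patch_enn(patches@labels, n, patches@cellSize))
  validObject(patches)
  patches
}
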