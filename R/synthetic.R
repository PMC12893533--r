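## Seeded neutral-landscape generator for paired two-source LULC time
## series. The process model is a minimal distance-decay deforestation
## frontier: clearing starts from a road corridor, each step converts
## forest cells with probability frontierRate * exp(-d / delta) where d is
## the Euclidean distance (in cells) to the nearest already-cleared cell,
## and adds a Poisson number of independent small clearings (1-5 cells).
## Two observation sources view the same truth: source A generalises
## (majority filter, erasing small clearings — larger, fewer patches) and
## source B adds per-cell salt-and-pepper noise (resolving, and slightly
## over-segmenting, fine structure — many more, smaller patches).
## Forest is absorbing: area is non-increasing over years.

#' Default road corridor: a full-width horizontal swath at mid-height
#' with a vertical branch from the centre to the top edge. The corridor
#' is `width` cells wide so that it survives the generalising source's
#' majority smoothing, as a real cleared road swath would.
#' @param nrows,ncols grid size.
#' @param width corridor width in cells.
#' @return two-column integer matrix of (row, col) road cells.
#' @export
defaultRoadCells <- function(nrows, ncols, width = 5L) {
  mid <- as.integer(ceiling(nrows / 2))
  vc <- as.integer(ceiling(ncols / 2))
  h <- as.integer(width) %/% 2L
  horiz <- expand.grid(row = (mid - h):(mid + h), col = seq_len(ncols))
  vert <- expand.grid(row = seq_len(mid - h - 1L), col = (vc - h):(vc + h))
  cells <- unique(rbind(horiz, vert))
  cells <- cells[cells$row >= 1L & cells$row <= nrows &
                 cells$col >= 1L & cells$col <= ncols, ]
  cbind(as.integer(cells$row), as.integer(cells$col))
}

#' Define a synthetic deforestation scenario
#'
#' Defaults emulate the dual-source study design: a 200 x 200 grid of
#' 30 m cells observed in the eight map years 1990-2022, a road-seeded
#' deforestation frontier, a generalising source A (majority radius 3,
#' i.e. 7 x 7) and a fine-grained source B (1% per-cell systematic flip
#' noise).
#'
#' @param nrows,ncols grid size (default 200 x 200).
#' @param cellSize cell side in metres (default 30).
#' @param seed master seed; the same seed reproduces the dataset
#'   bit-identically. The clearing process and source-B noise use
#'   independent streams derived from it, so changing `sourceBNoise`
#'   never perturbs the true series.
#' @param years strictly increasing map years.
#' @param roadCells two-column (row, col) matrix; default
#'   [defaultRoadCells].
#' @param frontierRate per-step clearing probability scale in `[0, 1]`.
#' @param delta distance-decay scale in cells (> 0).
#' @param smallclearLambda expected number of new independent small
#'   clearings (1-5 cells) per step.
#' @param sourceASmoothRadius majority-filter radius of source A, cells.
#' @param sourceBNoise per-cell flip probability of source B.
#' @return a `SyntheticScenario` list.
#' @export
syntheticScenario <- function(nrows = 200, ncols = 200, cellSize = 30,
                              seed = 1L,
                              years = c(1990, 2000, 2008, 2014, 2016,
                                        2018, 2020, 2022),
                              roadCells = NULL,
                              frontierRate = 0.22, delta = 2.5,
                              smallclearLambda = 6,
                              sourceASmoothRadius = 3L,
                              sourceBNoise = 0.01) {
  if (is.null(roadCells)) roadCells <- defaultRoadCells(nrows, ncols)
  roadCells <- matrix(as.integer(roadCells), ncol = 2L)
  sc <- list(nrows = as.integer(nrows), ncols = as.integer(ncols),
             cellSize = cellSize, seed = as.integer(seed), years = years,
             roadCells = roadCells, frontierRate = frontierRate,
             delta = delta, smallclearLambda = smallclearLambda,
             sourceASmoothRadius = as.integer(sourceASmoothRadius),
             sourceBNoise = sourceBNoise)
  if (sc$nrows < 1L || sc$ncols < 1L) stop("grid must be non-empty")
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (frontierRate < 0 || frontierRate > 1 || sourceBNoise < 0 ||
      sourceBNoise > 1)
    stop("probabilities must lie in [0, 1]")
  if (delta <= 0) stop("delta must be positive")
  if (smallclearLambda < 0) stop("smallclearLambda must be non-negative")
  if (any(roadCells[, 1L] < 1L | roadCells[, 1L] > sc$nrows |
          roadCells[, 2L] < 1L | roadCells[, 2L] > sc$ncols))
    stop("road cells outside the grid")
  structure(sc, class = "SyntheticScenario")
}

binaryFromMatrix <- function(m, cellSize) {
  categoricalRaster(m, cellSize = cellSize, nodata = -9999L,
                    legend = c(`0` = "non-natural", `1` = "natural"))
}

## one Poisson-sized crop of small clearings grown by random adjacency
punchSmallClearings <- function(state, lambda) {
  k <- stats::rpois(1L, lambda)
  if (k == 0L) return(state)
  nr <- nrow(state); nc <- ncol(state)
  for (i in seq_len(k)) {
    forestIdx <- which(state == 1L)
    if (!length(forestIdx)) break
    size <- sample(1:5, 1L)
    seedCell <- forestIdx[sample.int(length(forestIdx), 1L)]
    cells <- seedCell
    state[seedCell] <- 0L
    while (length(cells) < size) {
      rc <- arrayInd(cells, c(nr, nc))
      nb <- rbind(cbind(rc[, 1L] - 1L, rc[, 2L]),
                  cbind(rc[, 1L] + 1L, rc[, 2L]),
                  cbind(rc[, 1L], rc[, 2L] - 1L),
                  cbind(rc[, 1L], rc[, 2L] + 1L))
      nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= nr &
               nb[, 2L] >= 1L & nb[, 2L] <= nc, , drop = FALSE]
      cand <- unique(nb[, 1L] + (nb[, 2L] - 1L) * nr)
      cand <- cand[state[cand] == 1L]
      if (!length(cand)) break
      nxt <- cand[sample.int(length(cand), 1L)]
      state[nxt] <- 0L
      cells <- c(cells, nxt)
    }
  }
  state
}

#' Generate the true deforestation series
#'
#' Year 1 is all forest minus the road cells; each subsequent year clears
#' forest with the distance-decay frontier probability and punches
#' `Poisson(smallclearLambda)` small clearings. Deterministic given the
#' scenario seed; forest area is non-increasing over years.
#'
#' @param scenario a [syntheticScenario].
#' @return named list (by year) of binary [CategoricalRaster-class].
#' @export
generateTrueSeries <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  set.seed(scenario$seed)
  nr <- scenario$nrows; nc <- scenario$ncols
  state <- matrix(1L, nr, nc)
  state[scenario$roadCells] <- 0L
  out <- vector("list", length(scenario$years))
  names(out) <- scenario$years
  out[[1L]] <- binaryFromMatrix(state, scenario$cellSize)
  for (step in seq_along(scenario$years)[-1L]) {
    if (any(state == 0L) && any(state == 1L)) {
      d <- EBImage::distmap(state, metric = "euclidean")
      d <- matrix(as.numeric(d), nr, nc)
      p <- scenario$frontierRate * exp(-d / scenario$delta)
      clear <- state == 1L & matrix(stats::runif(nr * nc), nr, nc) < p
      state[clear] <- 0L
    }
    state <- punchSmallClearings(state, scenario$smallclearLambda)
    out[[step]] <- binaryFromMatrix(state, scenario$cellSize)
  }
  out
}

#' Generalising observation source (majority smoothing)
#'
#' Each cell takes the majority value of its clipped
#' `(2 radius + 1)^2` neighbourhood, ties going to forest; radius 0 is
#' the identity. Small clearings vanish, patch outlines are simplified —
#' the coarse-source behaviour of the study design.
#'
#' @param true binary [CategoricalRaster-class].
#' @param radius majority-filter radius in cells.
#' @return binary [CategoricalRaster-class].
#' @export
deriveSourceA <- function(true, radius) {
  stopifnot(is(true, "CategoricalRaster"), radius >= 0)
  if (radius == 0) return(true)
  cd <- true@codes
  valid <- !is.na(cd)
  forest <- valid & cd == 1L
  fs <- boxSum(forest + 0, as.integer(radius))
  vs <- boxSum(valid + 0, as.integer(radius))
  out <- matrix(NA_integer_, nrow(cd), ncol(cd))
  out[valid] <- ifelse(2 * fs[valid] >= vs[valid], 1L, 0L)
  binaryFromMatrix(out, true@cellSize)
}

#' Fine-grained observation source (classification noise)
#'
#' Each non-nodata cell flips independently with probability `noise`;
#' deterministic given `seed`. Emulates a sensitive classifier that
#' resolves small clearings but also speckles — the fine-source
#' behaviour of the study design.
#'
#' @param true binary [CategoricalRaster-class].
#' @param noise per-cell flip probability in `[0, 1]`.
#' @param seed integer seed for the flip stream.
#' @return binary [CategoricalRaster-class].
#' @export
deriveSourceB <- function(true, noise, seed) {
  stopifnot(is(true, "CategoricalRaster"), noise >= 0, noise <= 1)
  set.seed(as.integer(seed))
  cd <- true@codes
  flip <- matrix(stats::runif(length(cd)) < noise, nrow(cd), ncol(cd))
  out <- cd
  sel <- flip & !is.na(cd)
  out[sel] <- 1L - cd[sel]
  binaryFromMatrix(out, true@cellSize)
}

#' Generate the full paired two-source dataset
#'
#' Runs the true series, derives sources A (majority-smoothed) and B
#' (noisy) for every year and returns three-class rasters (forest ->
#' natural, cleared -> anthropic) plus a manifest echoing the scenario.
#' Source-B noise uses a stream independent of the clearing process, both
#' derived from the master seed. The same flip seed is applied to every
#' year: the fine source's errors model a consistent classification
#' algorithm that misclassifies the same pixels each year (systematic
#' bias), not independent annual speckle — so the fine source's patch
#' count grows monotonically with the cleared area rather than
#' fluctuating with resampled noise.
#'
#' @param scenario a [syntheticScenario].
#' @param dir optional directory; when given, every raster is written as
#'   an ESRI ASCII grid plus `manifest.yaml`.
#' @return list with `sources` (nested `A`/`B` by year,
#'   [CategoricalRaster-class] three-class), `truth` (binary series) and
#'   `manifest`.
#' @export
generatePairedDataset <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  truth <- generateTrueSeries(scenario)
  noiseSeed <- (scenario$seed * 7919L + 1000003L) %% .Machine$integer.max
  toClass3 <- function(b) {
    cd <- b@codes
    out <- ifelse(is.na(cd), NA_integer_,
                  ifelse(cd == 1L, NATURAL, ANTHROPIC))
    categoricalRaster(matrix(as.integer(out), nrow(cd), ncol(cd)),
                      cellSize = b@cellSize, nodata = b@nodata,
                      legend = CLASS3_LEGEND)
  }
  A <- B <- vector("list", length(truth))
  names(A) <- names(B) <- names(truth)
  for (i in seq_along(truth)) {
    A[[i]] <- toClass3(deriveSourceA(truth[[i]],
                                     scenario$sourceASmoothRadius))
    B[[i]] <- toClass3(deriveSourceB(truth[[i]], scenario$sourceBNoise,
                                     seed = noiseSeed))
  }
  manifest <- list(
    scenario = scenario[setdiff(names(scenario), "roadCells")],
    road_cell_count = nrow(scenario$roadCells),
    sources = c("A", "B"), years = scenario$years
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (src in c("A", "B")) {
      set <- if (src == "A") A else B
      for (yr in names(set))
        writeCategoricalRaster(
          set[[yr]], file.path(dir, sprintf("%s_%s.asc", src, yr)))
    }
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  list(sources = list(A = A, B = B), truth = truth, manifest = manifest)
}
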