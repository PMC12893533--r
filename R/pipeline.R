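## Config-driven orchestration of the full study design:
## reclassify -> clip -> patch metrics -> multiscale FAD -> change ->
## paired source comparison, run independently per source x zone, with a
## reproducible output layout (metrics.csv, comparison.csv, transition
## and change-profile CSVs, class rasters, manifest.yaml, run.log).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a pipeline run configuration
#'
#' YAML schema:
#' \preformatted{
#' sources:
#'   <name>:
#'     scheme: reclass CSV path (optional; omit for 3-class inputs)
#'     years: {<year>: <raster path>, ...}
#' zones:
#'   <name>: <0/1 mask raster path, or ~ for the full grid>
#' fad: {scales: [7,13,27,81,243], classes: 6}
#' comparison: {alpha: 0.05, round: true}
#' output_dir: <dir>
#' }
#' Relative paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  abs <- function(p) if (is.null(p) || file.exists(p)) p
                     else file.path(base, p)
  if (is.null(cfg$sources) || !length(cfg$sources))
    stop("config must declare at least one source")
  if (is.null(cfg$zones) || !length(cfg$zones))
    stop("config must declare at least one zone")
  for (s in names(cfg$sources)) {
    src <- cfg$sources[[s]]
    if (is.null(src$years) || !length(src$years))
      stop("source '", s, "' declares no years")
    cfg$sources[[s]]$years <- lapply(src$years, abs)
    cfg$sources[[s]]$scheme <- abs(src$scheme)
  }
  cfg$zones <- lapply(cfg$zones, abs)
  cfg$output_dir <- cfg$output_dir %||% "fragscape-output"
  cfg
}

pipelineLogger <- function(logPath) {
  con <- file(logPath, open = "wt")
  list(
    log = function(...) {
      line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                      paste0(...))
      writeLines(line, con)
      message(line)
    },
    close = function() close(con)
  )
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full fragmentation pipeline
#'
#' Per source x zone: reclassifies (when a scheme is configured), clips
#' to the zone, computes the six class metrics for every year, runs the
#' multiscale FAD classification for the first and last year, and writes
#' the transition matrix, natural-loss hectares and change profile for
#' that endpoint pair. Per zone, the first two sources are compared with
#' the paired signed-rank test across all metrics. Outputs are written
#' under `outputDir` with stable ordering and fixed rounding, so a rerun
#' on identical inputs is byte-identical.
#'
#' @param config a config list, or the path of a YAML file for
#'   [readRunConfig].
#' @param outputDir output directory; defaults to `config$output_dir`.
#' @return (invisibly) list with `metrics`, `comparisons`, `transitions`,
#'   `changeProfiles`, `loss` and `manifest`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  outputDir <- outputDir %||% config$output_dir
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  lg <- pipelineLogger(file.path(outputDir, "run.log"))
  on.exit(lg$close(), add = TRUE)

  alpha <- config$comparison$alpha %||% 0.05
  doRound <- isTRUE(config$comparison$round %||% TRUE)
  scales <- as.integer(config$fad$scales %||% FAD_SCALES)
  scheme <- fadClassScheme(config$fad$classes %||% 6)

  inputs <- character()
  artifacts <- character()
  metricsRows <- list(); comparisons <- list()
  transitions <- list(); profiles <- list(); losses <- list()

  zones <- config$zones
  for (zn in names(zones)) {
    mask <- NULL
    if (!is.null(zones[[zn]])) {
      lg$log("zone ", zn, ": reading mask ", zones[[zn]])
      mask <- stageTry("zone-mask",
                       zoneMask(readCategoricalRaster(zones[[zn]]), zn))
      inputs <- c(inputs, zones[[zn]])
    }
    zoneTables <- list()
    for (sn in names(config$sources)) {
      src <- config$sources[[sn]]
      schemeMap <- NULL
      if (!is.null(src$scheme)) {
        schemeMap <- stageTry("reclass-scheme", readReclassScheme(src$scheme))
        inputs <- c(inputs, src$scheme)
      }
      yrs <- sort(as.integer(names(src$years)))
      lg$log("source ", sn, " zone ", zn, ": ", length(yrs), " year(s)")
      binaries <- list()
      clipped <- list()
      for (yr in yrs) {
        p <- src$years[[as.character(yr)]]
        inputs <- c(inputs, p)
        r <- stageTry("read", readCategoricalRaster(p))
        if (!is.null(schemeMap))
          r <- stageTry("reclassify", reclassify(r, schemeMap))
        if (!is.null(mask)) r <- stageTry("clip", clipToZone(r, mask))
        clipped[[as.character(yr)]] <- r
        binaries[[as.character(yr)]] <- stageTry("binary", naturalBinary(r))
      }
      tb <- stageTry("metrics",
                     metricsTable(clipped, source = sn, zone = zn,
                                  year = yrs))
      metricsRows[[paste(sn, zn)]] <- tb
      zoneTables[[sn]] <- tb

      y1 <- as.character(yrs[1L]); y2 <- as.character(yrs[length(yrs)])
      lg$log("source ", sn, " zone ", zn, ": multiscale FAD ", y1, " vs ",
             y2)
      ms1 <- stageTry("fad", multiscaleFAD(binaries[[y1]], scales, scheme,
                                           tag = y1))
      ms2 <- stageTry("fad", multiscaleFAD(binaries[[y2]], scales, scheme,
                                           tag = y2))
      for (d in list(list(y1, ms1), list(y2, ms2))) {
        for (w in names(d[[2L]]$perScaleClass)) {
          fp <- file.path(outputDir,
                          sprintf("fradclass_%s_%s_%s_w%s.asc",
                                  zn, sn, d[[1L]], w))
          artifacts <- c(artifacts,
                         writeClassRaster(d[[2L]]$perScaleClass[[w]], fp))
        }
        fp <- file.path(outputDir, sprintf("fradclass_%s_%s_%s_avg.asc",
                                           zn, sn, d[[1L]]))
        artifacts <- c(artifacts,
                       writeClassRaster(d[[2L]]$averageClass, fp))
      }
      tm <- stageTry("transitions",
                     transitionMatrix(ms1$averageClass, ms2$averageClass))
      transitions[[paste(sn, zn)]] <- tm
      tp <- file.path(outputDir, sprintf("transitions_%s_%s.csv", zn, sn))
      ct <- as.data.frame(transitionCounts(tm))
      artifacts <- c(artifacts,
                     writeTable(cbind(from = rownames(ct), ct), tp))
      pr <- stageTry("change-profile",
                     changeProfile(ms1$perScaleClass, ms2$perScaleClass,
                                   dates = c(y1, y2)))
      profiles[[paste(sn, zn)]] <- pr
      artifacts <- c(artifacts, writeTable(
        pr, file.path(outputDir,
                      sprintf("change_profile_%s_%s.csv", zn, sn))))
      losses[[paste(sn, zn)]] <- data.frame(
        source = sn, zone = zn, year1 = as.integer(y1),
        year2 = as.integer(y2),
        natural_loss_ha = naturalLossArea(binaries[[y1]], binaries[[y2]]))
    }
    if (length(zoneTables) >= 2L) {
      sa <- names(zoneTables)[1L]; sb <- names(zoneTables)[2L]
      lg$log("zone ", zn, ": comparing sources ", sa, " vs ", sb)
      cmp <- stageTry("comparison",
                      compareAll(zoneTables[[sa]], zoneTables[[sb]],
                                 zones = zn, alpha = alpha))
      cmp <- cbind(source_1 = sa, source_2 = sb, cmp)
      comparisons[[zn]] <- cmp
    }
  }

  metrics <- do.call(rbind, metricsRows)
  rownames(metrics) <- NULL
  artifacts <- c(artifacts,
                 writeTable(metrics, file.path(outputDir, "metrics.csv")))
  loss <- do.call(rbind, losses)
  rownames(loss) <- NULL
  artifacts <- c(artifacts,
                 writeTable(loss, file.path(outputDir,
                                            "natural_loss.csv")))
  cmpAll <- NULL
  if (length(comparisons)) {
    cmpAll <- do.call(rbind, comparisons)
    rownames(cmpAll) <- NULL
    out <- cmpAll
    if (doRound) {
      out$p_value <- round(out$p_value, 4L)
      out$r_effect <- round(out$r_effect, 3L)
    }
    artifacts <- c(artifacts,
                   writeTable(out, file.path(outputDir, "comparison.csv")))
  }

  manifest <- list(
    inputs = lapply(sort(unique(inputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = sort(basename(artifacts)),
    fad = list(scales = scales, classes = nrow(scheme)),
    alpha = alpha
  )
  yaml::write_yaml(manifest, file.path(outputDir, "manifest.yaml"))
  lg$log("pipeline complete: ", length(artifacts), " artifact(s) in ",
         outputDir)
  invisible(list(metrics = metrics, comparisons = cmpAll,
                 transitions = transitions, changeProfiles = profiles,
                 loss = loss, manifest = manifest))
}

## class maps serialise as ordinary categorical rasters (codes 0..K)
writeClassRaster <- function(fc, path) {
  leg <- stats::setNames(c("nonforest", fc@scheme$name),
                         c(0L, fc@scheme$code))
  r <- categoricalRaster(fc@classes, cellSize = fc@cellSize,
                         nodata = -9999L, legend = leg)
  writeCategoricalRaster(r, path)
}
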