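Package: fragscape
Title: Landscape Fragmentation Analysis of Categorical Land-Cover Rasters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying forest fragmentation from categorical
    land-use/land-cover rasters. Delineates 8-connected patches of natural
    cover and computes six class-level landscape metrics (mean patch area,
    number of patches, patch density, largest patch index, mean Euclidean
    nearest-neighbour distance, effective mesh size); maps per-pixel forest
    area density (FAD) at multiple moving-window scales and classifies it
    into ordered fragmentation classes with between-date change and
    transition accounting; and compares paired metric time series from two
    land-cover sources with the exact Wilcoxon signed-rank test and a
    standardised effect size. Includes a seeded neutral-landscape simulator
    of progressive road-corridor deforestation observed by a generalising
    and a fine-grained source, and a config-driven pipeline that runs the
    full reclassify-clip-metrics-FAD-compare study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
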