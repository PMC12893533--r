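test_that("all-forest raster scores FAD 100 everywhere, including borders", {
  f <- computeFAD(makeBinary(matrix(1L, 5, 5)), 3)
  expect_true(all(fadValues(f) == 100))
})

test_that("hand-computed window proportions: 8/9 and 1/9", {
  m <- matrix(1L, 5, 5); m[3, 3] <- 0L
  f <- computeFAD(makeBinary(m), 3)
  expect_equal(fadValues(f)[2, 2], 100 * 8 / 9, tolerance = 1e-12)
  iso <- matrix(0L, 5, 5); iso[3, 3] <- 1L
  f2 <- computeFAD(makeBinary(iso), 3)
  expect_equal(fadValues(f2)[3, 3], 100 * 1 / 9, tolerance = 1e-12)
})

test_that("FAD is undefined off the foreground and rejects bad windows", {
  m <- matrix(c(1L, 0L, NA, 1L), 2, 2)
  f <- computeFAD(makeBinary(m), 3)
  expect_true(is.na(fadValues(f)[1, 2]))
  expect_true(is.na(fadValues(f)[2, 1]))
  b <- makeBinary(matrix(1L, 3, 3))
  expect_error(computeFAD(b, 4), "odd")
  expect_error(computeFAD(b, 1), "odd")
})

test_that("nodata cells drop out of the FAD denominator", {
  m <- matrix(1L, 3, 3); m[1, 1] <- NA; m[3, 3] <- 0L
  f <- computeFAD(makeBinary(m), 3)
  # centre window: 8 valid cells (one nodata), 7 forest
  expect_equal(fadValues(f)[2, 2], 100 * 7 / 8, tolerance = 1e-12)
})

test_that("FAD matches the per-pixel double-loop oracle on random rasters", {
  set.seed(301)
  for (i in 1:50) {
    m <- randomBinaryMatrix(30, 30, runif(1, 0.2, 0.9),
                            pNodata = if (i %% 5 == 0) 0.1 else 0)
    for (w in c(3L, 7L)) {
      got <- fadValues(computeFAD(makeBinary(m), w))
      ref <- naiveFad(m, w)
      expect_equal(got, ref, tolerance = 1e-9,
                   label = sprintf("fixture %d window %d", i, w))
    }
  }
})

test_that("growing forest never lowers FAD anywhere", {
  set.seed(302)
  for (i in 1:10) {
    m <- randomBinaryMatrix(20, 20, 0.5)
    bg <- which(m == 0L)
    if (!length(bg)) next
    m2 <- m; m2[sample(bg, 1)] <- 1L
    f1 <- fadValues(computeFAD(makeBinary(m), 5))
    f2 <- fadValues(computeFAD(makeBinary(m2), 5))
    common <- !is.na(f1) & !is.na(f2)
    expect_true(all(f2[common] >= f1[common] - 1e-12))
  }
})

test_that("classification is lower-inclusive and order-preserving", {
  sch <- fadClassScheme()
  mk <- function(v) {
    f <- new("FADRaster", values = matrix(v, 1, 1), window = "3",
             cellSize = 30)
    fragClasses(classifyFAD(f, sch))[1, 1]
  }
  expect_equal(mk(100), 6)       # intact only at exactly 100
  expect_equal(mk(99.99), 5)
  expect_equal(mk(100 * 8 / 9), 4)   # 88.89 is dominant
  expect_equal(mk(10), 2)        # boundary joins the class above
  expect_equal(mk(9.999), 1)
  expect_equal(mk(0), 1)
  vals <- sort(runif(50, 0, 100))
  expect_true(!is.unsorted(vapply(vals, mk, 0L)))
})

test_that("multiscale average lies between per-scale extremes", {
  set.seed(303)
  m <- randomBinaryMatrix(40, 40, 0.6)
  ms <- multiscaleFAD(makeBinary(m), scales = c(3, 7, 13))
  avg <- fadValues(ms$averageFad)
  stack <- simplify2array(lapply(ms$perScaleFad, fadValues))
  lo <- apply(stack, c(1, 2), min)
  hi <- apply(stack, c(1, 2), max)
  fg <- !is.na(avg)
  expect_true(all(avg[fg] >= lo[fg] - 1e-12 & avg[fg] <= hi[fg] + 1e-12))
})

test_that("all-forest raster is 100% intact at every scale and on average", {
  ms <- multiscaleFAD(makeBinary(matrix(1L, 30, 30)))
  for (fc in c(ms$perScaleClass, list(ms$averageClass)))
    expect_true(all(fragClasses(fc) == 6L))
})

test_that("a window covering the grid degenerates to the global proportion", {
  set.seed(304)
  m <- randomBinaryMatrix(9, 9, 0.5, pNodata = 0.1)
  f <- fadValues(computeFAD(makeBinary(m), 243))
  expected <- 100 * sum(m == 1L, na.rm = TRUE) / sum(!is.na(m))
  fg <- !is.na(f)
  expect_true(all(abs(f[fg] - expected) < 1e-9))
})

test_that("transition matrix counts states and conserves cells", {
  sch <- fadClassScheme()
  mkClass <- function(v)
    new("FragClassRaster",
        classes = matrix(as.integer(v), 1, length(v)),
        scheme = sch, provenance = "test", cellSize = 30)
  c1 <- mkClass(c(6, 6, 5, 0))
  c2 <- mkClass(c(6, 5, 0, 0))
  tm <- transitionMatrix(c1, c2)
  ct <- transitionCounts(tm)
  expect_equal(ct["intact", "intact"], 1)
  expect_equal(ct["intact", "interior"], 1)
  expect_equal(ct["interior", "nonforest"], 1)
  expect_equal(ct["nonforest", "nonforest"], 1)
  expect_equal(sum(ct), 4)
  # identity map is purely diagonal
  tmId <- transitionMatrix(c1, c1)
  expect_equal(sum(transitionCounts(tmId)),
               sum(diag(transitionCounts(tmId))))
  # rank ordering defines the fragmentation direction
  lg <- transitionLong(tm)
  expect_equal(lg$direction[lg$from == "intact" & lg$to == "interior"],
               "increase")
  expect_equal(lg$direction[lg$from == "interior" & lg$to == "intact"],
               "decrease")
})

test_that("transition totals equal co-valid cells on random fixtures", {
  set.seed(305)
  for (i in 1:10) {
    m1 <- randomBinaryMatrix(15, 15, 0.6, pNodata = 0.1)
    m2 <- m1; flip <- runif(length(m2)) < 0.2
    m2[flip & !is.na(m2)] <- 1L - m2[flip & !is.na(m2)]
    b1 <- makeBinary(m1); b2 <- makeBinary(m2)
    c1 <- classifyFAD(computeFAD(b1, 3), binary = b1)
    c2 <- classifyFAD(computeFAD(b2, 3), binary = b2)
    tm <- transitionMatrix(c1, c2)
    expect_equal(sum(transitionCounts(tm)),
                 sum(!is.na(m1) & !is.na(m2)))
    pct <- rowSums(transitionPercent(tm))
    expect_true(all(is.na(pct) | abs(pct - 100) < 1e-9))
  }
})

test_that("natural loss is the directional cleared area in hectares", {
  m1 <- matrix(1L, 3, 3)
  expect_equal(naturalLossArea(makeBinary(m1), makeBinary(m1)), 0)
  m2 <- m1; m2[2, 2] <- 0L
  expect_equal(naturalLossArea(makeBinary(m1), makeBinary(m2)), 0.09)
  expect_equal(naturalLossArea(makeBinary(m2), makeBinary(m1)), 0)
})

test_that("change profile normalises per date and scale", {
  set.seed(306)
  m1 <- randomBinaryMatrix(25, 25, 0.7)
  m2 <- m1; m2[m1 == 1L & runif(length(m1)) < 0.3] <- 0L
  ms1 <- multiscaleFAD(makeBinary(m1), scales = c(3, 7))
  ms2 <- multiscaleFAD(makeBinary(m2), scales = c(3, 7))
  pr <- changeProfile(ms1$perScaleClass, ms2$perScaleClass,
                      dates = c("t1", "t2"))
  sums <- tapply(pr$percent, list(pr$date, pr$scale), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(
    changeProfile(ms1$perScaleClass, ms2$perScaleClass[1],
                  dates = c("a", "b")),
    "scale mismatch")
  # all-forest both dates: everything intact
  msA <- multiscaleFAD(makeBinary(matrix(1L, 10, 10)), scales = c(3, 7))
  prA <- changeProfile(msA$perScaleClass, msA$perScaleClass)
  expect_true(all(prA$percent[prA$class == "intact"] == 100))
  expect_true(all(prA$percent[prA$class != "intact"] == 0))
})
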