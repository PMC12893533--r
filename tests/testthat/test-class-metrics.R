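twoBlockFixture <- function() {
  m <- matrix(0L, 6, 6)
  m[1:2, 1:2] <- 1L
  m[4:6, 4:6] <- 1L
  computeEnn(labelPatches(makeBinary(m, 30)))
}

test_that("6x6 fixture reproduces the hand-computed metric values", {
  cm <- computeClassMetrics(twoBlockFixture())
  expect_equal(cm$np, 2)
  expect_equal(cm$pa_mn_ha, 0.585)
  expect_equal(cm$pd_per100ha, 2 / 32400 * 1e4 * 100, tolerance = 1e-12)
  expect_equal(cm$pd_per100ha, 61.7284, tolerance = 1e-6)
  expect_equal(cm$lpi_pct, 25)
  # (3600^2 + 8100^2) / 32400 = 2425 m^2 exactly
  expect_equal(cm$mesh_ha, (3600^2 + 8100^2) / 32400 / 1e4)
  expect_equal(cm$mesh_ha, 0.2425)
})

test_that("a single saturating patch gives LPI 100 and MESH = A", {
  ps <- computeEnn(labelPatches(makeBinary(matrix(1L, 6, 6), 30)))
  cm <- computeClassMetrics(ps)
  expect_equal(cm$np, 1)
  expect_equal(cm$lpi_pct, 100)
  expect_equal(cm$mesh_ha, cm$landscape_area_ha)
  expect_equal(cm$mesh_ha, 3.24)
  expect_equal(cm$pd_per100ha, 30.8642, tolerance = 1e-6)
  expect_true(is.na(cm$enn_mn_m))
})

test_that("an empty class yields zero counts and missing means", {
  cm <- computeClassMetrics(labelPatches(makeBinary(matrix(0L, 6, 6))))
  expect_equal(cm$np, 0)
  expect_equal(cm$lpi_pct, 0)
  expect_equal(cm$mesh_ha, 0)
  expect_equal(cm$pd_per100ha, 0)
  expect_true(is.na(cm$pa_mn_ha))
  expect_true(is.na(cm$enn_mn_m))
  expect_error(
    computeClassMetrics(labelPatches(makeBinary(
      matrix(NA_integer_, 2, 2)))),
    "zero")
})

test_that("all six metrics match naive formula evaluation on random rasters", {
  set.seed(202)
  for (i in 1:100) {
    m <- randomBinaryMatrix(20, 20, pForest = runif(1, 0.1, 0.8),
                            pNodata = if (i %% 5 == 0) 0.15 else 0)
    ps <- computeEnn(labelPatches(makeBinary(m)))
    cm <- computeClassMetrics(ps)
    ref <- naiveMetrics(patchLabels(ps), 30, sum(!is.na(m)))
    for (f in names(ref)) {
      if (is.na(ref[[f]])) expect_true(is.na(cm[[f]]))
      else expect_equal(cm[[f]], ref[[f]], tolerance = 1e-9,
                        label = paste(f, "fixture", i))
    }
  }
})

test_that("conservation and Cauchy-Schwarz bounds hold on random rasters", {
  set.seed(203)
  for (i in 1:50) {
    m <- randomBinaryMatrix(25, 25, runif(1, 0.1, 0.9))
    cm <- computeClassMetrics(computeEnn(labelPatches(makeBinary(m))))
    if (cm$np > 0) {
      expect_equal(cm$np * cm$pa_mn_ha, cm$total_class_area_ha,
                   tolerance = 1e-9)
      A <- cm$landscape_area_ha
      expect_gte(cm$mesh_ha * (1 + 1e-12),
                 cm$total_class_area_ha^2 / (cm$np * A))
      expect_lte(cm$mesh_ha,
                 (cm$lpi_pct / 100) * cm$total_class_area_ha *
                   (1 + 1e-12))
      expect_lte(cm$mesh_ha, A)
      expect_lte(cm$lpi_pct, 100)
    }
  }
})

test_that("deleting a whole patch reduces NP by one and never grows area", {
  set.seed(204)
  for (i in 1:20) {
    m <- randomBinaryMatrix(15, 15, 0.35)
    ps <- labelPatches(makeBinary(m))
    if (nPatches(ps) < 2) next
    kill <- sample(nPatches(ps), 1)
    m2 <- m; m2[patchLabels(ps) == kill] <- 0L
    cm <- computeClassMetrics(ps)
    cm2 <- computeClassMetrics(labelPatches(makeBinary(m2)))
    expect_equal(cm2$np, cm$np - 1)
    expect_lt(cm2$total_class_area_ha, cm$total_class_area_ha)
  }
})

test_that("metricsTable keys, determinism, and missing-value handling", {
  m1 <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  m2 <- matrix(2L, 2, 2)
  r1 <- categoricalRaster(m1); r2 <- categoricalRaster(m2)
  tb <- metricsTable(list(r1, r2, r1, r1, r2, r1),
                     source = rep(c("a", "b"), each = 3),
                     zone = "z", year = rep(c(2000, 2010, 2020), 2))
  expect_equal(nrow(tb), 6)
  expect_equal(tb$np[tb$source == "a" & tb$year == 2000],
               tb$np[tb$source == "b" & tb$year == 2020])
  allAnthro <- tb[tb$source == "a" & tb$year == 2010, ]
  expect_equal(allAnthro$np, 0)
  expect_true(is.na(allAnthro$pa_mn_ha))
  expect_error(
    metricsTable(list(r1, r1), source = "a", zone = "z",
                 year = c(2000, 2000)),
    "duplicate")
})
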