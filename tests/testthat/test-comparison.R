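test_that("all-same-sign differences at n=8 give the exact textbook pair", {
  res <- wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6, 7, 8) + 10, rep(10, 8))
  expect_equal(res$w_plus, 36)
  expect_equal(res$p_value, 2 / 2^8)
  expect_equal(round(res$p_value, 4), 0.0078)
  expect_equal(res$method, "exact")
  r <- wilcoxonEffectSize(res$w_plus, res$n_pairs)
  expect_equal(r, (18 / sqrt(51)) / sqrt(8), tolerance = 1e-12)
  expect_equal(round(r, 3), 0.891)
})

test_that("one flipped sign at n=8 gives p = 4/256", {
  d <- c(-1, 2, 3, 4, 5, 6, 7, 8)
  res <- wilcoxonSignedRank(d, rep(0, 8))
  expect_equal(res$w_plus, 35)
  expect_equal(res$p_value, 0.015625)
})

test_that("exact p agrees with full 2^n enumeration on random samples", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, sd = 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    res <- wilcoxonSignedRank(d, rep(0, length(d)))
    expect_equal(res$p_value, enumSignedRankP(d), tolerance = 1e-12,
                 label = paste("sample", i))
  }
})

test_that("the enumeration oracle itself satisfies the closed form 2/2^n", {
  for (n in c(4, 6, 8))
    expect_equal(enumSignedRankP(seq_len(n)), 2 / 2^n)
})

test_that("implementation agrees with stats::wilcox.test where comparable", {
  set.seed(402)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    d <- x - y
    if (any(d == 0) || any(duplicated(abs(d)))) next
    res <- wilcoxonSignedRank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(res$w_plus, unname(ref$statistic))
  }
})

test_that("ties in |d| fall back to the normal approximation", {
  res <- wilcoxonSignedRank(c(1, 1, 2, 3, -1), rep(0, 5))
  expect_equal(res$method, "normal-approximation")
  expect_true(res$p_value > 0 && res$p_value < 1)
})

test_that("zero differences are dropped; the all-zero sample is an error", {
  res <- wilcoxonSignedRank(c(0, 1, 2, 3), rep(0, 4))
  expect_equal(res$n_pairs, 3)
  expect_error(wilcoxonSignedRank(1:5, 1:5), "undefined")
})

test_that("sign-flip symmetry leaves p and r unchanged", {
  set.seed(403)
  for (i in 1:10) {
    d <- rnorm(8)
    a <- wilcoxonSignedRank(d, rep(0, 8))
    b <- wilcoxonSignedRank(-d, rep(0, 8))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(wilcoxonEffectSize(a$w_plus, a$n_pairs),
                 wilcoxonEffectSize(b$w_plus, b$n_pairs),
                 tolerance = 1e-12)
  }
})

test_that("p is invariant under a shared positive affine rescaling", {
  set.seed(404)
  x <- rnorm(8); y <- rnorm(8)
  a <- wilcoxonSignedRank(x, y)
  b <- wilcoxonSignedRank(3.7 * x + 11, 3.7 * y + 11)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("effect size is bounded by the n=8 extremes and zero-centred", {
  expect_equal(wilcoxonEffectSize(18, 8), 0)
  r0 <- wilcoxonEffectSize(0, 8)
  r36 <- wilcoxonEffectSize(36, 8)
  expect_equal(r0, r36, tolerance = 1e-12)
  for (w in 0:36)
    expect_lte(wilcoxonEffectSize(w, 8), r36 + 1e-12)
})

test_that("pairSeries pairs on the year intersection and drops missing", {
  t1 <- data.frame(source = "a", zone = "z",
                   year = c(1990, 2000, 2008, 2014, 2016, 2018, 2020,
                            2022),
                   np = 1:8)
  t2 <- data.frame(source = "b", zone = "z", year = seq(1990, 2022, 2),
                   np = 101:117)
  ps <- pairSeries(t1, t2, "np", "z")
  expect_equal(length(ps$years), 8)
  expect_equal(ps$years, t1$year)
  t3 <- t2; t3$year <- t3$year + 1
  expect_error(pairSeries(t1, t3, "np", "z"), "common years")
  t4 <- t1; t4$np[3] <- NA
  expect_warning(ps2 <- pairSeries(t4, t2, "np", "z"), "dropping 1")
  expect_equal(length(ps2$years), 7)
})

test_that("compareAll sweeps metric x zone and survives degenerate cells", {
  base <- expand.grid(zone = c("n", "c", "s"),
                      year = c(2000, 2010, 2020))
  t1 <- cbind(base, source = "a")
  t2 <- cbind(base, source = "b")
  for (m in c("pa_mn_ha", "np", "pd_per100ha", "lpi_pct", "enn_mn_m",
              "mesh_ha")) {
    t1[[m]] <- seq_len(nrow(t1)) + 10
    t2[[m]] <- seq_len(nrow(t2))
  }
  res <- compareAll(t1, t2)
  expect_equal(nrow(res), 18)
  expect_true(all(res$n_pairs == 3))
  # identical tables: every cell degenerates but the sweep completes
  resId <- compareAll(t1, t1)
  expect_equal(nrow(resId), 18)
  expect_true(all(resId$method == "degenerate"))
  expect_true(all(is.na(resId$p_value)))
})

test_that("all-same-sign cells at n=8 reproduce the p/r report pattern", {
  yrs <- c(1990, 2000, 2008, 2014, 2016, 2018, 2020, 2022)
  off <- c(3, 5, 2, 7, 1, 4, 6, 8)   # distinct magnitudes, one sign
  t1 <- data.frame(zone = "north", year = yrs, np = (1:8) * 10,
                   pa_mn_ha = 100 - (1:8))
  t2 <- data.frame(zone = "north", year = yrs, np = (1:8) * 10 + off,
                   pa_mn_ha = 95 - (1:8) - off / 10)
  res <- compareAll(t1, t2, metrics = c("np", "pa_mn_ha"))
  expect_equal(round(res$p_value, 4), c(0.0078, 0.0078))
  expect_equal(round(res$r_effect, 3), c(0.891, 0.891))
  expect_true(all(res$significant))
})
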