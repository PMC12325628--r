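test_that("normalizeFirmness maps onto [0, 1] and rejects degenerate input", {
  x <- c(3, 1, 7, 5)
  n <- normalizeFirmness(x)
  expect_equal(range(n), c(0, 1))
  expect_equal(n, (x - 1) / 6)
  expect_error(normalizeFirmness(c(2, 2)), "identical")
  expect_error(normalizeFirmness(3), "two samples")
})

test_that("pearsonCorrelation matches the closed-form coefficient", {
  set.seed(3)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, 0, 0.3)
  pc <- pearsonCorrelation(x, y)
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, rManual, tolerance = 1e-12)
  tStat <- rManual * sqrt((20 - 2) / (1 - rManual^2))
  expect_equal(pc$pValue, 2 * pt(-abs(tStat), 18), tolerance = 1e-12)
  expect_equal(pc$n, 20)
})

test_that("welchTTest matches the closed-form statistic and df", {
  a <- c(5.1, 4.8, 6.2, 5.5, 5.0)
  b <- c(3.9, 4.1, 3.5, 4.4)
  w <- welchTTest(a, b)
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tManual <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfManual <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(w$t, tManual, tolerance = 1e-12)
  expect_equal(w$df, dfManual, tolerance = 1e-12)
  expect_equal(w$pValue, 2 * pt(-abs(tManual), dfManual), tolerance = 1e-12)
})

test_that("Welch test keeps its nominal size under the null", {
  # calibration property: ~5% rejections for two same-distribution groups
  set.seed(99)
  p <- replicate(600, welchTTest(rnorm(8), rnorm(8))$pValue)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("simpleLinearRegression matches the normal equations", {
  set.seed(4)
  x <- runif(15); y <- 2 - 3 * x + rnorm(15, 0, 0.1)
  lr <- simpleLinearRegression(x, y)
  slopeManual <- cov(x, y) / var(x)
  expect_equal(lr$slope, slopeManual, tolerance = 1e-12)
  expect_equal(lr$intercept, mean(y) - slopeManual * mean(x), tolerance = 1e-12)
  expect_equal(lr$r2, cor(x, y)^2, tolerance = 1e-12)
})

test_that("the bundled cohort table has the expected shape", {
  ct <- cohortTable()
  expect_equal(nrow(ct), 9)
  expect_true(all(c("age", "mean_fiber_diameter_um", "fiber_count",
                    "volume_fraction_pct", "n_clusters", "max_cluster_size",
                    "vertical_proportion_pct", "firmness") %in% names(ct)))
  expect_equal(range(ct$firmness), c(0, 1))
  expect_true(all(diff(ct$age) > 0))
})

test_that("group split and summaries are consistent", {
  ct <- cohortTable()
  yg <- youngerGroup(ct$age)
  expect_equal(sum(yg), 4)                 # ages 38, 39, 43, 49
  gs <- groupSummary(ct$fiber_count, yg)
  expect_equal(gs$younger$n, 4)
  expect_equal(gs$older$n, 5)
  expect_equal(gs$younger$mean, mean(ct$fiber_count[yg]))
  expect_length(gs$younger$boxStats, 5)
})

test_that("compareAgeGroups reproduces per-metric Welch tests", {
  ct <- cohortTable()
  cmp <- compareAgeGroups(ct)
  expect_true("fiber_count" %in% cmp$metric)
  row <- cmp[cmp$metric == "fiber_count", ]
  yg <- youngerGroup(ct$age)
  w <- welchTTest(ct$fiber_count[yg], ct$fiber_count[!yg])
  expect_equal(row$p_value, w$pValue)
  expect_equal(row$mean_younger, mean(ct$fiber_count[yg]))
})

test_that("correlateWithFirmness reports r, p, slope and r2 per metric", {
  ct <- cohortTable()
  cw <- correlateWithFirmness(ct)
  expect_setequal(cw$metric, setdiff(names(ct)[sapply(ct, is.numeric)], "firmness"))
  row <- cw[cw$metric == "max_cluster_size", ]
  pc <- pearsonCorrelation(ct$max_cluster_size, ct$firmness)
  expect_equal(row$r, pc$r)
  expect_equal(row$p_value, pc$pValue)
  expect_error(correlateWithFirmness(data.frame(a = 1:3)), "firmness")
})
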