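test_that("buildNetwork merges touching endpoints into shared nodes", {
  f1 <- fiberPolyline(rbind(c(0, 0, 0), c(10, 0, 0)), c(1, 1), 1L)
  f2 <- fiberPolyline(rbind(c(10.2, 0, 0), c(20, 0, 0)), c(1, 1), 2L)
  f3 <- fiberPolyline(rbind(c(0, 30, 0), c(10, 30, 0)), c(1, 1), 3L)
  net <- buildNetwork(list(f1, f2, f3), mergeTolerance = 0.5)
  expect_equal(fiberCount(net), 3L)
  expect_equal(nrow(networkNodes(net)), 5L)    # shared node at x = 10
  cl <- countClusters(net)
  expect_equal(cl$nClusters, 2L)
  expect_equal(maxClusterSize(net), 2L)
  # with a tolerance too small to bridge the 0.2 um gap: 3 singletons
  net2 <- buildNetwork(list(f1, f2, f3), mergeTolerance = 0.1)
  expect_equal(countClusters(net2)$nClusters, 3L)
})

test_that("empty networks behave sensibly", {
  net <- buildNetwork(list())
  expect_equal(fiberCount(net), 0L)
  expect_equal(countClusters(net)$nClusters, 0L)
  expect_equal(maxClusterSize(net), 0L)
  expect_equal(volumeFraction(net, domainSpec(10, 10, 10)), 0)
  expect_error(verticalProportion(net), "empty")
})

test_that("vertical proportion folds angles and is threshold-exclusive", {
  mk <- function(p1, p2, id) fiberPolyline(rbind(p1, p2), c(1, 1), id)
  net <- buildNetwork(list(
    mk(c(0, 0, 0), c(0, 10, 0), 1L),        # 0 deg: vertical
    mk(c(5, 10, 5), c(5, 0, 5), 2L),        # pointing down, folds to 0 deg
    mk(c(0, 20, 0), c(10, 20, 0), 3L),      # 90 deg: horizontal
    mk(c(0, 30, 0), c(10, 40, 0), 4L)))     # exactly 45 deg: horizontal
  expect_equal(verticalProportion(net), 50)
  sp <- splitDiametersByOrientation(net)
  expect_length(sp$vertical, 2)
  expect_length(sp$horizontal, 2)
  expect_equal(length(sp$vertical) + length(sp$horizontal), fiberCount(net))
})

test_that("volume fraction matches the closed-form cylinder volume", {
  dom <- domainSpec(20, 20, 20)
  net <- buildNetwork(list(
    fiberPolyline(rbind(c(2, 10, 10), c(18, 10, 10)), c(1.5, 1.5), 1L)))
  want <- 100 * pi * 3^2 / 4 * 16 / (20^3)
  expect_equal(volumeFraction(net, dom), want, tolerance = 1e-12)
})

test_that("diameter statistics average per fiber then across fibers", {
  net <- buildNetwork(list(
    fiberPolyline(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), c(1, 2, 3), 1L),
    fiberPolyline(rbind(c(0, 5, 0), c(10, 5, 0)), c(0.5, 0.5), 2L)))
  ds <- diameterStats(net)
  expect_equal(ds$mean, mean(c(4, 1)))
  expect_equal(ds$min, 1)
  expect_equal(ds$max, 4)
})

test_that("horizontal orientation histogram bins the X-Z angles", {
  mk <- function(p1, p2, id) fiberPolyline(rbind(p1, p2), c(1, 1), id)
  net <- buildNetwork(list(
    mk(c(0, 0, 0), c(10, 0, 0), 1L),       # 0 deg
    mk(c(0, 5, 0), c(0, 5, 10), 2L),       # 90 deg
    mk(c(0, 10, 0), c(0, 20, 0), 3L)))     # purely vertical: excluded
  h <- horizontalOrientationHistogram(net, nBins = 18)
  expect_equal(sum(h$counts), 2)
  expect_equal(h$excluded, 1)
  expect_equal(h$counts[1], 1L)            # [0, 10) bin
  expect_equal(h$counts[10], 1L)           # [90, 100) bin
})

test_that("architectureMetrics reports all six descriptors consistently", {
  dom <- domainSpec(60, 80, 60)
  net <- generateFiberNetwork(dom, networkGenParams(nFibers = 25, seed = 6L))
  m <- architectureMetrics(net, dom)
  expect_named(m, c("mean_fiber_diameter_um", "fiber_count",
                    "volume_fraction_pct", "n_clusters", "max_cluster_size",
                    "vertical_proportion_pct"))
  expect_equal(m$fiber_count, 25L)
  expect_equal(m$mean_fiber_diameter_um, diameterStats(net)$mean)
  expect_equal(m$volume_fraction_pct, volumeFraction(net, dom))
  expect_equal(m$n_clusters, countClusters(net)$nClusters)
  expect_equal(m$max_cluster_size, maxClusterSize(net))
  expect_equal(m$vertical_proportion_pct, verticalProportion(net))
})

test_that("cluster labels agree with the union-find oracle on hand cases", {
  f1 <- fiberPolyline(rbind(c(0, 0, 0), c(10, 0, 0)), c(1, 1), 1L)
  f2 <- fiberPolyline(rbind(c(10, 0, 0), c(10, 10, 0)), c(1, 1), 2L)
  f3 <- fiberPolyline(rbind(c(30, 0, 0), c(40, 0, 0)), c(1, 1), 3L)
  net <- buildNetwork(list(f1, f2, f3))
  got <- countClusters(net)
  want <- unionFindClusters(net)
  expect_equal(got$nClusters, want$nClusters)
  expect_equal(got$labels, want$labels)
})
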