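test_that("generateFiberNetwork is seed-deterministic and respects counts", {
  dom <- domainSpec(60, 80, 60)
  p <- networkGenParams(nFibers = 40, seed = 11L)
  n1 <- generateFiberNetwork(dom, p)
  n2 <- generateFiberNetwork(dom, p)
  expect_equal(fiberCount(n1), 40L)
  expect_identical(networkNodes(n1), networkNodes(n2))
  expect_identical(fiberPaths(n1), fiberPaths(n2))
  n3 <- generateFiberNetwork(dom, networkGenParams(nFibers = 40, seed = 12L))
  expect_false(identical(networkNodes(n1), networkNodes(n3)))
})

test_that("generated fibers stay inside the domain", {
  dom <- domainSpec(50, 70, 50)
  net <- generateFiberNetwork(dom, networkGenParams(nFibers = 60, seed = 3L))
  pts <- networkNodes(net)
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 50))
  expect_true(all(pts[, 2] >= 0 & pts[, 2] <= 70))
  expect_true(all(pts[, 3] >= 0 & pts[, 3] <= 50))
})

test_that("requested cluster structure is realized exactly", {
  dom <- domainSpec(80, 100, 80)
  p <- networkGenParams(nFibers = 30, clusterSizes = c(20L, 6L, 3L, 1L),
                        lengthMean = 25, seed = 5L)
  net <- generateFiberNetwork(dom, p)
  cl <- countClusters(net)
  expect_equal(cl$nClusters, 4L)
  expect_equal(sort(tabulate(cl$labels), decreasing = TRUE), c(20L, 6L, 3L, 1L))
})

test_that("fragmentNetwork adds fibers and clusters without adding material", {
  dom <- domainSpec(80, 100, 80)
  net <- generateFiberNetwork(dom, networkGenParams(
    nFibers = 20, clusterSizes = c(20L), lengthMean = 30, seed = 9L))
  vf0 <- volumeFraction(net, dom)
  frag <- fragmentNetwork(net, nBreaks = 10, seed = 2L)
  expect_gt(fiberCount(frag), fiberCount(net))
  expect_gte(countClusters(frag)$nClusters, countClusters(net)$nClusters)
  expect_lte(volumeFraction(frag, dom), vf0)
})

test_that("cropNetwork clips fibers to the box", {
  dom <- domainSpec(100, 100, 100)
  net <- generateFiberNetwork(dom, networkGenParams(nFibers = 30, seed = 4L))
  sub <- domainSpec(40, 100, 100)
  cnet <- cropNetwork(net, sub)
  if (fiberCount(cnet)) {
    expect_true(all(networkNodes(cnet)[, 1] <= 40 + 1e-9))
  }
  expect_lte(fiberCount(cnet), fiberCount(net))
})

test_that("voxelizeNetwork produces the acquisition geometry and levels", {
  dom <- domainSpec(20, 30, 20)
  f <- fiberPolyline(rbind(c(5, 15, 10), c(15, 15, 10)), c(2, 2), 1L)
  net <- buildNetwork(list(f))
  vp <- voxelizationParams(voxelSpacing = 0.5, backgroundLevel = 100,
                           fiberLevel = 1000, noiseSd = 0, blurSigma = 0)
  vol <- voxelizeNetwork(net, dom, vp)
  expect_s4_class(vol, "VoxelVolume")
  expect_equal(dim(voxelData(vol)), c(40L, 60L, 40L))
  expect_setequal(unique(as.numeric(voxelData(vol))), c(100, 1000))
  # center voxel of the fiber is lit, a far corner is background
  expect_equal(voxelData(vol)[20, 30, 20], 1000)
  expect_equal(voxelData(vol)[1, 1, 1], 100)
  # voxels light up within the radius of the segment, i.e. a capsule
  vFib <- sum(voxelData(vol) == 1000) * 0.5^3
  vCapsule <- pi * 2^2 * 10 + 4 / 3 * pi * 2^3
  expect_lt(abs(vFib - vCapsule) / vCapsule, 0.10)
})

test_that("voxelization noise is seeded and reproducible", {
  dom <- domainSpec(15, 15, 15)
  net <- buildNetwork(list(fiberPolyline(rbind(c(4, 7, 7), c(11, 7, 7)),
                                         c(1.5, 1.5), 1L)))
  vp <- voxelizationParams(noiseSd = 40, blurSigma = 0.8, seed = 7L)
  v1 <- voxelizeNetwork(net, dom, vp)
  v2 <- voxelizeNetwork(net, dom, vp)
  expect_identical(voxelData(v1), voxelData(v2))
})

test_that("age presets load and regenerate their tabulated architecture", {
  ages <- agePresets()
  expect_length(ages, 9)
  ps <- agePreset(ages[1])
  expect_s4_class(ps$domain, "DomainSpec")
  expect_s4_class(ps$params, "NetworkGenParams")
  net <- generatePresetNetwork(ages[1])
  m <- architectureMetrics(net, ps$domain)
  expect_equal(m$fiber_count, ps$targets$fiber_count)
  expect_equal(m$n_clusters, ps$targets$n_clusters)
  expect_equal(m$max_cluster_size, ps$targets$max_cluster_size)
})
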