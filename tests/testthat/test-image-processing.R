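test_that("medianFilter3D removes isolated salt noise and keeps structure", {
  arr <- array(100, c(12, 12, 12))
  arr[4:9, 6, 6] <- 1000           # a bright rod
  arr[2, 2, 2] <- 5000             # salt voxel
  vol <- voxelVolume(arr, spacing = 1)
  flt <- medianFilter3D(vol, kernel = 3L)
  expect_equal(voxelData(flt)[2, 2, 2], 100)        # salt removed
  expect_equal(voxelData(flt)[1, 1, 1], 100)        # border handled
  expect_lt(max(voxelData(flt)), 5000)
})

test_that("otsuThreshold separates a bimodal intensity mixture", {
  set.seed(1)
  arr <- array(rnorm(20^3, 100, 10), c(20, 20, 20))
  arr[8:13, 8:13, 8:13] <- rnorm(6^3, 900, 10)
  vol <- voxelVolume(arr, spacing = 1)
  thr <- otsuThreshold(vol)
  expect_gt(thr, 120)
  expect_lt(thr, 880)
  # the threshold actually separates the two classes
  m <- thresholdSegment(vol, thr)
  expect_true(voxelData(m)[10, 10, 10])
  expect_false(voxelData(m)[1, 1, 1])
})

test_that("thresholdSegment returns a mask on the same grid", {
  arr <- array(0, c(8, 8, 8)); arr[4:5, 4:5, 4:5] <- 10
  vol <- voxelVolume(arr, spacing = 0.5)
  m <- thresholdSegment(vol, threshold = 5)
  expect_s4_class(m, "BinaryMask")
  expect_equal(sum(voxelData(m)), 8L)
  expect_equal(voxelSpacing(m), voxelSpacing(vol))
})

test_that("morphological opening removes specks, closing fills holes", {
  arr <- array(FALSE, c(16, 16, 16))
  arr[4:12, 4:12, 4:12] <- TRUE
  arr[8, 8, 8] <- FALSE           # interior hole
  arr[15, 15, 15] <- TRUE         # isolated speck
  m <- binaryMask(arr, spacing = 1)
  opened <- morphologicalOpen(m, 1)
  expect_false(voxelData(opened)[15, 15, 15])
  closed <- morphologicalClose(m, 1)
  expect_true(voxelData(closed)[8, 8, 8])
})

test_that("surface smoothing is near volume-preserving on a cylinder", {
  m <- cylinderMask(radius = 4, boxUm = 24, spacing = 0.5)
  v0 <- sum(voxelData(m))
  sm <- smoothBinarySurface(m, iterations = 1L)
  expect_lt(abs(sum(voxelData(sm)) - v0) / v0, 0.05)
})

test_that("centerline extraction recovers a single straight fiber", {
  m <- cylinderMask(radius = 2, boxUm = 30, spacing = 0.5)
  fibers <- extractCenterlines(m)
  expect_length(fibers, 1)
  pts <- fibers[[1]]@points
  # runs along x through the box center
  expect_lt(max(abs(pts[, 2] - 15)), 1.5)
  expect_lt(max(abs(pts[, 3] - 15)), 1.5)
  expect_gt(sum(sqrt(rowSums(diff(pts)^2))), 0.8 * 30)
})

test_that("local diameter estimation matches known cylinder radii", {
  for (r in c(1.75, 2.5)) {
    m <- cylinderMask(radius = r, boxUm = 30, spacing = 0.5)
    fibers <- estimateLocalDiameters(m, extractCenterlines(m))
    d <- mean(unlist(lapply(fibers, function(f) 2 * f@radii)))
    expect_lt(abs(d - 2 * r) / (2 * r), 0.15)
  }
})

test_that("segmentFiberStack recovers a clean two-fiber scene", {
  dom <- domainSpec(40, 40, 40)
  f1 <- fiberPolyline(rbind(c(5, 10, 10), c(35, 10, 10)), c(2, 2), 1L)
  f2 <- fiberPolyline(rbind(c(20, 5, 30), c(20, 35, 30)), c(1.8, 1.8), 2L)
  net <- buildNetwork(list(f1, f2))
  vol <- voxelizeNetwork(net, dom, voxelizationParams(noiseSd = 50,
                                                      blurSigma = 0.8, seed = 2L))
  seg <- segmentFiberStack(vol)
  expect_length(seg$fibers, 2)
  expect_s4_class(seg$mask, "BinaryMask")
  d <- sort(vapply(seg$fibers, function(f) mean(2 * f@radii), 1))
  expect_lt(abs(d[1] - 3.6) / 3.6, 0.25)
  expect_lt(abs(d[2] - 4.0) / 4.0, 0.25)
})
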