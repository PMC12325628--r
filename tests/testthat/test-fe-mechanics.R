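mat <- materialParams()

test_that("buildBoxMesh tiles the domain with positive-volume tets", {
  dom <- domainSpec(24, 36, 24)
  mesh <- buildBoxMesh(dom, 12)
  X <- mesh@nodes; T6 <- mesh@tets
  vols <- apply(T6, 1, function(t) {
    a <- X[t[2], ] - X[t[1], ]; b <- X[t[3], ] - X[t[1], ]; c <- X[t[4], ] - X[t[1], ]
    det(cbind(a, b, c)) / 6
  })
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 24 * 36 * 24, tolerance = 1e-9)
})

test_that("tetrahedron forces and tangent match finite differences", {
  set.seed(42)
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE) * 3
  u <- matrix(rnorm(12, 0, 0.1), 4, 3)
  r <- svkInternalForces(X, u, mat)
  fd <- tetForceFD(X, u, mat)
  expect_lt(max(abs(fd - r$f)) / max(abs(r$f)), 1e-6)
  expect_equal(r$K, t(r$K))
  # tangent = force Jacobian
  h <- 1e-6
  fdK <- matrix(0, 12, 12)
  for (k in 1:12) {
    up <- u; um <- u
    i <- (k - 1) %/% 3 + 1; j <- (k - 1) %% 3 + 1
    up[i, j] <- up[i, j] + h; um[i, j] <- um[i, j] - h
    fdK[, k] <- (svkInternalForces(X, up, mat)$f -
                 svkInternalForces(X, um, mat)$f) / (2 * h)
  }
  expect_lt(max(abs(fdK - r$K)) / max(abs(r$K)), 1e-4)
})

test_that("tetrahedron is invariant to rigid translation", {
  X <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2), 4, 3, byrow = TRUE)
  r <- svkInternalForces(X, matrix(1.7, 4, 3), mat)
  expect_lt(max(abs(r$f)), 1e-10)
  expect_lt(abs(r$energy), 1e-12)
})

test_that("beam forces match finite differences and stay symmetric", {
  set.seed(7)
  X1 <- c(0, 0, 0); X2 <- c(10, 3, -2)
  u <- matrix(rnorm(6, 0, 0.05), 2, 3)
  rot <- matrix(rnorm(6, 0, 0.02), 2, 3)
  b <- beamInternalForces(X1, X2, 3.5, mat, u, rot)
  fd <- beamForceFD(X1, X2, 3.5, mat, u, rot)
  expect_lt(max(abs(fd - b$f)) / max(abs(b$f)), 1e-6)
  expect_equal(b$K, t(b$K))
  # rigid translation: no force, no energy
  bt <- beamInternalForces(X1, X2, 3.5, mat, matrix(1.3, 2, 3), matrix(0, 2, 3))
  expect_lt(max(abs(bt$f)), 1e-10)
})

test_that("beam axial response reduces to the elastic bar", {
  d <- 3.5; L0 <- 10; eps <- 0.01
  b <- beamInternalForces(c(0, 0, 0), c(L0, 0, 0), d, mat,
                          rbind(c(0, 0, 0), c(L0 * eps, 0, 0)))
  A <- pi * d^2 / 4
  expect_equal(b$axialForce, mat@EFiber * A * eps, tolerance = 0.01)
  expect_gt(b$axialForce, 0)   # tension positive
})

test_that("cantilever tip deflection matches PL^3 / 3EI", {
  L <- 20; d <- 3.5; P <- 1e-4
  I <- pi * d^4 / 64
  tip <- cantileverTipDeflection(L = L, d = d, nel = 8, P = P, materials = mat)
  expect_equal(tip, P * L^3 / (3 * mat@EFiber * I), tolerance = 0.01)
})

test_that("fiber-free compression matches the homogeneous closed form", {
  dom <- domainSpec(24, 36, 24)
  mesh <- buildBoxMesh(dom, 12)
  sim <- solveCompression(mesh, mat, compressionSetup(nIncrements = 4))
  oracle <- homogeneousCompressionOracle(mat)
  expect_true(sim@converged)
  traction <- sim@reactionForceTop / (24 * 24)
  expect_lt(abs(-traction - oracle$tractionMPa) / abs(oracle$tractionMPa), 1e-3)
  # every element sees the homogeneous strain state
  expect_lt(max(abs(sim@elementEquivalentStrain - oracle$eqStrain)),
            1e-3 * oracle$eqStrain)
  # lateral faces move by the oracle's lateral stretch
  ux <- sim@displacements[, 1]
  right <- mesh@nodes[, 1] > 24 - 1e-6
  expect_lt(max(abs((24 + ux[right]) / 24 - oracle$lateralStretch)), 1e-4)
})

test_that("solveCompression is deterministic and reports axial forces", {
  dom <- domainSpec(30, 40, 30)
  net <- generateFiberNetwork(dom, networkGenParams(nFibers = 15, lengthMean = 15,
                                                    seed = 2L))
  mesh <- embedBeams(buildBoxMesh(dom, 10), net)
  expect_gt(nrow(mesh@beams), 0)
  s1 <- solveCompression(mesh, mat, compressionSetup(nIncrements = 3))
  s2 <- solveCompression(mesh, mat, compressionSetup(nIncrements = 3))
  expect_identical(s1@displacements, s2@displacements)
  expect_equal(length(s1@fiberAxialForces), nrow(mesh@beams))
  ax <- extractFiberAxialForces(s1)
  expect_equal(sum(ax$histogram$counts), length(ax$forces))
  expect_equal(length(ax$perFiber), length(unique(mesh@beams$fiber)))
})

test_that("embedBeams snaps fibers onto mesh nodes with bookkeeping", {
  dom <- domainSpec(30, 40, 30)
  net <- generateFiberNetwork(dom, networkGenParams(nFibers = 10, lengthMean = 15,
                                                    seed = 5L))
  mesh <- embedBeams(buildBoxMesh(dom, 10), net)
  expect_true(all(mesh@beams$node1 != mesh@beams$node2))
  expect_lte(mesh@metadata$maxSnapDisplacement, sqrt(3) * 10 / 2 + 1e-9)
  expect_true(is.numeric(mesh@metadata$snappedLengthError))
})

test_that("equivalent strain accessors agree with the stored field", {
  dom <- domainSpec(24, 36, 24)
  sim <- solveCompression(buildBoxMesh(dom, 12), mat,
                          compressionSetup(nIncrements = 4))
  expect_identical(equivalentStrainField(sim), sim@elementEquivalentStrain)
  expect_identical(lowStrainMask(sim), sim@elementEquivalentStrain < 0.1)
})
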