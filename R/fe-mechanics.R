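#' Lame parameters from Young's modulus and Poisson's ratio
#'
#' @param materials a \linkS4class{MaterialParams}.
#' @return list with \code{lambda} and \code{mu} (MPa) of the matrix material.
#' @export
lameParameters <- function(materials) {
  E <- materials@EMatrix; nu <- materials@nu
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Build a structured tetrahedral box mesh
#'
#' A structured hexahedral grid, each cell split into six tetrahedra (Kuhn
#' subdivision with a consistent main diagonal, conforming across cells). The
#' summed tetrahedron volume equals the box volume to round-off.
#'
#' @param domain a \linkS4class{DomainSpec}.
#' @param targetEdge requested cell edge (um); the actual edge per axis is the
#'   box size divided by the rounded cell count.
#' @return a \linkS4class{TetMeshModel} without beams.
#' @export
buildBoxMesh <- function(domain, targetEdge) {
  size <- c(domain@sizeX, domain@sizeY, domain@sizeZ)
  if (targetEdge >= min(size) * (1 + 1e-12) && targetEdge > min(size))
    stop("targetEdge must not exceed the smallest box dimension")
  nc <- pmax(1L, as.integer(round(size / targetEdge)))
  h <- size / nc
  nx <- nc[1] + 1L; ny <- nc[2] + 1L; nz <- nc[3] + 1L
  gx <- seq(0, size[1], length.out = nx)
  gy <- seq(0, size[2], length.out = ny)
  gz <- seq(0, size[3], length.out = nz)
  nodes <- cbind(rep(gx, times = ny * nz),
                 rep(rep(gy, each = nx), times = nz),
                 rep(gz, each = nx * ny))
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L) # 1-based
  # Kuhn subdivision: six tets per cell via permutations of the unit steps
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ii <- rep(seq_len(nc[1]), times = nc[2] * nc[3])
  jj <- rep(rep(seq_len(nc[2]), each = nc[1]), times = nc[3])
  kk <- rep(seq_len(nc[3]), each = nc[1] * nc[2])
  ncell <- length(ii)
  tets <- matrix(0L, 6L * ncell, 4L)
  for (p in 1:6) {
    e <- diag(3)[perms[p, ], , drop = FALSE]
    c1 <- rbind(0, e[1, ], e[1, ] + e[2, ], e[1, ] + e[2, ] + e[3, ])
    block <- matrix(0L, ncell, 4L)
    for (v in 1:4) {
      block[, v] <- nid(ii + c1[v, 1], jj + c1[v, 2], kk + c1[v, 3])
    }
    tets[seq.int(p, by = 6L, length.out = ncell), ] <- block
  }
  # enforce positive orientation
  v1 <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  v2 <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  v3 <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  det <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
         v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
         v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  flip <- det < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  new("TetMeshModel", nodes = nodes, tets = tets,
      beams = data.frame(node1 = integer(0), node2 = integer(0),
                         diameter = numeric(0), fiber = integer(0)),
      gridDims = nc, gridSpacing = h, domain = domain, metadata = list())
}

#' Embed beam fibers into a tetrahedral mesh
#'
#' Every fiber node is snapped to the nearest matrix mesh node; beams whose
#' two endpoints snap to the same node are dropped as zero length. Snapped
#' translations are shared with the matrix; rotational degrees of freedom
#' remain beam-only.
#'
#' @param mesh a structured \linkS4class{TetMeshModel} from
#'   \code{\link{buildBoxMesh}}.
#' @param net a \linkS4class{FiberNetwork} inside the mesh domain.
#' @return the mesh with beams attached; \code{metadata} gains
#'   \code{maxSnapDisplacement}, \code{meanSnapDisplacement},
#'   \code{droppedBeams} and \code{snappedLengthError}.
#' @export
embedBeams <- function(mesh, net) {
  size <- c(mesh@domain@sizeX, mesh@domain@sizeY, mesh@domain@sizeZ)
  if (nrow(net@nodes)) {
    lo <- apply(net@nodes, 2, min); hi <- apply(net@nodes, 2, max)
    if (any(lo < -1e-6) || any(hi > size + 1e-6))
      stop("fiber network extends outside the mesh box")
  }
  h <- mesh@gridSpacing
  nc <- mesh@gridDims
  gidx <- function(x, ax) pmin(nc[ax], pmax(0L, as.integer(round(x / h[ax]))))
  gi <- gidx(net@nodes[, 1], 1); gj <- gidx(net@nodes[, 2], 2); gk <- gidx(net@nodes[, 3], 3)
  nx <- nc[1] + 1L; ny <- nc[2] + 1L
  meshNode <- 1L + gi + nx * gj + nx * ny * gk
  snapped <- mesh@nodes[meshNode, , drop = FALSE]
  snapDisp <- sqrt(rowSums((snapped - net@nodes)^2))
  seg <- networkSegments(net)
  b1 <- meshNode[seg$node1]; b2 <- meshNode[seg$node2]
  keep <- b1 != b2
  beams <- data.frame(node1 = b1[keep], node2 = b2[keep],
                      diameter = seg$diameter[keep], fiber = seg$fiber[keep])
  lenOrig <- sum(sqrt(rowSums((net@nodes[seg$node2, , drop = FALSE] -
                               net@nodes[seg$node1, , drop = FALSE])^2)))
  lenSnap <- sum(sqrt(rowSums((mesh@nodes[beams$node2, , drop = FALSE] -
                               mesh@nodes[beams$node1, , drop = FALSE])^2)))
  md <- mesh@metadata
  md$maxSnapDisplacement <- if (length(snapDisp)) max(snapDisp) else 0
  md$meanSnapDisplacement <- if (length(snapDisp)) mean(snapDisp) else 0
  md$droppedBeams <- sum(!keep)
  md$snappedLengthError <- if (lenOrig > 0) abs(lenSnap - lenOrig) / lenOrig else 0
  initialize(mesh, beams = beams, metadata = md)
}

#' Saint Venant-Kirchhoff internal forces of one tetrahedron
#'
#' Exposes the element kernel: internal force vector, consistent tangent and
#' strain energy for a single 4-node tetrahedron under the total-Lagrangian
#' SVK law.
#'
#' @param nodesRef 4 x 3 reference coordinates (um).
#' @param disp 4 x 3 nodal displacements (um).
#' @param materials a \linkS4class{MaterialParams} (matrix constants used).
#' @return list with \code{f} (12-vector, node-major x,y,z), \code{K} (12 x
#'   12), \code{energy} (uN um) and \code{eqStrain}.
#' @export
svkInternalForces <- function(nodesRef, disp, materials) {
  lp <- lameParameters(materials)
  res <- cpp_tet_assemble(nodesRef, matrix(0:3, 1, 4), lp$lambda, lp$mu,
                          as.numeric(t(disp)), TRUE)
  K <- matrix(0, 12, 12)
  K[cbind(res$ki + 1L, res$kj + 1L)] <- 0 # initialize pattern
  for (t in seq_along(res$kx))
    K[res$ki[t] + 1L, res$kj[t] + 1L] <- K[res$ki[t] + 1L, res$kj[t] + 1L] + res$kx[t]
  list(f = res$f, K = K, energy = res$energy, eqStrain = res$eqstrain[1])
}

#' Internal forces of one embedded beam element
#'
#' Circular-section fiber beam: geometrically exact axial response on the
#' current chord plus linearized Euler-Bernoulli bending and torsion in the
#' initial local frame. Axial force is signed, tension positive.
#'
#' @param X1,X2 reference endpoint coordinates (um).
#' @param diameter section diameter (um).
#' @param materials a \linkS4class{MaterialParams} (fiber modulus used).
#' @param disp 2 x 3 endpoint displacements.
#' @param rot 2 x 3 endpoint rotations (rad).
#' @return list with \code{f} (12-vector ordered u1, theta1, u2, theta2),
#'   \code{K} (12 x 12), \code{energy} and \code{axialForce} (uN).
#' @export
beamInternalForces <- function(X1, X2, diameter, materials,
                               disp = matrix(0, 2, 3), rot = matrix(0, 2, 3)) {
  nodes <- rbind(X1, X2)
  res <- cpp_beam_assemble(nodes, 0L, 1L, 0L, 1L, diameter,
                           materials@EFiber, materials@nu,
                           as.numeric(t(disp)), as.numeric(t(rot)), TRUE)
  K <- matrix(0, 12, 12)
  for (t in seq_along(res$kx))
    K[res$ki[t] + 1L, res$kj[t] + 1L] <- K[res$ki[t] + 1L, res$kj[t] + 1L] + res$kx[t]
  # internal layout is (u1, u2, theta1, theta2); reorder to (u1, th1, u2, th2)
  perm <- c(1:3, 7:9, 4:6, 10:12)
  list(f = res$f[perm], K = K[perm, perm], energy = res$energy,
       axialForce = res$axial[1])
}

#' Boundary conditions of the unconfined compression test
#'
#' Dirichlet faces: left (x = 0) fixed in x, bottom (y = 0) fixed in y, back
#' (z = 0) fixed in z, top (y = H) driven down by the compression ratio.
#' Multi-point constraints keep the right (x = Lx) and front (z = Lz) faces
#' planar: all their normal displacements are tied to a single free master
#' degree of freedom each. Corner nodes on intersecting faces receive the
#' union of constraints.
#'
#' @param mesh a \linkS4class{TetMeshModel}.
#' @param setup a \linkS4class{CompressionSetup}.
#' @return constraint system: \code{rmap} (full dof to reduced column, 0 =
#'   eliminated), \code{nReduced}, \code{prescribedDofs} (full dof indices of
#'   the driven top-face y dofs), \code{prescribedValue(t)} giving the top
#'   displacement at load factor t, \code{topNodes}, \code{nConstrained}, and
#'   the master column ids \code{masterX}, \code{masterZ}.
#' @export
applyBoundaryConditions <- function(mesh, setup) {
  size <- c(mesh@domain@sizeX, mesh@domain@sizeY, mesh@domain@sizeZ)
  tol <- 1e-6 * max(size)
  nn <- nrow(mesh@nodes)
  x <- mesh@nodes[, 1]; y <- mesh@nodes[, 2]; z <- mesh@nodes[, 3]
  left <- x < tol;          right <- x > size[1] - tol
  bottom <- y < tol;        top <- y > size[2] - tol
  back <- z < tol;          front <- z > size[3] - tol
  nrot <- length(unique(c(mesh@beams$node1, mesh@beams$node2))) * 3L
  ndof <- 3L * nn + nrot
  # classification per translational dof: 0 free, 1 fixed, 2 prescribed,
  # 3 tied to masterX, 4 tied to masterZ
  cls <- integer(ndof)
  dofx <- 3L * (seq_len(nn) - 1L) + 1L
  cls[dofx[left]] <- 1L
  cls[dofx[right]] <- 3L
  cls[dofx + 1L][bottom] <- 1L
  cls[dofx + 1L][top] <- 2L
  cls[dofx + 2L][back] <- 1L
  cls[dofx + 2L][front] <- 4L
  free <- which(cls == 0L)
  rmap <- integer(ndof)
  rmap[free] <- seq_along(free)
  nRed <- length(free)
  masterX <- masterZ <- 0L
  if (any(cls == 3L)) { masterX <- nRed + 1L; nRed <- masterX; rmap[cls == 3L] <- masterX }
  if (any(cls == 4L)) { masterZ <- nRed + 1L; nRed <- masterZ; rmap[cls == 4L] <- masterZ }
  H <- size[2]
  list(rmap = rmap, nReduced = nRed,
       prescribedDofs = which(cls == 2L),
       prescribedValue = function(t) -setup@compressionRatio * H * t,
       topNodes = which(top), nConstrained = sum(cls %in% c(1L, 2L)),
       masterX = masterX, masterZ = masterZ)
}

#' Solve the quasi-static unconfined compression
#'
#' Incremental loading with a full Newton iteration per increment, assembling
#' the SVK tetrahedra and embedded beams into a sparse symmetric tangent.
#' Convergence requires the reduced residual norm to fall below
#' \code{newtonTol} relative to the increment's initial residual (with a small
#' absolute floor).
#'
#' @param mesh a \linkS4class{TetMeshModel} (beams optional).
#' @param materials a \linkS4class{MaterialParams}.
#' @param setup a \linkS4class{CompressionSetup}.
#' @param verbose print per-increment convergence summaries.
#' @return a \linkS4class{SimulationResult}; the top-surface reaction (the
#'   elastic recovery force) is reported positive under compression.
#' @export
solveCompression <- function(mesh, materials, setup = compressionSetup(),
                             verbose = FALSE) {
  lp <- lameParameters(materials)
  nn <- nrow(mesh@nodes)
  rotNodes <- sort(unique(c(mesh@beams$node1, mesh@beams$node2)))
  nrot <- length(rotNodes)
  hasBeams <- nrow(mesh@beams) > 0
  rotSlot <- integer(nn)
  rotSlot[rotNodes] <- seq_len(nrot)
  ndof <- 3L * nn + 3L * nrot
  bc <- applyBoundaryConditions(mesh, setup)
  stopifnot(length(bc$rmap) == ndof)

  bn1 <- mesh@beams$node1 - 1L; bn2 <- mesh@beams$node2 - 1L
  br1 <- rotSlot[mesh@beams$node1] - 1L; br2 <- rotSlot[mesh@beams$node2] - 1L

  assemble <- function(u, wantK) {
    ut <- u[seq_len(3L * nn)]
    ur <- if (nrot) u[(3L * nn + 1L):ndof] else numeric(0)
    tet <- cpp_tet_assemble(mesh@nodes, mesh@tets - 1L, lp$lambda, lp$mu, ut, wantK)
    f <- tet$f
    ki <- tet$ki; kj <- tet$kj; kx <- tet$kx
    axial <- numeric(0)
    energy <- tet$energy
    if (hasBeams) {
      bm <- cpp_beam_assemble(mesh@nodes, bn1, bn2, br1, br2,
                              mesh@beams$diameter, materials@EFiber,
                              materials@nu, ut, ur, wantK)
      f <- c(f, numeric(3L * nrot))
      f <- f + bm$f
      axial <- bm$axial
      energy <- energy + bm$energy
      if (wantK) { ki <- c(ki, bm$ki); kj <- c(kj, bm$kj); kx <- c(kx, bm$kx) }
    } else if (length(f) < ndof) {
      f <- c(f, numeric(ndof - length(f)))
    }
    list(f = f, ki = ki, kj = kj, kx = kx, eqstrain = tet$eqstrain,
         axial = axial, energy = energy)
  }

  # sparse pattern bookkeeping (reduced system), built on first use
  patt <- NULL
  reducedK <- function(asm) {
    ri <- bc$rmap[asm$ki + 1L]; rj <- bc$rmap[asm$kj + 1L]
    if (is.null(patt)) {
      keep <- ri > 0L & rj > 0L
      K <- Matrix::sparseMatrix(i = ri[keep], j = rj[keep], x = asm$kx[keep],
                                dims = c(bc$nReduced, bc$nReduced))
      # map each kept triplet (in original order) to its slot in K@x
      key <- (as.numeric(rj[keep]) - 1) * bc$nReduced + as.numeric(ri[keep])
      ord <- order(key)
      slotOfSorted <- cumsum(!duplicated(key[ord]))
      slot <- integer(length(key))
      slot[ord] <- slotOfSorted
      map <- integer(length(ri))
      map[keep] <- slot
      patt <<- list(K = K, map = map, nslots = max(slotOfSorted))
      K
    } else {
      xs <- cpp_accumulate(asm$kx, patt$map, patt$nslots)
      K <- patt$K
      K@x <- xs
      K
    }
  }

  u <- numeric(ndof)
  converged <- TRUE
  chol <- NULL
  lastAsm <- NULL
  lastKs <- NULL
  # Rotational grounding: torsion only penalizes the rotation *difference*
  # between beam ends, so an isolated or perfectly collinear beam chain can
  # spin freely about its own axis -- an exact null mode of the tangent. A
  # tiny diagonal spring on the reduced rotation dofs removes it. It is added
  # to the tangent only (never to the forces), so the converged solution is
  # untouched; the spin component simply stays put.
  rotReg <- NULL
  if (nrot) {
    rotDofs <- bc$rmap[(3L * nn + 1L):ndof]
    rotDofs <- rotDofs[rotDofs > 0L]
    regX <- numeric(bc$nReduced)
    regX[rotDofs] <- 1
    rotReg <- Matrix::Diagonal(bc$nReduced, regX)
  }
  prevT <- 0
  H <- mesh@domain@sizeY
  dofY <- 3L * (seq_len(nn) - 1L) + 2L
  for (inc in seq_len(setup@nIncrements)) {
    tfac <- inc / setup@nIncrements
    # predictor: scale the previous converged field (affine compression
    # profile on the first increment) so the prescribed top displacement does
    # not squash the top element row before Newton redistributes it
    if (prevT == 0) {
      u[dofY] <- bc$prescribedValue(tfac) * mesh@nodes[, 2] / H
    } else {
      u <- u * (tfac / prevT)
    }
    u[bc$prescribedDofs] <- bc$prescribedValue(tfac)
    prevT <- tfac
    r0 <- NA_real_
    ok <- FALSE
    rnPrev <- Inf
    for (it in seq_len(setup@maxIterations)) {
      asm <- assemble(u, FALSE)
      lastAsm <- asm
      rred <- -cpp_accumulate(asm$f, bc$rmap, bc$nReduced)
      rn <- sqrt(sum(rred^2))
      if (it == 1) r0 <- max(rn, 1e-10)
      if (verbose) message(sprintf("inc %d it %d |r| = %.3e", inc, it, rn))
      if (rn <= setup@newtonTol * r0 || rn < 1e-12) { ok <- TRUE; break }
      # modified Newton: the factored tangent is reused while the residual
      # keeps contracting fast; refactor at each increment start and whenever
      # the contraction rate degrades (factorization dominates the runtime
      # because the planarity constraints couple whole faces)
      if (is.null(chol) || it == 1L || rn > 0.25 * rnPrev) {
        asmK <- assemble(u, TRUE)
        K <- reducedK(asmK)
        Ks <- Matrix::forceSymmetric(K)
        if (!is.null(rotReg)) {
          Ks <- Ks + (1e-6 * max(abs(K@x))) * rotReg
        }
        chol <- tryCatch({
          if (is.null(chol)) Matrix::Cholesky(Ks, LDL = TRUE)
          else Matrix::update(chol, Ks)
        }, error = function(e) NULL)
        if (is.null(chol)) {
          # factorization failed outright: climb a diagonal-shift ladder
          # (again tangent-only, so only the step direction is perturbed)
          scale <- max(abs(K@x))
          for (shift in 10^seq(-8, -2)) {
            Kshift <- Ks + (shift * scale) * Matrix::Diagonal(bc$nReduced)
            chol <- tryCatch(Matrix::Cholesky(Kshift, LDL = TRUE),
                             error = function(e) NULL)
            if (!is.null(chol)) { Ks <- Kshift; break }
          }
        }
        lastKs <- Ks
      }
      du <- if (!is.null(chol)) as.numeric(Matrix::solve(chol, rred))
            else as.numeric(Matrix::solve(lastKs, rred))
      rnPrev <- rn
      full <- numeric(ndof)
      sel <- bc$rmap > 0L
      full[sel] <- du[bc$rmap[sel]]
      # backtracking: halve the step while it would invert an element
      alpha <- 1
      for (bt in 1:8) {
        ok2 <- tryCatch({ assemble(u + alpha * full, FALSE); TRUE },
                        error = function(e) FALSE)
        if (ok2) break
        alpha <- alpha / 2
      }
      if (!ok2) stop("Newton step inverts elements even after backtracking; ",
                     "increase nIncrements")
      u <- u + alpha * full
    }
    if (!ok) {
      converged <- FALSE
      warning(sprintf("Newton did not converge in increment %d (%d iterations)",
                      inc, setup@maxIterations))
      break
    }
  }
  asm <- lastAsm
  topY <- 3L * (bc$topNodes - 1L) + 2L
  reaction <- -sum(asm$f[topY])
  disp <- matrix(u[seq_len(3L * nn)], nn, 3, byrow = TRUE)
  rotm <- if (nrot) matrix(u[(3L * nn + 1L):ndof], nrot, 3, byrow = TRUE) else matrix(0, 0, 3)
  new("SimulationResult", displacements = disp, rotations = rotm,
      rotNodes = as.integer(rotNodes), reactionForceTop = reaction,
      fiberAxialForces = as.numeric(asm$axial),
      elementEquivalentStrain = as.numeric(asm$eqstrain),
      converged = converged, mesh = mesh, materials = materials, setup = setup)
}

#' Per-fiber axial forces and their histogram
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param breaks histogram breaks (passed to \code{hist}).
#' @return list with \code{forces} (signed uN per beam, tension positive),
#'   \code{perFiber} (mean per source fiber id) and \code{histogram}.
#' @export
extractFiberAxialForces <- function(result, breaks = 30) {
  f <- result@fiberAxialForces
  fib <- result@mesh@beams$fiber
  perFiber <- if (length(f)) tapply(f, fib, mean) else numeric(0)
  h <- if (length(f)) graphics::hist(f, breaks = breaks, plot = FALSE) else NULL
  list(forces = f, perFiber = perFiber, histogram = h)
}

#' Equivalent strain field and low-strain mask
#'
#' Equivalent strain is sqrt(2/3 dev(E):dev(E)) of the Green-Lagrange strain
#' per tetrahedron; elements below the threshold form the low-strain region
#' that maps mechanical shielding by the fiber network.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param threshold low-strain cutoff (default 0.1).
#' @return \code{equivalentStrainField}: numeric per tetrahedron;
#'   \code{lowStrainMask}: logical per tetrahedron.
#' @export
equivalentStrainField <- function(result) result@elementEquivalentStrain

#' @rdname equivalentStrainField
#' @export
lowStrainMask <- function(result, threshold = 0.1) {
  result@elementEquivalentStrain < threshold
}

#' Closed-form homogeneous solution of fiber-free compression
#'
#' For a fiber-free SVK box under uniaxial nominal compression with free
#' planar lateral faces the deformation is homogeneous, F = diag(lt, ly, lt):
#' the lateral stretch solves lambda (2 Et + Ey) + 2 mu Et = 0 and the nominal
#' top traction is ly [lambda (2 Et + Ey) + 2 mu Ey].
#'
#' @param materials a \linkS4class{MaterialParams}.
#' @param compressionRatio height reduction fraction.
#' @return list with \code{lateralStretch}, \code{tractionMPa} (nominal, signed:
#'   negative = compression) and \code{eqStrain} of the homogeneous state.
#' @export
homogeneousCompressionOracle <- function(materials, compressionRatio = 0.20) {
  lp <- lameParameters(materials)
  ly <- 1 - compressionRatio
  Ey <- 0.5 * (ly^2 - 1)
  Et <- -lp$lambda * Ey / (2 * (lp$lambda + lp$mu))
  lt <- sqrt(1 + 2 * Et)
  Syy <- lp$lambda * (2 * Et + Ey) + 2 * lp$mu * Ey
  Em <- diag(c(Et, Ey, Et))
  dev <- Em - diag(rep(sum(diag(Em)) / 3, 3))
  list(lateralStretch = lt, tractionMPa = ly * Syy,
       eqStrain = sqrt(2 / 3 * sum(dev^2)))
}
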