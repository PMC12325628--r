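# Independent oracles and small generators shared across the tests.

# ---- union-find fiber clustering (oracle for countClusters) ----------------

# Clusters fibers through shared nodes with a hand-written union-find
# (path halving + union by size), fully independent of the graph library
# used by the package.
unionFindClusters <- function(net) {
  nNodes <- nrow(net@nodes)
  if (!length(net@paths)) return(list(nClusters = 0L, labels = integer(0)))
  parent <- seq_len(nNodes)
  size <- rep(1L, nNodes)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra == rb) return(invisible())
    if (size[ra] < size[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
    parent[rb] <<- ra
    size[ra] <<- size[ra] + size[rb]
    invisible()
  }
  for (p in net@paths) {
    if (length(p) > 1) for (k in seq_len(length(p) - 1L)) unite(p[k], p[k + 1L])
  }
  roots <- vapply(net@paths, function(p) findRoot(p[1]), 1L)
  labels <- match(roots, unique(roots))
  list(nClusters = length(unique(labels)), labels = labels)
}

# Random polyline networks on an integer grid: grid spacing (2 um) exceeds the
# merge tolerance, so node sharing means exact coordinate coincidence and the
# cluster structure is rich and random.
randomGridNetwork <- function(seed, nFibers = 200, gridMax = 12L) {
  set.seed(seed)
  fibers <- lapply(seq_len(nFibers), function(i) {
    npts <- sample(2:5, 1)
    pts <- matrix(2 * sample(0:gridMax, 3L * npts, replace = TRUE), npts, 3)
    repeat {
      n <- nrow(pts)
      keep <- c(TRUE, rowSums(abs(pts[-1, , drop = FALSE] -
                                  pts[-n, , drop = FALSE])) > 0)
      if (all(keep)) break
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) < 2) pts <- rbind(pts, pts[1, ] + c(2, 0, 0))
    fiberPolyline(pts, rep(1.5, nrow(pts)), as.integer(i))
  })
  buildNetwork(fibers, mergeTolerance = 0.5)
}

# ---- well-separated straight-fiber family (round-trip ground truth) --------

# Closest distance between two 3D segments.
segDist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  cc <- sum(d1 * r); b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > 1e-12) max(0, min(1, (b * f - cc * e) / den)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- max(0, min(1, -cc / a)) }
  else if (t > 1) { t <- 1; s <- max(0, min(1, (b - cc) / a)) }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

# Straight fibers in a 60 um box with a guaranteed surface-to-surface gap, so
# the imaging ground truth is unambiguous (no merging/occlusion effects).
makeSparseNet <- function(seed, n = 15, minGap = 3) {
  set.seed(seed)
  segs <- list(); fibers <- list()
  tries <- 0
  while (length(fibers) < n && tries < 5000) {
    tries <- tries + 1
    vertical <- runif(1) < 0.3
    cosT <- if (vertical) runif(1, cos(pi / 4), 1) else runif(1, 0, cos(pi / 4))
    phi <- runif(1, 0, 2 * pi); sinT <- sqrt(1 - cosT^2)
    dir <- c(sinT * cos(phi), cosT, sinT * sin(phi))
    L <- runif(1, 18, 28)
    c0 <- runif(3, 4, 56)
    p1 <- c0 - dir * L / 2; p2 <- c0 + dir * L / 2
    if (any(c(p1, p2) < 3) || any(c(p1, p2) > 57)) next
    r <- runif(1, 1.6, 2.1)
    ok <- TRUE
    for (s in segs) {
      if (segDist(p1, p2, s$p1, s$p2) < r + s$r + minGap) { ok <- FALSE; break }
    }
    if (!ok) next
    pts <- t(sapply(seq(0, 1, length.out = 6), function(t) p1 + t * (p2 - p1)))
    fibers[[length(fibers) + 1]] <- fiberPolyline(pts, rep(r, 6),
                                                  length(fibers) + 1L)
    segs[[length(segs) + 1]] <- list(p1 = p1, p2 = p2, r = r)
  }
  buildNetwork(fibers)
}

# ---- finite-difference energy gradients (oracle for element forces) --------

# Central-difference gradient of the tetrahedron strain energy.
tetForceFD <- function(X, u, materials, h = 1e-6) {
  fd <- numeric(12)
  for (k in 1:12) {
    up <- u; um <- u
    i <- (k - 1) %/% 3 + 1; j <- (k - 1) %% 3 + 1
    up[i, j] <- up[i, j] + h
    um[i, j] <- um[i, j] - h
    fd[k] <- (svkInternalForces(X, up, materials)$energy -
              svkInternalForces(X, um, materials)$energy) / (2 * h)
  }
  fd
}

# Central-difference gradient of the beam strain energy (dof order u1, theta1,
# u2, theta2 to match beamInternalForces).
beamForceFD <- function(X1, X2, d, materials, u, rot, h = 1e-6) {
  enAt <- function(du, dr) beamInternalForces(X1, X2, d, materials, du, dr)$energy
  fd <- numeric(12)
  for (k in 1:12) {
    node <- if (k <= 6) 1 else 2
    loc <- (k - 1) %% 6
    up <- u; um <- u; rp <- rot; rm <- rot
    if (loc < 3) {
      up[node, loc + 1] <- up[node, loc + 1] + h
      um[node, loc + 1] <- um[node, loc + 1] - h
    } else {
      rp[node, loc - 2] <- rp[node, loc - 2] + h
      rm[node, loc - 2] <- rm[node, loc - 2] - h
    }
    fd[k] <- (enAt(up, rp) - enAt(um, rm)) / (2 * h)
  }
  fd
}

# Clamped cantilever tip deflection assembled from the exported element kernel.
cantileverTipDeflection <- function(L = 20, d = 3.5, nel = 8, P = 1e-4,
                                    materials = materialParams()) {
  n <- nel + 1
  K <- matrix(0, 6 * n, 6 * n)
  for (e in seq_len(nel)) {
    X1e <- c((e - 1) * L / nel, 0, 0); X2e <- c(e * L / nel, 0, 0)
    ke <- beamInternalForces(X1e, X2e, d, materials)$K
    idx <- c((6 * (e - 1) + 1):(6 * (e - 1) + 6), (6 * e + 1):(6 * e + 6))
    K[idx, idx] <- K[idx, idx] + ke
  }
  f <- numeric(6 * n)
  f[6 * nel + 2] <- P
  free <- 7:(6 * n)
  uu <- solve(K[free, free], f[free])
  uu[length(uu) - 4]
}

# ---- misc -------------------------------------------------------------------

# Synthetic solid cylinder mask along the x axis, centered in the box.
cylinderMask <- function(radius, boxUm = 40, spacing = 0.5) {
  nv <- round(boxUm / spacing)
  cy <- cz <- boxUm / 2
  coords <- (seq_len(nv) - 0.5) * spacing
  yz <- outer((coords - cy)^2, (coords - cz)^2, "+")
  inside <- yz <= radius^2
  arr <- array(FALSE, c(nv, nv, nv))
  for (i in seq_len(nv)) arr[i, , ] <- inside
  binaryMask(arr, spacing = rep(spacing, 3))
}
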