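#' Generate a synthetic dermal elastin fiber network
#'
#' Fibers are polylines built from a straight axis plus a smooth transverse
#' waviness perturbation, clipped at the domain faces. The polar angle of each
#' axis relative to the Y (surface-normal) axis is drawn from a two-component
#' mixture -- uniform on the spherical cap below 45 degrees with probability
#' \code{verticalFraction}, uniform on the complementary band otherwise -- so
#' the expected vertical proportion equals the target exactly; the azimuth is
#' uniform. Diameters and lengths are truncated normal draws.
#'
#' When \code{clusterSizes} is set, fibers are grown in attached groups: every
#' fiber after the first in a group starts at a point of a recently placed
#' group fiber, so the group is one connected component by construction and
#' percolates through the domain rather than collapsing into a blob. The
#' generator retries (deterministically, by reseeding from \code{seed}) if
#' chance contacts between groups change the component count.
#'
#' @param domain a \linkS4class{DomainSpec}.
#' @param params a \linkS4class{NetworkGenParams}.
#' @param mergeTolerance node merge tolerance passed to
#'   \code{\link{buildNetwork}}.
#' @return a \linkS4class{FiberNetwork}; \code{metadata(net)$trueVolume} holds
#'   the generator's exact total cylinder volume and
#'   \code{metadata$trueVerticalCount} the number of fibers drawn from the
#'   vertical mixture component (after clipping).
#' @export
generateFiberNetwork <- function(domain, params, mergeTolerance = 0.5) {
  validObject(domain); validObject(params)
  size <- c(domain@sizeX, domain@sizeY, domain@sizeZ)
  n <- params@nFibers
  if (n == 0L) {
    return(buildNetwork(list(), mergeTolerance,
                        metadata = list(trueVolume = 0, trueVerticalCount = 0L)))
  }
  sizes <- if (length(params@clusterSizes)) params@clusterSizes else rep(1L, n)
  maxTries <- if (length(params@clusterSizes)) 10L else 1L
  for (try in seq_len(maxTries)) {
    net <- withSeed(params@seed + 7919L * (try - 1L), {
      drawNetworkOnce(size, params, sizes, mergeTolerance)
    })
    if (!length(params@clusterSizes)) break
    if (countClusters(net)$nClusters == length(sizes)) break
  }
  if (params@nBreaks > 0L)
    net <- fragmentNetwork(net, params@nBreaks, gap = 2, seed = params@seed + 1L)
  net
}

# one seeded realization (RNG state assumed set by the caller)
drawNetworkOnce <- function(size, params, sizes, mergeTolerance) {
  cos45 <- cos(45 * pi / 180)
  drawDirection <- function() {
    vertical <- runif(1) < params@verticalFraction
    cosTheta <- if (vertical) runif(1, cos45, 1) else runif(1, 0, cos45)
    phi <- runif(1, 0, 2 * pi)
    sinTheta <- sqrt(1 - cosTheta^2)
    sgn <- sample(c(-1, 1), 1)
    c(sinTheta * cos(phi), sgn * cosTheta, sinTheta * sin(phi))
  }
  drawTrunc <- function(mean, sd, lower) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v > lower) return(v)
    }
  }
  fibers <- vector("list", sum(sizes))
  fid <- 0L
  trueVolume <- 0
  trueVertical <- 0L
  for (cs in sizes) {
    groupPts <- list()
    for (j in seq_len(cs)) {
      placed <- FALSE
      for (attempt in 1:50) {
        dir <- drawDirection()
        L <- drawTrunc(params@lengthMean, params@lengthSd, 1)
        anchorStart <- (j > 1L)
        if (anchorStart) {
          # attach to a recently placed group fiber so the group percolates
          # through the domain instead of collapsing into a compact blob
          gf <- length(groupPts)
          pf <- groupPts[[sample(max(1L, gf - 9L):gf, 1)]]
          a0 <- pf[sample(nrow(pf), 1), ]
          base0 <- a0
        } else {
          center <- runif(3) * size
          base0 <- center - dir * L / 2
        }
        npts <- max(2L, as.integer(ceiling(L / params@pointSpacing)) + 1L)
        s <- seq(0, L, length.out = npts)
        pts <- matrix(base0, npts, 3, byrow = TRUE) + outer(s, dir)
        if (params@waviness > 0) {
          p1 <- fiberPerp(dir)
          p2 <- c(dir[2] * p1[3] - dir[3] * p1[2],
                  dir[3] * p1[1] - dir[1] * p1[3],
                  dir[1] * p1[2] - dir[2] * p1[1])
          amp <- params@waviness * L
          f1 <- runif(1, 0.5, 1.5); f2 <- runif(1, 0.5, 1.5)
          ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
          o1 <- amp * (sin(2 * pi * f1 * s / L + ph1) - sin(ph1))
          o2 <- amp * (sin(2 * pi * f2 * s / L + ph2) - sin(ph2))
          # offsets vanish at the anchor point (s = 0) so attachments stay exact
          pts <- pts + outer(o1, p1) + outer(o2, p2)
        }
        anchorIdx <- 1L
        clip <- clipPolylineToBox(pts, size, anchor = anchorIdx)
        if (is.null(clip)) next
        if (anchorStart && !clip$containsAnchor) next
        m <- clip$piece
        if (polylineLength(m) < 0.5) next
        r <- drawTrunc(params@diameterMean, params@diameterSd, params@diameterMin) / 2
        fid <- fid + 1L
        fibers[[fid]] <- fiberPolyline(m, rep(r, nrow(m)), fid)
        trueVolume <- trueVolume + pi * r^2 * polylineLength(m)
        v <- m[nrow(m), ] - m[1, ]
        Lc <- sqrt(sum(v^2))
        if (Lc > 0 && acos(min(1, abs(v[2]) / Lc)) < 45 * pi / 180)
          trueVertical <- trueVertical + 1L
        groupPts[[length(groupPts) + 1L]] <- m
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place a fiber inside the domain after 50 attempts")
    }
  }
  fibers <- fibers[seq_len(fid)]
  buildNetwork(fibers, mergeTolerance,
               metadata = list(trueVolume = trueVolume,
                               trueVerticalCount = trueVertical))
}

# deterministic unit vector perpendicular to v
fiberPerp <- function(v) {
  ref <- c(0, 0, 0)
  ref[which.min(abs(v))] <- 1
  p <- ref - sum(ref * v) * v
  p / sqrt(sum(p^2))
}

#' Sever a fiber network at random interior locations
#'
#' Each break removes a \code{gap}-long interior portion of a randomly chosen
#' fiber (uniform among fibers long enough to be broken), splitting it into
#' two shorter fibers. Total fiber material volume decreases by exactly the
#' removed cylinder portions and the cluster count never decreases.
#'
#' @param net a \linkS4class{FiberNetwork}.
#' @param nBreaks number of severings (>= 0).
#' @param gap length of removed material per break (um, > 0).
#' @param seed integer RNG seed.
#' @return the fragmented \linkS4class{FiberNetwork}; metadata gains
#'   \code{removedVolume}.
#' @export
fragmentNetwork <- function(net, nBreaks, gap = 2, seed = 1L) {
  if (nBreaks < 0) stop("nBreaks must be >= 0")
  if (gap <= 0) stop("gap must be > 0")
  if (nBreaks == 0L) return(net)
  polys <- Filter(Negate(is.null), networkPolylines(net))
  withSeed(seed, {
    removed <- 0
    for (b in seq_len(nBreaks)) {
      lens <- vapply(polys, function(f) polylineLength(f@points), 1)
      eligible <- which(lens > gap + 0.2)
      if (!length(eligible)) {
        if (b == 1L) stop("gap is longer than every fiber; nothing can be broken")
        break
      }
      pick <- eligible[sample(length(eligible), 1)]
      f <- polys[[pick]]
      L <- lens[pick]
      margin <- min(0.1, (L - gap) / 4)
      u <- runif(1, gap / 2 + margin, L - gap / 2 - margin)
      pieces <- splitPolylineAt(f, u - gap / 2, u + gap / 2)
      removed <- removed + pi * mean(f@radii)^2 * gap
      polys[[pick]] <- pieces[[1]]
      polys[[length(polys) + 1]] <- pieces[[2]]
    }
    for (i in seq_along(polys)) polys[[i]]@fiberId <- i
    md <- net@metadata
    md$removedVolume <- (md$removedVolume %||% 0) + removed
    if (!is.null(md$trueVolume)) md$trueVolume <- md$trueVolume - removed
    buildNetwork(polys, net@mergeTolerance, metadata = md)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a polyline at arclengths s1 < s2, discarding the middle portion
splitPolylineAt <- function(f, s1, s2) {
  pts <- f@points
  r <- f@radii
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  interp <- function(s) {
    k <- max(which(cum <= s + 1e-12))
    k <- min(k, length(seglen))
    t <- (s - cum[k]) / seglen[k]
    list(p = pts[k, ] + t * (pts[k + 1, ] - pts[k, ]),
         r = r[k] + t * (r[k + 1] - r[k]), k = k)
  }
  a <- interp(s1); b <- interp(s2)
  m1 <- rbind(pts[seq_len(a$k), , drop = FALSE], a$p)
  r1 <- c(r[seq_len(a$k)], a$r)
  keep1 <- c(TRUE, rowSums((m1[-1, , drop = FALSE] - m1[-nrow(m1), , drop = FALSE])^2) > 1e-16)
  m1 <- m1[keep1, , drop = FALSE]; r1 <- r1[keep1]
  m2 <- rbind(b$p, pts[(b$k + 1):nrow(pts), , drop = FALSE])
  r2 <- c(b$r, r[(b$k + 1):length(r)])
  keep2 <- c(TRUE, rowSums((m2[-1, , drop = FALSE] - m2[-nrow(m2), , drop = FALSE])^2) > 1e-16)
  m2 <- m2[keep2, , drop = FALSE]; r2 <- r2[keep2]
  list(fiberPolyline(m1, r1, f@fiberId), fiberPolyline(m2, r2, f@fiberId))
}

#' Voxelize a fiber network into a synthetic image stack
#'
#' A voxel is fiber foreground when its center lies within the local radius of
#' any fiber centerline (capsule rasterization). Foreground voxels take
#' \code{fiberLevel}, the rest \code{backgroundLevel}; an optional Gaussian
#' blur and seeded additive Gaussian noise emulate confocal acquisition.
#'
#' @param net a \linkS4class{FiberNetwork}.
#' @param domain a \linkS4class{DomainSpec}; the voxel grid covers it.
#' @param vp a \linkS4class{VoxelizationParams}.
#' @return a \linkS4class{VoxelVolume}.
#' @export
voxelizeNetwork <- function(net, domain, vp) {
  validObject(vp)
  size <- c(domain@sizeX, domain@sizeY, domain@sizeZ)
  dims <- pmax(1L, as.integer(ceiling(size / vp@voxelSpacing)))
  seg <- networkSegments(net)
  minR <- if (nrow(seg)) min(seg$diameter) / 2 else Inf
  if (vp@voxelSpacing > minR)
    warning("voxel spacing exceeds the smallest fiber radius; thin fibers may vanish")
  fg <- if (nrow(seg)) {
    cpp_rasterize_segments(
      net@nodes[seg$node1, , drop = FALSE], net@nodes[seg$node2, , drop = FALSE],
      seg$diameter / 2, dims, rep(vp@voxelSpacing, 3), c(0, 0, 0))
  } else rep(FALSE, prod(dims))
  vol <- ifelse(fg, vp@fiberLevel, vp@backgroundLevel)
  if (vp@blurSigma > 0)
    vol <- cpp_gaussian_blur3d(vol, dims, vp@blurSigma)
  if (vp@noiseSd > 0)
    vol <- withSeed(vp@seed, vol + rnorm(length(vol), 0, vp@noiseSd))
  voxelVolume(array(vol, dims), spacing = vp@voxelSpacing)
}

#' Crop a fiber network to a sub-domain
#'
#' Fibers are clipped at the faces of the axis-aligned box \code{[lower,
#' lower + size]}; clipped pieces shorter than two points are dropped and the
#' result is re-indexed to the sub-domain's coordinates (lower corner at the
#' origin).
#'
#' @param net a \linkS4class{FiberNetwork}.
#' @param domain target \linkS4class{DomainSpec}.
#' @param lower lower corner of the crop box in the source coordinates.
#' @return a \linkS4class{FiberNetwork} in the cropped coordinates.
#' @export
cropNetwork <- function(net, domain, lower = c(0, 0, 0)) {
  size <- c(domain@sizeX, domain@sizeY, domain@sizeZ)
  polys <- Filter(Negate(is.null), networkPolylines(net))
  out <- list()
  for (f in polys) {
    pts <- sweep(f@points, 2, lower)
    clip <- clipPolylineToBox(pts, size)
    if (is.null(clip) || nrow(clip$piece) < 2) next
    # radii: nearest original radius (constant per fiber in generated nets)
    out[[length(out) + 1]] <- fiberPolyline(clip$piece,
                                            rep(mean(f@radii), nrow(clip$piece)),
                                            length(out) + 1L)
  }
  buildNetwork(out, net@mergeTolerance, metadata = list(croppedFrom = net@metadata))
}

# ---- donor-age presets ------------------------------------------------------

#' Donor-age network presets
#'
#' One preset per donor of the nine-sample cohort (ages 38-78). Each preset
#' pins the fiber count, mean diameter, vertical proportion, cluster count and
#' maximum cluster size of its donor; the fiber length scale is calibrated so
#' the measured elastin volume fraction matches the donor's value in the
#' standard 343.57 x 250 x 99.75 um domain. Presets ship as flat TOML files
#' under \code{inst/extdata/presets}.
#'
#' @param age donor age in years (one of 38, 39, 43, 49, 58, 59, 67, 70, 78).
#' @return \code{agePreset}: list with elements \code{age}, \code{params}
#'   (a \linkS4class{NetworkGenParams}), \code{domain} and \code{targets}
#'   (the donor's tabulated metrics). \code{agePresets}: vector of available
#'   ages.
#' @export
agePreset <- function(age) {
  path <- system.file("extdata", "presets", sprintf("preset_%d.toml", as.integer(age)),
                      package = "dermafiber")
  if (!nzchar(path)) stop("no preset for age ", age)
  readPresetFile(path)
}

#' @rdname agePreset
#' @export
agePresets <- function() {
  files <- list.files(system.file("extdata", "presets", package = "dermafiber"),
                      pattern = "^preset_[0-9]+\\.toml$")
  sort(as.integer(gsub("[^0-9]", "", files)))
}

#' Read a preset TOML file
#'
#' @param path preset file path.
#' @return see \code{\link{agePreset}}.
#' @export
readPresetFile <- function(path) {
  tm <- readFlatTOML(path)
  g <- tm$generator
  d <- tm$domain
  t <- tm$targets
  clusterSizes <- as.integer(g$cluster_sizes)
  params <- networkGenParams(
    nFibers = g$n_fibers, diameterMean = g$diameter_mean,
    diameterSd = g$diameter_sd, lengthMean = g$length_mean,
    lengthSd = g$length_sd, verticalFraction = g$vertical_fraction,
    waviness = g$waviness, clusterSizes = clusterSizes, seed = g$seed)
  list(age = tm$age,
       params = params,
       domain = domainSpec(d$size_x, d$size_y, d$size_z),
       targets = t)
}

#' Generate the network of a donor-age preset
#'
#' @param age donor age (see \code{\link{agePreset}}).
#' @param seed optional seed overriding the preset's.
#' @return a \linkS4class{FiberNetwork}.
#' @export
generatePresetNetwork <- function(age, seed = NULL) {
  ps <- agePreset(age)
  if (!is.null(seed)) ps$params@seed <- as.integer(seed)
  generateFiberNetwork(ps$domain, ps$params)
}
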