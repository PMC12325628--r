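#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib dermafiber, .registration = TRUE
NULL

#' Physical domain of a dermal sample
#'
#' A rectangular box in micrometres. The Y axis is the skin-surface normal and
#' the compression axis; X and Z span the horizontal (surface-parallel) plane.
#' The default cross-section of the study models is 343.57 x 99.75 um^2 in
#' (X, Z); the height (Y) corresponds to the depth of the imaged stack.
#'
#' @slot sizeX,sizeY,sizeZ box edge lengths in um (all positive).
#' @export
setClass("DomainSpec",
  representation(sizeX = "numeric", sizeY = "numeric", sizeZ = "numeric"),
  validity = function(object) {
    s <- c(object@sizeX, object@sizeY, object@sizeZ)
    if (length(s) != 3 || any(!is.finite(s)) || any(s <= 0))
      return("all domain sizes must be finite and positive")
    TRUE
  })

#' @param sizeX,sizeY,sizeZ box edge lengths in um.
#' @rdname DomainSpec-class
#' @export
domainSpec <- function(sizeX = 343.57, sizeY = 250, sizeZ = 99.75) {
  new("DomainSpec", sizeX = as.numeric(sizeX), sizeY = as.numeric(sizeY),
      sizeZ = as.numeric(sizeZ))
}

#' Parameters controlling synthetic fiber-network generation
#'
#' @slot nFibers number of fibers to draw (before any fragmentation).
#' @slot diameterMean,diameterSd fiber diameter distribution (um), truncated
#'   below at \code{diameterMin}.
#' @slot diameterMin lower truncation of the diameter draw (um).
#' @slot lengthMean,lengthSd fiber length distribution (um), truncated below
#'   at 1 um.
#' @slot verticalFraction target expected proportion of fibers whose chord
#'   makes an angle < 45 degrees with the Y axis, in [0, 1].
#' @slot nBreaks number of random severings applied after generation.
#' @slot waviness dimensionless transverse perturbation amplitude (fraction of
#'   fiber length).
#' @slot clusterSizes optional integer vector summing to \code{nFibers}; when
#'   set, fibers are grown in attached groups of these sizes so the network
#'   has exactly \code{length(clusterSizes)} connected components by
#'   construction. When empty, fibers are placed independently.
#' @slot pointSpacing arclength step between polyline points (um).
#' @slot seed integer RNG seed.
#' @export
setClass("NetworkGenParams",
  representation(nFibers = "integer", diameterMean = "numeric",
                 diameterSd = "numeric", diameterMin = "numeric",
                 lengthMean = "numeric", lengthSd = "numeric",
                 verticalFraction = "numeric", nBreaks = "integer",
                 waviness = "numeric", clusterSizes = "integer",
                 pointSpacing = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nFibers < 0) return("nFibers must be >= 0")
    if (object@diameterMean <= 0) return("diameterMean must be > 0")
    if (object@verticalFraction < 0 || object@verticalFraction > 1)
      return("verticalFraction must lie in [0, 1]")
    if (object@nBreaks < 0) return("nBreaks must be >= 0")
    if (length(object@clusterSizes) &&
        sum(object@clusterSizes) != object@nFibers)
      return("clusterSizes must sum to nFibers")
    if (object@pointSpacing <= 0) return("pointSpacing must be > 0")
    TRUE
  })

#' @param nFibers,diameterMean,diameterSd,diameterMin,lengthMean,lengthSd,verticalFraction,nBreaks,waviness,clusterSizes,pointSpacing,seed see slots.
#' @rdname NetworkGenParams-class
#' @export
networkGenParams <- function(nFibers = 500, diameterMean = 3.6,
                             diameterSd = 0.5, diameterMin = 0.5,
                             lengthMean = 20, lengthSd = 6,
                             verticalFraction = 0.25, nBreaks = 0,
                             waviness = 0.05, clusterSizes = integer(0),
                             pointSpacing = 4, seed = 1L) {
  new("NetworkGenParams", nFibers = as.integer(nFibers),
      diameterMean = as.numeric(diameterMean), diameterSd = as.numeric(diameterSd),
      diameterMin = as.numeric(diameterMin),
      lengthMean = as.numeric(lengthMean), lengthSd = as.numeric(lengthSd),
      verticalFraction = as.numeric(verticalFraction),
      nBreaks = as.integer(nBreaks), waviness = as.numeric(waviness),
      clusterSizes = as.integer(clusterSizes),
      pointSpacing = as.numeric(pointSpacing), seed = as.integer(seed))
}

#' Parameters of the synthetic confocal acquisition
#'
#' @slot voxelSpacing isotropic voxel edge (um/voxel).
#' @slot backgroundLevel,fiberLevel image intensities of background and fiber
#'   voxels (fiberLevel must exceed backgroundLevel).
#' @slot noiseSd additive Gaussian noise standard deviation (intensity units).
#' @slot blurSigma Gaussian blur standard deviation (voxels); 0 disables.
#' @slot seed integer RNG seed for the noise draw.
#' @export
setClass("VoxelizationParams",
  representation(voxelSpacing = "numeric", backgroundLevel = "numeric",
                 fiberLevel = "numeric", noiseSd = "numeric",
                 blurSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@voxelSpacing <= 0) return("voxelSpacing must be > 0")
    if (object@fiberLevel <= object@backgroundLevel)
      return("fiberLevel must exceed backgroundLevel")
    if (object@noiseSd < 0 || object@blurSigma < 0)
      return("noiseSd and blurSigma must be >= 0")
    TRUE
  })

#' @param voxelSpacing,backgroundLevel,fiberLevel,noiseSd,blurSigma,seed see slots.
#' @rdname VoxelizationParams-class
#' @export
voxelizationParams <- function(voxelSpacing = 0.5, backgroundLevel = 100,
                               fiberLevel = 1000, noiseSd = 0, blurSigma = 0,
                               seed = 1L) {
  new("VoxelizationParams", voxelSpacing = as.numeric(voxelSpacing),
      backgroundLevel = as.numeric(backgroundLevel),
      fiberLevel = as.numeric(fiberLevel), noiseSd = as.numeric(noiseSd),
      blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

#' 3D grayscale volume with physical voxel spacing
#'
#' Array axes are ordered (x, y, z); voxel i (1-based) is centered at
#' origin + (i - 0.5) * spacing along each axis.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing per-axis voxel spacing (um/voxel, length 3).
#' @slot origin physical coordinate of the grid corner (um, length 3).
#' @export
setClass("VoxelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3) return("data must be a 3D array")
    if (any(dim(object@data) < 1)) return("each axis must have >= 1 voxel")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    if (length(object@origin) != 3) return("origin must have length 3")
    TRUE
  })

#' @param data 3D numeric array.
#' @param spacing voxel spacing, recycled to length 3.
#' @param origin grid corner coordinates.
#' @rdname VoxelVolume-class
#' @export
voxelVolume <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  new("VoxelVolume", data = data, spacing = rep(as.numeric(spacing), length.out = 3),
      origin = as.numeric(origin))
}

#' Binary segmentation mask on the grid of its source volume
#'
#' @slot data 3D logical array.
#' @slot spacing,origin as in \linkS4class{VoxelVolume}.
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (!is.logical(object@data)) return("mask data must be logical")
    if (length(dim(object@data)) != 3) return("data must be a 3D array")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    TRUE
  })

#' @param data 3D logical array.
#' @param spacing,origin grid geometry.
#' @rdname BinaryMask-class
#' @export
binaryMask <- function(data, spacing = 1, origin = c(0, 0, 0)) {
  new("BinaryMask", data = data, spacing = rep(as.numeric(spacing), length.out = 3),
      origin = as.numeric(origin))
}

#' A single fiber centerline
#'
#' An ordered polyline in physical coordinates with a local radius at every
#' point.
#'
#' @slot points n x 3 coordinate matrix (um), n >= 2, consecutive points
#'   distinct.
#' @slot radii per-point radii (um, positive).
#' @slot fiberId integer identifier.
#' @export
setClass("FiberPolyline",
  representation(points = "matrix", radii = "numeric", fiberId = "integer"),
  validity = function(object) {
    if (ncol(object@points) != 3) return("points must be n x 3")
    if (nrow(object@points) < 2) return("a polyline needs >= 2 points")
    if (length(object@radii) != nrow(object@points))
      return("one radius per point required")
    if (any(object@radii <= 0)) return("radii must be positive")
    d <- rowSums((object@points[-1, , drop = FALSE] -
                  object@points[-nrow(object@points), , drop = FALSE])^2)
    if (any(d == 0)) return("consecutive points must be distinct")
    TRUE
  })

#' @param points,radii,fiberId see slots.
#' @rdname FiberPolyline-class
#' @export
fiberPolyline <- function(points, radii, fiberId = 1L) {
  new("FiberPolyline", points = points, radii = as.numeric(radii),
      fiberId = as.integer(fiberId))
}

#' Fiber network as a shared-node beam-segment graph
#'
#' Polyline points within \code{mergeTolerance} of one another collapse to a
#' single node, so fibers touching each other share nodes and form connected
#' components ("clusters").
#'
#' @slot nodes n x 3 node coordinates (um).
#' @slot paths list of integer vectors: ordered node indices of each fiber.
#' @slot radii list of numeric vectors: per-point radii aligned with paths.
#' @slot fiberIds integer fiber identifiers.
#' @slot mergeTolerance node-merge tolerance (um).
#' @slot metadata free-form list (generator bookkeeping such as the ground
#'   truth fiber volume).
#' @export
setClass("FiberNetwork",
  representation(nodes = "matrix", paths = "list", radii = "list",
                 fiberIds = "integer", mergeTolerance = "numeric",
                 metadata = "list"),
  validity = function(object) {
    if (length(object@paths) != length(object@radii) ||
        length(object@paths) != length(object@fiberIds))
      return("paths, radii and fiberIds must have equal length")
    if (length(object@paths)) {
      idx <- unlist(object@paths)
      if (length(idx) && (min(idx) < 1 || max(idx) > nrow(object@nodes)))
        return("path node index out of range")
    }
    if (object@mergeTolerance < 0) return("mergeTolerance must be >= 0")
    TRUE
  })

#' Tetrahedral box mesh with embedded beam fibers
#'
#' @slot nodes n x 3 node coordinates (um).
#' @slot tets m x 4 tetrahedron connectivity (1-based node indices, positive
#'   orientation).
#' @slot beams data.frame with columns node1, node2, diameter, fiber: 2-node
#'   beam elements whose endpoints are mesh nodes.
#' @slot gridDims number of cells per axis of the structured grid.
#' @slot gridSpacing cell edge per axis (um).
#' @slot domain the \linkS4class{DomainSpec} the mesh fills.
#' @slot metadata embedding bookkeeping (snap displacements, dropped beams).
#' @export
setClass("TetMeshModel",
  representation(nodes = "matrix", tets = "matrix", beams = "data.frame",
                 gridDims = "integer", gridSpacing = "numeric",
                 domain = "DomainSpec", metadata = "list"))

#' Material parameters of the dermal compression model
#'
#' Units: MPa. Lame parameters are derived as lambda = E nu /((1+nu)(1-2nu)),
#' mu = E/(2(1+nu)).
#'
#' @slot EMatrix dermal matrix Young's modulus (MPa; default 0.08 = 80 kPa).
#' @slot nu Poisson's ratio (0 < nu < 0.5; default 0.48, near-incompressible).
#' @slot EFiber elastin fiber Young's modulus (MPa; default 0.5).
#' @export
setClass("MaterialParams",
  representation(EMatrix = "numeric", nu = "numeric", EFiber = "numeric"),
  validity = function(object) {
    if (object@EMatrix <= 0 || object@EFiber <= 0)
      return("moduli must be positive")
    if (object@nu <= 0 || object@nu >= 0.5)
      return("nu must satisfy 0 < nu < 0.5")
    TRUE
  })

#' @param EMatrix,nu,EFiber see slots.
#' @rdname MaterialParams-class
#' @export
materialParams <- function(EMatrix = 0.08, nu = 0.48, EFiber = 0.5) {
  new("MaterialParams", EMatrix = as.numeric(EMatrix), nu = as.numeric(nu),
      EFiber = as.numeric(EFiber))
}

#' Loading program of the unconfined compression simulation
#'
#' @slot compressionRatio fraction of the initial height removed at full load
#'   (default 0.20, i.e. compression to 80 percent height).
#' @slot nIncrements number of displacement increments.
#' @slot newtonTol relative residual tolerance of the Newton iteration.
#' @slot maxIterations Newton iteration cap per increment.
#' @export
setClass("CompressionSetup",
  representation(compressionRatio = "numeric", nIncrements = "integer",
                 newtonTol = "numeric", maxIterations = "integer"),
  validity = function(object) {
    if (object@compressionRatio <= 0 || object@compressionRatio >= 1)
      return("compressionRatio must lie in (0, 1)")
    if (object@newtonTol <= 0) return("newtonTol must be > 0")
    if (object@nIncrements < 1) return("nIncrements must be >= 1")
    TRUE
  })

#' @param compressionRatio,nIncrements,newtonTol,maxIterations see slots.
#' @rdname CompressionSetup-class
#' @export
compressionSetup <- function(compressionRatio = 0.20, nIncrements = 10,
                             newtonTol = 1e-8, maxIterations = 25) {
  new("CompressionSetup", compressionRatio = as.numeric(compressionRatio),
      nIncrements = as.integer(nIncrements), newtonTol = as.numeric(newtonTol),
      maxIterations = as.integer(maxIterations))
}

#' Converged state of a compression simulation
#'
#' @slot displacements n x 3 nodal displacements (um).
#' @slot rotations r x 3 beam-node rotations (rad), rows aligned with
#'   \code{rotNodes}.
#' @slot rotNodes mesh node indices carrying beam rotational dofs.
#' @slot reactionForceTop total resisting force on the compressed top surface
#'   (uN, positive under compression).
#' @slot fiberAxialForces per-beam signed axial force (uN, tension positive).
#' @slot elementEquivalentStrain per-tetrahedron equivalent Green-Lagrange
#'   strain (dimensionless).
#' @slot converged logical convergence flag.
#' @slot mesh the \linkS4class{TetMeshModel} that was solved.
#' @slot materials the \linkS4class{MaterialParams} used.
#' @slot setup the \linkS4class{CompressionSetup} used.
#' @export
setClass("SimulationResult",
  representation(displacements = "matrix", rotations = "matrix",
                 rotNodes = "integer", reactionForceTop = "numeric",
                 fiberAxialForces = "numeric",
                 elementEquivalentStrain = "numeric", converged = "logical",
                 mesh = "TetMeshModel", materials = "MaterialParams",
                 setup = "CompressionSetup"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "DomainSpec", function(object) {
  cat(sprintf("DomainSpec: %.2f x %.2f x %.2f um (X x Y x Z; Y = surface normal)\n",
              object@sizeX, object@sizeY, object@sizeZ))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing %s um, intensity [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@data),
              100 * mean(object@data)))
})

setMethod("show", "FiberNetwork", function(object) {
  cat(sprintf("FiberNetwork: %d fibers, %d nodes, %d segments (merge tol %.3g um)\n",
              length(object@paths), nrow(object@nodes),
              sum(vapply(object@paths, length, 1L)) - length(object@paths),
              object@mergeTolerance))
})

setMethod("show", "TetMeshModel", function(object) {
  cat(sprintf("TetMeshModel: %d nodes, %d tetrahedra, %d beams\n",
              nrow(object@nodes), nrow(object@tets), nrow(object@beams)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %s, top reaction %.4g uN, %d beams, %d tets\n",
              if (object@converged) "converged" else "NOT converged",
              object@reactionForceTop, length(object@fiberAxialForces),
              length(object@elementEquivalentStrain)))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for the core data classes
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{voxelData} the raw array; \code{voxelSpacing} the per-axis
#'   spacing; \code{networkNodes} the node coordinate matrix;
#'   \code{fiberPaths} the list of node-index paths; \code{fiberCount} the
#'   number of fibers; \code{networkSegments} a data.frame of 2-node segments
#'   with diameters; \code{domainVolume} the box volume in um^3.
#' @name accessors
NULL

#' @rdname accessors
#' @export
voxelData <- function(x) x@data

#' @rdname accessors
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
fiberPaths <- function(x) x@paths

#' @rdname accessors
#' @export
fiberCount <- function(x) length(x@paths)

#' @rdname accessors
#' @export
domainVolume <- function(x) x@sizeX * x@sizeY * x@sizeZ

#' @rdname accessors
#' @export
networkSegments <- function(x) {
  np <- vapply(x@paths, length, 1L)
  if (!length(np) || sum(np - 1L) == 0)
    return(data.frame(node1 = integer(0), node2 = integer(0),
                      diameter = numeric(0), fiber = integer(0)))
  n1 <- unlist(lapply(x@paths, function(p) p[-length(p)]))
  n2 <- unlist(lapply(x@paths, function(p) p[-1]))
  dia <- unlist(lapply(x@radii, function(r) r[-length(r)] + r[-1]))
  fib <- rep(x@fiberIds, np - 1L)
  data.frame(node1 = n1, node2 = n2, diameter = dia, fiber = fib)
}
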