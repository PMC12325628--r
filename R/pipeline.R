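#' Quantify one donor sample end to end
#'
#' Generates the donor's preset network, measures the six architecture metrics
#' and optionally runs the unconfined compression simulation of the full
#' domain at a coarse tetrahedral mesh (cluster-grown networks are spatially
#' heterogeneous, so sub-cropping would misrepresent them).
#'
#' @param age donor age (see \code{\link{agePreset}}).
#' @param seed optional RNG seed overriding the preset's.
#' @param simulate run the finite element compression step.
#' @param meshEdge target tetrahedral cell edge (um).
#' @param nIncrements compression increments.
#' @param materials a \linkS4class{MaterialParams}.
#' @return list with \code{age}, \code{network}, \code{metrics} (one-row
#'   data.frame) and, when simulated, \code{simulation} plus the derived
#'   columns \code{reaction_force_un}, \code{top_traction_kpa},
#'   \code{mean_equivalent_strain}, \code{low_strain_fraction},
#'   \code{mean_axial_force_un} merged into \code{metrics}.
#' @export
quantifySample <- function(age, seed = NULL, simulate = TRUE,
                           meshEdge = 12, nIncrements = 4,
                           materials = materialParams()) {
  ps <- agePreset(age)
  net <- generatePresetNetwork(age, seed)
  metrics <- architectureMetrics(net, ps$domain)
  metrics <- cbind(data.frame(age = ps$age), metrics)
  out <- list(age = ps$age, network = net, metrics = metrics)
  if (simulate) {
    mesh <- buildBoxMesh(ps$domain, meshEdge)
    mesh <- embedBeams(mesh, net)
    setup <- compressionSetup(nIncrements = nIncrements)
    sim <- solveCompression(mesh, materials, setup)
    area <- ps$domain@sizeX * ps$domain@sizeZ
    metrics$reaction_force_un <- sim@reactionForceTop
    metrics$top_traction_kpa <- 1000 * sim@reactionForceTop / area
    metrics$mean_equivalent_strain <- mean(sim@elementEquivalentStrain)
    metrics$low_strain_fraction <- mean(lowStrainMask(sim))
    metrics$mean_axial_force_un <-
      if (length(sim@fiberAxialForces)) mean(sim@fiberAxialForces) else NA_real_
    out$simulation <- sim
    out$metrics <- metrics
  }
  out
}

#' Run the full cohort study
#'
#' For every donor preset: generate the network, measure its architecture,
#' optionally simulate the compression, then merge the tabulated normalized
#' firmness and correlate each quantity with it. All stages are seeded, so a
#' rerun with the same arguments reproduces every number exactly.
#'
#' @param ages donor ages to include (default: all presets).
#' @param seed base RNG seed; donor i uses \code{seed + i} (NULL keeps each
#'   preset's own seed).
#' @param simulate run the finite element stage per donor.
#' @param outputDir optional directory; when set, writes
#'   \code{study_metrics.csv}, \code{study_correlations.csv},
#'   \code{study_summary.json} and \code{manifest.json} (with md5 checksums).
#' @param meshEdge,nIncrements,materials forwarded to
#'   \code{\link{quantifySample}}.
#' @param verbose print progress lines.
#' @return list with \code{metrics} (one row per donor, incl. firmness),
#'   \code{correlations} (each metric vs firmness), \code{ageComparison}
#'   (younger/older Welch tests), \code{samples} (the per-donor lists) and
#'   \code{manifest} (when written).
#' @export
runStudy <- function(ages = agePresets(), seed = NULL, simulate = TRUE,
                     outputDir = NULL, meshEdge = 12,
                     nIncrements = 4, materials = materialParams(),
                     verbose = FALSE) {
  cohort <- cohortTable()
  samples <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    if (verbose) message("donor age ", ages[i])
    s <- if (is.null(seed)) NULL else as.integer(seed + i)
    samples[[i]] <- quantifySample(ages[i], seed = s, simulate = simulate,
                                   meshEdge = meshEdge,
                                   nIncrements = nIncrements,
                                   materials = materials)
  }
  metrics <- do.call(rbind, lapply(samples, function(s) s$metrics))
  metrics$firmness <- cohort$firmness[match(metrics$age, cohort$age)]
  correlations <- correlateWithFirmness(metrics)
  ageComparison <- compareAgeGroups(metrics)
  out <- list(metrics = metrics, correlations = correlations,
              ageComparison = ageComparison, samples = samples)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    fMet <- file.path(outputDir, "study_metrics.csv")
    fCor <- file.path(outputDir, "study_correlations.csv")
    fSum <- file.path(outputDir, "study_summary.json")
    utils::write.csv(metrics, fMet, row.names = FALSE)
    utils::write.csv(correlations, fCor, row.names = FALSE)
    writeMetricsJSON(list(
      n_donors = length(ages), ages = ages,
      simulated = simulate,
      correlations = correlations,
      age_comparison = ageComparison), fSum)
    files <- c(fMet, fCor, fSum)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    fMan <- file.path(outputDir, "manifest.json")
    writeMetricsJSON(manifest, fMan)
    out$manifest <- manifest
  }
  out
}

#' Round-trip a generated network through the imaging pipeline
#'
#' Voxelizes a network at the given acquisition settings, runs the full
#' segmentation pipeline on the synthetic stack and measures the recovered
#' architecture, returning truth and recovery side by side. This is the
#' validation loop for the image-processing stage.
#'
#' @param net a \linkS4class{FiberNetwork} (ground truth).
#' @param domain the \linkS4class{DomainSpec} containing it.
#' @param vp a \linkS4class{VoxelizationParams}.
#' @param ... forwarded to \code{\link{segmentFiberStack}}.
#' @return list with \code{truth} and \code{recovered} metric rows,
#'   \code{recoveredNetwork} and the segmentation \code{mask}.
#' @export
roundTripNetwork <- function(net, domain, vp = voxelizationParams(), ...) {
  vol <- voxelizeNetwork(net, domain, vp)
  seg <- segmentFiberStack(vol, ...)
  rec <- buildNetwork(seg$fibers, mergeTolerance = net@mergeTolerance)
  list(truth = architectureMetrics(net, domain),
       recovered = architectureMetrics(rec, domain),
       recoveredNetwork = rec, mask = seg$mask)
}
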