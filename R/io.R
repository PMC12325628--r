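#' Write fiber polylines to CSV
#'
#' Long format, one row per polyline point: \code{fiber_id},
#' \code{point_index}, \code{x_um}, \code{y_um}, \code{z_um},
#' \code{radius_um}.
#'
#' @param fibers list of \linkS4class{FiberPolyline} objects.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeFiberCSV <- function(fibers, path) {
  rows <- lapply(fibers, function(f) {
    n <- nrow(f@points)
    data.frame(fiber_id = f@fiberId, point_index = seq_len(n),
               x_um = f@points[, 1], y_um = f@points[, 2],
               z_um = f@points[, 3], radius_um = f@radii)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fiber_id = integer(0), point_index = integer(0),
               x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
               radius_um = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fiber polylines from CSV
#'
#' Inverse of \code{\link{writeFiberCSV}}.
#'
#' @param path CSV file written by \code{\link{writeFiberCSV}}.
#' @return list of \linkS4class{FiberPolyline} objects.
#' @export
readFiberCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("fiber_id", "point_index", "x_um", "y_um", "z_um", "radius_um")
  if (!all(need %in% names(df))) stop("missing fiber CSV columns")
  ids <- unique(df$fiber_id)
  lapply(ids, function(id) {
    sub <- df[df$fiber_id == id, , drop = FALSE]
    sub <- sub[order(sub$point_index), , drop = FALSE]
    fiberPolyline(cbind(sub$x_um, sub$y_um, sub$z_um), sub$radius_um,
                  as.integer(id))
  })
}

#' Write a voxel volume as a multi-page 16-bit TIFF
#'
#' Pages run along the Y axis (depth from the skin surface); each page is the
#' X-Z plane at one depth. Intensities are stored as 16-bit unsigned samples;
#' values are clamped to [0, 65535].
#'
#' @param vol a \linkS4class{VoxelVolume}.
#' @param path output .tif file.
#' @return the path, invisibly.
#' @export
writeVolumeTIFF <- function(vol, path) {
  d <- dim(vol@data)
  pages <- lapply(seq_len(d[2]), function(j) {
    # tiff expects a matrix indexed [row, col]; use rows = Z, cols = X
    pg <- t(vol@data[, j, , drop = FALSE][, 1, ])
    pmin(pmax(pg, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF written by \code{\link{writeVolumeTIFF}}
#'
#' @param path .tif file.
#' @param spacing voxel spacing (um) to attach to the volume.
#' @param origin corner coordinates (um).
#' @return a \linkS4class{VoxelVolume} with integer intensities in
#'   [0, 65535].
#' @export
readVolumeTIFF <- function(path, spacing = 0.5, origin = c(0, 0, 0)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); ny <- length(pages)
  arr <- array(0, dim = c(nx, ny, nz))
  for (j in seq_len(ny)) arr[, j, ] <- t(pages[[j]])
  voxelVolume(round(arr * 65535), spacing = spacing, origin = origin)
}

#' Write a tetrahedral mesh and nodal results as legacy VTK
#'
#' ASCII legacy (.vtk) unstructured grid with optional point displacement
#' vectors and per-cell equivalent strain, viewable in standard VTK tools.
#'
#' @param mesh a \linkS4class{TetMeshModel}.
#' @param path output .vtk file.
#' @param result optional \linkS4class{SimulationResult} for the field data.
#' @return the path, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, result = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh@nodes); nt <- nrow(mesh@tets)
  writeLines(c("# vtk DataFile Version 3.0", "tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", nn)),
             con)
  writeLines(apply(mesh@nodes, 1, function(p) paste(format(p, digits = 10),
                                                    collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nt, nt * 5L), con)
  writeLines(apply(mesh@tets - 1L, 1, function(t)
    paste(c(4L, t), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  if (!is.null(result)) {
    writeLines(c(sprintf("POINT_DATA %d", nn),
                 "VECTORS displacement double"), con)
    writeLines(apply(result@displacements, 1, function(p)
      paste(format(p, digits = 10), collapse = " ")), con)
    writeLines(c(sprintf("CELL_DATA %d", nt),
                 "SCALARS equivalent_strain double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(format(result@elementEquivalentStrain, digits = 10), con)
  }
  invisible(path)
}

#' Write fiber centerlines as legacy VTK polylines
#'
#' @param fibers list of \linkS4class{FiberPolyline} objects.
#' @param path output .vtk file.
#' @return the path, invisibly.
#' @export
writeFibersVTK <- function(fibers, path) {
  fibers <- fibers[!vapply(fibers, is.null, TRUE)]
  con <- file(path, "w")
  on.exit(close(con))
  pts <- do.call(rbind, lapply(fibers, function(f) f@points))
  npt <- vapply(fibers, function(f) nrow(f@points), 1L)
  writeLines(c("# vtk DataFile Version 3.0", "fiber centerlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(pts))),
             con)
  writeLines(apply(pts, 1, function(p) paste(format(p, digits = 10),
                                             collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(fibers),
                     length(fibers) + sum(npt)), con)
  off <- c(0L, cumsum(npt))
  for (i in seq_along(fibers)) {
    writeLines(paste(c(npt[i], seq.int(off[i], off[i + 1] - 1L)),
                     collapse = " "), con)
  }
  writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS radius_um double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(unlist(lapply(fibers, function(f) f@radii)),
                    digits = 10), con)
  invisible(path)
}

#' Write a metrics list or data.frame as JSON
#'
#' @param metrics list or data.frame of named numeric results.
#' @param path output .json file.
#' @return the path, invisibly.
#' @export
writeMetricsJSON <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
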