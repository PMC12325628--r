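# internal helpers shared across modules

# evaluate expr with a local, seeded RNG state, restoring the caller's state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# single-linkage merge of 3D points within tolerance, via cell hashing.
# Returns integer vector mapping each point to its merged-group id (1..ngroups).
mergePointGroups <- function(pts, tol) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  if (tol <= 0) {
    key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "_")
    return(match(key, unique(key)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  cell <- floor(pts / tol)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = "_")
  byCell <- split(seq_len(n), key)
  tol2 <- tol * tol
  # candidate pairs: same cell or one of the 13 forward neighbor cells
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[(offs[, 1] > 0) | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  linkWithin <- function(ids) {
    if (length(ids) < 2) return(invisible())
    for (a in seq_len(length(ids) - 1)) {
      da <- pts[ids[(a + 1):length(ids)], , drop = FALSE]
      pa <- pts[ids[a], ]
      d2 <- (da[, 1] - pa[1])^2 + (da[, 2] - pa[2])^2 + (da[, 3] - pa[3])^2
      hit <- which(d2 <= tol2)
      for (h in hit) unite(ids[a], ids[a + h])
    }
  }
  for (ids in byCell) linkWithin(ids)
  cellEnv <- new.env(hash = TRUE, size = length(byCell) * 2L)
  for (k in names(byCell)) assign(k, byCell[[k]], envir = cellEnv)
  cells <- names(byCell)
  cellMat <- do.call(rbind, lapply(strsplit(cells, "_", fixed = TRUE), as.numeric))
  for (o in seq_len(nrow(offs))) {
    nbr <- cellMat + matrix(offs[o, ], nrow(cellMat), 3, byrow = TRUE)
    nbrKey <- paste(nbr[, 1], nbr[, 2], nbr[, 3], sep = "_")
    present <- which(nbrKey %in% cells)
    for (ci in present) {
      idsA <- byCell[[cells[ci]]]
      idsB <- get(nbrKey[ci], envir = cellEnv)
      pb <- pts[idsB, , drop = FALSE]
      for (a in idsA) {
        d2 <- (pb[, 1] - pts[a, 1])^2 + (pb[, 2] - pts[a, 2])^2 +
              (pb[, 3] - pts[a, 3])^2
        hit <- which(d2 <= tol2)
        for (h in hit) unite(a, idsB[h])
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# clip a polyline to an axis-aligned box [0, size] per axis; returns the list
# of >= 2-point pieces (matrices), with exact boundary intersection points.
# anchor: row index whose piece is preferred (else the longest piece).
clipPolylineToBox <- function(pts, size, anchor = 1L) {
  eps <- 1e-9
  inside <- pts[, 1] >= -eps & pts[, 1] <= size[1] + eps &
            pts[, 2] >= -eps & pts[, 2] <= size[2] + eps &
            pts[, 3] >= -eps & pts[, 3] <= size[3] + eps
  n <- nrow(pts)
  if (all(inside)) {
    return(list(piece = pmin(pmax(pts, 0), matrix(size, n, 3, byrow = TRUE)),
                containsAnchor = TRUE))
  }
  # parametric clip of each segment against the box, assemble runs
  pieces <- list()
  cur <- NULL
  curHasAnchor <- FALSE
  pushPoint <- function(p) cur[[length(cur) + 1]] <<- p
  closeRun <- function() {
    if (length(cur) >= 2) {
      m <- do.call(rbind, cur)
      keep <- c(TRUE, rowSums((m[-1, , drop = FALSE] -
                               m[-nrow(m), , drop = FALSE])^2) > 1e-16)
      m <- m[keep, , drop = FALSE]
      if (nrow(m) >= 2)
        pieces[[length(pieces) + 1]] <<- list(m = m, anchor = curHasAnchor)
    }
    cur <<- NULL
    curHasAnchor <<- FALSE
  }
  clampIn <- function(p) pmin(pmax(p, 0), size)
  for (s in seq_len(n - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    d <- b - a
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-14) {
        if (a[ax] < -eps || a[ax] > size[ax] + eps) { ok <- FALSE; break }
      } else {
        ta <- (0 - a[ax]) / d[ax]; tb <- (size[ax] - a[ax]) / d[ax]
        lo <- min(ta, tb); hi <- max(ta, tb)
        t0 <- max(t0, lo); t1 <- min(t1, hi)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (!ok) { closeRun(); next }
    pa <- clampIn(a + t0 * d); pb <- clampIn(a + t1 * d)
    if (is.null(cur)) {
      pushPoint(pa)
    } else if (t0 > 0) {
      closeRun()
      pushPoint(pa)
    }
    pushPoint(pb)
    if (s == anchor || (s + 1) == anchor) curHasAnchor <- TRUE
    if (t1 < 1) closeRun()
  }
  closeRun()
  if (!length(pieces)) return(NULL)
  anchored <- which(vapply(pieces, function(p) p$anchor, TRUE))
  pick <- if (length(anchored)) anchored[1] else {
    lens <- vapply(pieces, function(p) {
      m <- p$m
      sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
    }, 1)
    which.max(lens)
  }
  list(piece = pieces[[pick]]$m, containsAnchor = length(anchored) > 0)
}

# total arclength of a polyline matrix
polylineLength <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

# fiber chord unit vector (first to last point); NULL for degenerate chords
fiberChord <- function(m) {
  v <- m[nrow(m), ] - m[1, ]
  L <- sqrt(sum(v^2))
  if (L < 1e-12) return(NULL)
  v / L
}

# minimal flat TOML reader: [section] headers, key = value scalars (numbers,
# booleans, quoted strings) and [a, b, ...] numeric arrays
readFlatTOML <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parseVal <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[", v)) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (!nzchar(trimws(inner))) return(numeric(0))
      return(as.numeric(trimws(strsplit(inner, ",")[[1]])))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln) && !grepl("=", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(kv) == 3) {
      if (is.null(section)) out[[kv[2]]] <- parseVal(kv[3])
      else out[[section]][[kv[2]]] <- parseVal(kv[3])
    }
  }
  out
}
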