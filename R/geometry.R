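# Field-of-view estimation and autocalibration-region detection from the
# Voronoi tessellation of the sampling pattern.
#
# On a Nyquist-sampled Cartesian grid with N pixels per axis the sample
# spacing is 1/N and the Chebyshev distance from a sample to its Voronoi cell
# vertices is exactly 1/(2N). Reading that relation backwards, the largest
# Chebyshev vertex distance D among the densely sampled center cells bounds
# the alias-free field of view: N = floor(1 / (2 D)).

#' Estimate the supported field of view from sampling density
#'
#' Examines the Voronoi cells of the k-space samples inside the
#' fully sampled center (radius \code{centerRadius} in normalized units) and
#' converts their largest Chebyshev vertex distance D into the largest
#' alias-free grid size \code{floor(1/(2D))}.
#'
#' @param tess \code{VoronoiTessellation} of the trajectory
#' @param traj the matching \code{Trajectory}
#' @param centerRadius radius of the k-space core assumed fully sampled
#'   (default 0.05, i.e. 5 percent of the unit bandwidth)
#' @param perAxis if TRUE use per-axis vertex offsets, giving an anisotropic
#'   estimate; default FALSE (isotropic: one N for all axes)
#' @return integer vector, estimated FOV in pixels per axis
#' @export
estimateFov <- function(tess, traj, centerRadius = 0.05, perAxis = FALSE) {
  pts <- tess@points
  d <- ncol(pts)
  C <- which(sqrt(rowSums(pts^2)) <= centerRadius)
  if (length(C) == 0L) stop("no k-space samples inside the center radius")
  if (any(tess@unbounded[C])) {
    stop("center cells are unbounded; cannot estimate the field of view")
  }
  if (perAxis) {
    D <- numeric(d)
    for (i in C) {
      off <- abs(sweep(tess@vertices[[i]], 2L, pts[i, ], `-`))
      D <- pmax(D, apply(off, 2L, max))
    }
    return(as.integer(floor(1 / (2 * D) + 1e-9)))
  }
  D <- 0
  for (i in C) {
    off <- abs(sweep(tess@vertices[[i]], 2L, pts[i, ], `-`))
    D <- max(D, max(off))
  }
  rep(as.integer(floor(1 / (2 * D) + 1e-9)), d)
}

#' Detect the autocalibration region
#'
#' Greedy whitelist/blacklist sweep over the Voronoi cells: samples are
#' visited in order of increasing k-space radius (ties broken
#' lexicographically). A sample is whitelisted when every vertex of its cell
#' is unblacklisted and within Chebyshev distance 1/(2 targetFov) (per axis)
#' of the sample. On a violation the offending vertices are blacklisted, and
#' a sample owning a blacklisted vertex is removed from candidacy; the
#' whitelisted region grows only through shared Voronoi vertices, so it can
#' never creep across an undersampled gap into a disconnected dense island.
#' The result is the largest center-connected set of k-space samples dense
#' enough for alias-free calibration images at the target field of view.
#'
#' Never raises on an inadequate pattern: an empty region (the caller must
#' then switch to the L1-regularized calibration fallback) is a valid result.
#'
#' @param tess \code{VoronoiTessellation}, or NULL when the trajectory was too
#'   small to tessellate (yields an empty region)
#' @param traj the matching \code{Trajectory}
#' @param targetFov requested grid size, scalar or one integer per axis
#' @return a \code{CalibrationRegion} (indices refer to original samples)
#' @export
detectCalibrationRegion <- function(tess, traj, targetFov) {
  d <- nDim(traj)
  targetFov <- as.integer(rep(targetFov, length.out = d))
  stopifnot(all(targetFov >= 1L))
  empty <- new("CalibrationRegion", indices = integer(0),
               achievedFov = rep(0L, d))
  if (is.null(tess) || nrow(tess@points) < d + 2L) return(empty)
  pts <- tess@points
  n <- nrow(pts)
  thr <- 1 / (2 * targetFov)

  # Per-cell vertex offsets and density verdicts.
  offs <- lapply(seq_len(n), function(i) {
    abs(sweep(tess@vertices[[i]], 2L, pts[i, ], `-`))
  })
  vertOk <- lapply(seq_len(n), function(i) {
    apply(sweep(offs[[i]], 2L, thr + 1e-12, `/`) <= 1, 1L, all)
  })

  # Shared-vertex identification across neighbouring cells.
  allV <- do.call(rbind, lapply(seq_len(n), function(i) tess@vertices[[i]]))
  counts <- vapply(tess@vertices, nrow, 1L)
  ids <- clusterPoints(allV)
  cellVerts <- split(ids, rep(seq_len(n), counts))

  ordc <- c(list(rowSums(pts^2)), lapply(seq_len(d), function(a) pts[, a]))
  ord <- do.call(order, ordc)

  black <- logical(max(ids))
  adjacent <- logical(max(ids))   # vertices touching the whitelisted region
  white <- logical(n)
  first <- TRUE
  for (i in ord) {
    vids <- cellVerts[[i]]
    ok <- vertOk[[i]]
    connected <- first || any(adjacent[vids])
    if (connected && !tess@unbounded[i] && all(ok) && !any(black[vids])) {
      white[i] <- TRUE
      adjacent[vids] <- TRUE
    } else {
      black[vids[!ok]] <- TRUE
    }
    first <- FALSE
  }

  if (!any(white)) return(empty)
  idx <- which(tess@mergedIndex %in% which(white))
  D <- numeric(d)
  for (i in which(white)) D <- pmax(D, apply(offs[[i]], 2L, max))
  new("CalibrationRegion", indices = sort(as.integer(idx)),
      achievedFov = as.integer(floor(1 / (2 * D) + 1e-9)))
}

#' Export per-sample density diagnostics as a data frame
#'
#' One row per sample: coordinates, k-space radius, maximum Chebyshev vertex
#' distance of its Voronoi cell, and membership of the calibration region.
#' Intended for CSV export and plotting of the detected region.
#'
#' @param tess \code{VoronoiTessellation}
#' @param traj matching \code{Trajectory}
#' @param region a \code{CalibrationRegion} for the same trajectory
#' @return data.frame with n_samples rows
#' @export
calibrationDiagnostics <- function(tess, traj, region) {
  k <- coords(traj)
  cell <- tess@mergedIndex
  cheb <- vapply(seq_len(nrow(tess@points)), function(i) {
    max(abs(sweep(tess@vertices[[i]], 2L, tess@points[i, ], `-`)))
  }, numeric(1))
  df <- data.frame(k)
  names(df) <- paste0("k", seq_len(ncol(k)))
  df$radius <- sqrt(rowSums(k^2))
  df$maxChebyshev <- cheb[cell]
  df$unbounded <- tess@unbounded[cell]
  df$inRegion <- seq_len(nrow(k)) %in% region@indices
  df
}
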