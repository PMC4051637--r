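#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib autopmri, .registration = TRUE
NULL

#' Trajectory: k-space sample coordinates
#'
#' A list of d-dimensional k-space sampling coordinates in normalized units:
#' the frequency axis is scaled so that the Nyquist bandwidth is the unit
#' bandwidth, i.e. every coordinate lies in \eqn{[-0.5, 0.5)} per axis and the
#' full Cartesian Nyquist grid for an N-pixel axis has spacing 1/N.
#'
#' @slot coords numeric matrix, n_samples x d (d in {2, 3}), finite, each value
#'   in \eqn{[-0.5, 0.5)}. Duplicate coordinates are permitted here; geometry
#'   operations merge them explicitly.
#' @export
setClass("Trajectory", representation(coords = "matrix"),
  validity = function(object) {
    k <- object@coords
    if (!is.numeric(k)) return("coords must be a numeric matrix")
    if (nrow(k) < 1L) return("trajectory needs at least one sample")
    if (!ncol(k) %in% c(2L, 3L)) return("trajectory dimension must be 2 or 3")
    if (!all(is.finite(k))) return("non-finite k-space coordinates")
    if (any(k < -0.5 | k >= 0.5)) {
      return("k-space coordinates must lie in [-0.5, 0.5) (normalized units); out-of-range coordinates are rejected, not wrapped")
    }
    TRUE
  })

#' @export
trajectory <- function(coords) {
  new("Trajectory", coords = as.matrix(coords))
}

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("nDim", function(x) standardGeneric("nDim"))
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setMethod("nSamples", "Trajectory", function(x) nrow(x@coords))
#' @export
setMethod("nDim", "Trajectory", function(x) ncol(x@coords))
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples in %dD k-space (normalized units)\n",
              nSamples(object), nDim(object)))
  r <- sqrt(rowSums(object@coords^2))
  cat(sprintf("  radial range [%.4f, %.4f]\n", min(r), max(r)))
})

#' KSpaceSamples: complex measurements aligned to a Trajectory
#'
#' Holds the measurement vector y of the acquisition model: one complex value
#' per k-space coordinate per receiver coil.
#'
#' @slot values complex matrix, n_samples x n_coils, all finite.
#' @export
setClass("KSpaceSamples", representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.complex(v)) return("values must be a complex matrix")
    if (ncol(v) < 1L) return("need at least one coil")
    if (!all(is.finite(Re(v))) || !all(is.finite(Im(v)))) return("non-finite sample values")
    TRUE
  })

#' @export
kspaceSamples <- function(values) {
  v <- as.matrix(values)
  storage.mode(v) <- "complex"
  new("KSpaceSamples", values = v)
}

#' @export
setGeneric("nCoils", function(x) standardGeneric("nCoils"))
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))
#' @export
setMethod("nCoils", "KSpaceSamples", function(x) ncol(x@values))
#' @export
setMethod("sampleValues", "KSpaceSamples", function(x) x@values)
#' @export
setMethod("nSamples", "KSpaceSamples", function(x) nrow(x@values))

setMethod("show", "KSpaceSamples", function(object) {
  cat(sprintf("KSpaceSamples: %d samples x %d coils\n",
              nrow(object@values), ncol(object@values)))
})

# Check that a samples object is aligned with a trajectory.
checkAligned <- function(traj, samples) {
  stopDim(nSamples(traj) == nSamples(samples),
          "trajectory and samples disagree on the number of k-space points")
  invisible(TRUE)
}

#' ImageGrid: complex image or volume on a regular grid
#'
#' @slot data complex array of shape (N_1, ..., N_d).
#' @slot fovPixels integer field of view per axis, in pixels (defaults to the
#'   grid shape); carried into NIfTI spacing metadata on output.
#' @export
setClass("ImageGrid", representation(data = "array", fovPixels = "integer"),
  validity = function(object) {
    if (length(dim(object@data)) < 2L) return("image must be at least 2D")
    if (any(dim(object@data) <= 0L)) return("grid shape must be strictly positive")
    if (length(object@fovPixels) != length(dim(object@data)))
      return("fovPixels must have one entry per axis")
    TRUE
  })

#' @export
imageGrid <- function(data, fovPixels = dim(data)) {
  data <- as.array(data)
  storage.mode(data) <- "complex"
  new("ImageGrid", data = data, fovPixels = as.integer(fovPixels))
}

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @export
setMethod("gridShape", "ImageGrid", function(x) dim(x@data))
#' @export
setGeneric("fovPixels", function(x) standardGeneric("fovPixels"))
#' @export
setMethod("fovPixels", "ImageGrid", function(x) x@fovPixels)

#' @export
setMethod("as.array", "ImageGrid", function(x, ...) x@data)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %s complex image, |range| [%.3g, %.3g]\n",
              paste(dim(object@data), collapse = "x"),
              min(Mod(object@data)), max(Mod(object@data))))
})

#' CoilProfiles: per-coil complex sensitivity maps
#'
#' The diagonal blocks S_c of the sensitivity operator: one complex map per
#' receiver coil on the image grid. After sum-of-squares normalization
#' (\code{\link{normalizeProfiles}}) the voxelwise sum over coils of
#' |map|^2 equals 1 wherever the combined magnitude is nonzero.
#'
#' @slot maps complex array of shape (N_1, ..., N_d, n_coils); the coil index
#'   is the last dimension.
#' @export
setClass("CoilProfiles", representation(maps = "array"),
  validity = function(object) {
    if (length(dim(object@maps)) < 3L) return("maps must be (grid dims, coil) array")
    TRUE
  })

#' @export
coilProfiles <- function(maps) {
  maps <- as.array(maps)
  storage.mode(maps) <- "complex"
  new("CoilProfiles", maps = maps)
}

#' @export
setMethod("nCoils", "CoilProfiles", function(x) dim(x@maps)[length(dim(x@maps))])
#' @export
setMethod("gridShape", "CoilProfiles", function(x) {
  d <- dim(x@maps); d[-length(d)]
})

#' Extract one coil map as a plain complex array.
#' @export
coilMap <- function(profiles, c) {
  d <- dim(profiles@maps)
  nd <- length(d) - 1L
  idx <- c(rep(list(quote(expr = )), nd), list(c))
  arr <- do.call(`[`, c(list(profiles@maps), idx, list(drop = FALSE)))
  array(arr, d[seq_len(nd)])
}

#' Voxelwise sum-of-squares magnitude of a profile set.
#' @export
sosMagnitude <- function(profiles) {
  d <- dim(profiles@maps)
  nd <- length(d) - 1L
  out <- array(0, d[seq_len(nd)])
  for (c in seq_len(d[length(d)])) out <- out + Mod(coilMap(profiles, c))^2
  sqrt(out)
}

setMethod("show", "CoilProfiles", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoilProfiles: %d coils on a %s grid\n",
              d[length(d)], paste(d[-length(d)], collapse = "x")))
})

#' ReconParams: estimated scalar parameters of the reconstruction
#'
#' Collects the automatically estimated scalars that drive the MAP estimator
#' and calibration: k-space noise standard deviation sigma, average foreground
#' gray level rho, the modality-independent relative signal constant s_rel,
#' the Laplacian prior scale beta = s_rel * rho, the calibration smoothness
#' weight mu, and the Tikhonov constant eps of the calibration-image solve.
#' @export
setClass("ReconParams",
  representation(sigma = "numeric", rho = "numeric", sRel = "numeric",
                 beta = "numeric", mu = "numeric", eps = "numeric"),
  prototype(sigma = 0, rho = 0, sRel = 0.02, beta = 0, mu = 0, eps = 1e-3),
  validity = function(object) {
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@rho < 0) return("rho must be >= 0")
    if (object@beta < 0) return("beta must be >= 0")
    if (object@mu < 0) return("mu must be >= 0")
    if (object@eps <= 0) return("eps must be > 0")
    TRUE
  })

#' @export
reconParams <- function(sigma = 0, rho = 0, sRel = 0.02, beta = sRel * rho,
                        mu = 0, eps = 1e-3) {
  new("ReconParams", sigma = sigma, rho = rho, sRel = sRel, beta = beta,
      mu = mu, eps = eps)
}

setMethod("show", "ReconParams", function(object) {
  cat(sprintf("ReconParams: sigma=%.4g rho=%.4g s_rel=%.3g beta=%.4g mu=%.4g eps=%.3g\n",
              object@sigma, object@rho, object@sRel, object@beta, object@mu,
              object@eps))
})

#' VoronoiTessellation of a k-space sampling pattern
#'
#' Per-sample Voronoi cell vertices of the (duplicate-merged) sampling
#' coordinates, plus a per-cell unbounded flag. Cells whose extent reaches the
#' working bounding box are flagged unbounded: their true cells extend to the
#' convex hull of the pattern and can never certify sampling density.
#'
#' @slot points merged coordinates (one row per cell)
#' @slot vertices list of matrices, one per cell (rows = Voronoi vertices)
#' @slot unbounded logical per cell
#' @slot mergedIndex integer mapping original sample index -> cell index
#' @export
setClass("VoronoiTessellation",
  representation(points = "matrix", vertices = "list", unbounded = "logical",
                 mergedIndex = "integer"))

setMethod("show", "VoronoiTessellation", function(object) {
  cat(sprintf("VoronoiTessellation: %d cells (%d unbounded) in %dD\n",
              nrow(object@points), sum(object@unbounded), ncol(object@points)))
})

#' CalibrationRegion: the autocalibration sample set
#'
#' The subset Omega of k-space samples dense enough (in the Chebyshev/Voronoi
#' sense) to form alias-free calibration images at the target field of view.
#'
#' @slot indices original sample indices belonging to Omega (unique, sorted)
#' @slot achievedFov integer per axis: the largest alias-free grid the region
#'   supports, 0 when the region is empty
#' @export
setClass("CalibrationRegion",
  representation(indices = "integer", achievedFov = "integer"))

setMethod("show", "CalibrationRegion", function(object) {
  cat(sprintf("CalibrationRegion: |Omega| = %d samples, achieved FOV %s\n",
              length(object@indices), paste(object@achievedFov, collapse = "x")))
})
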