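# Internal numerical helpers shared across modules.

# Centered integer axis for an N-sample grid: origin at floor(N/2).
centeredAxis <- function(n) seq_len(n) - 1L - floor(n / 2)

# d-dimensional array of centered coordinates along axis `axis`.
centeredCoordArray <- function(gridShape, axis) {
  ax <- centeredAxis(gridShape[axis])
  array(ax[slice.index(array(0, gridShape), axis)], gridShape)
}

# Radial (Euclidean) distance from the grid-center voxel, in voxel units.
gridRadius <- function(gridShape) {
  r2 <- array(0, gridShape)
  for (a in seq_along(gridShape)) r2 <- r2 + centeredCoordArray(gridShape, a)^2
  sqrt(r2)
}

complexL2 <- function(x) sqrt(sum(Mod(x)^2))

relErr <- function(x, ref) {
  nref <- complexL2(ref)
  if (nref == 0) return(complexL2(x))
  complexL2(x - ref) / nref
}

#' Peak signal-to-noise ratio
#'
#' PSNR of a reconstruction against a reference, in decibels:
#' \code{20*log10(max(|ref|) / rmse)} where the root-mean-square error is taken
#' over voxel magnitudes. This is the standard image-quality metric for
#' comparing MRI reconstructions against a known phantom.
#'
#' @param x reconstruction (complex or real array, or \code{ImageGrid})
#' @param ref reference image of the same shape
#' @return PSNR in dB (\code{Inf} for an exact match)
#' @export
psnr <- function(x, ref) {
  x <- as.array(x); ref <- as.array(ref)
  stopifnot(all(dim(x) == dim(ref)))
  err <- Mod(x) - Mod(ref)
  rmse <- sqrt(mean(err^2))
  if (rmse == 0) return(Inf)
  20 * log10(max(Mod(ref)) / rmse)
}

# Conjugate-gradient solve of a Hermitian positive-definite system A x = b,
# A supplied as a linear callback on complex vectors/arrays.
cgSolve <- function(applyA, b, x0 = NULL, tol = 1e-8, maxit = 200L) {
  x <- if (is.null(x0)) b * 0 else x0
  r <- b - applyA(x)
  p <- r
  rs <- sum(Mod(r)^2)
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(list(x = b * 0, iters = 0L, relres = 0))
  it <- 0L
  while (sqrt(rs) / bnorm > tol && it < maxit) {
    Ap <- applyA(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  relres <- sqrt(rs) / bnorm
  if (!is.finite(relres)) stop("conjugate gradient diverged (non-finite residual)")
  list(x = x, iters = it, relres = relres)
}

# Complex soft-thresholding (magnitude shrinkage), the prox of t*||.||_1.
softThreshold <- function(z, t) {
  m <- Mod(z)
  scale <- pmax(m - t, 0) / pmax(m, .Machine$double.eps)
  z * scale
}

# Project complex vector onto the L-infinity (magnitude) ball of radius r.
clampMagnitude <- function(z, r) {
  m <- Mod(z)
  over <- m > r
  if (any(over)) z[over] <- z[over] * (r / m[over])
  z
}

stopDim <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
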