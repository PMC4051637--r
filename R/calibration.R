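# Autocalibration: preliminary coil images from the calibration region
# (regularized least squares, with an L1-regularized failsafe when no usable
# region exists), sum-of-squares combination, and estimation of smooth
# high-bandwidth coil sensitivity profiles by a convex regularized fit.

#' Least-squares calibration images from the calibration region
#'
#' Per coil, solves the Tikhonov-regularized normal equations
#' (F^H F + eps I) x_c = F^H y_c on the calibration samples by conjugate
#' gradients. With a fully sampled Cartesian region and eps -> 0 this reduces
#' to the inverse FFT of the coil data.
#'
#' @param trajOmega \code{Trajectory} restricted to the calibration region
#' @param samplesOmega matching \code{KSpaceSamples}
#' @param gridShape reconstruction grid
#' @param eps Tikhonov constant; default 1e-3 times the mean diagonal of
#'   F^H F (which equals the number of calibration samples)
#' @param tol,maxit conjugate-gradient controls
#' @param op optional pre-built \code{NuftOperator}
#' @return list of per-coil \code{ImageGrid}
#' @export
reconstructCalibrationImages <- function(trajOmega, samplesOmega, gridShape,
                                         eps = NULL, tol = 1e-8, maxit = 200L,
                                         op = NULL) {
  checkAligned(trajOmega, samplesOmega)
  if (is.null(op)) op <- nuftOperator(trajOmega, gridShape)
  n <- nSamples(trajOmega)
  if (is.null(eps)) eps <- 1e-3 * n
  stopifnot(eps > 0)
  v <- sampleValues(samplesOmega)
  applyN <- function(x) nuftAdjoint(op, nuftForward(op, x))@data + eps * x
  lapply(seq_len(ncol(v)), function(c) {
    rhs <- nuftAdjoint(op, v[, c])@data
    sol <- cgSolve(applyN, rhs, tol = tol, maxit = maxit)
    imageGrid(sol$x)
  })
}

#' Sum-of-squares combination of coil images
#'
#' @param coilImages list of same-shape \code{ImageGrid} (or arrays)
#' @return real non-negative \code{ImageGrid}: voxelwise
#'   sqrt(sum_c |x_c|^2)
#' @export
sosCombine <- function(coilImages) {
  if (length(coilImages) == 0L) stop("empty coil image list")
  arrs <- lapply(coilImages, function(x) if (is(x, "ImageGrid")) x@data else as.array(x))
  sh <- dim(arrs[[1]])
  stopDim(all(vapply(arrs, function(a) all(dim(a) == sh), TRUE)),
          "coil images must share one shape")
  acc <- array(0, sh)
  for (a in arrs) acc <- acc + Mod(a)^2
  imageGrid(sqrt(acc))
}

#' L1-regularized failsafe calibration images
#'
#' When the detected calibration region cannot support alias-free coil
#' images at a usable resolution, per-coil images are instead recovered from
#' the full (sub-Nyquist) data by compressed-sensing reconstruction:
#' minimize ||W x_c||_1 subject to ||F x_c - y_c|| <= tau, with
#' tau = sigma * sqrt(2 n) the expected noise residual. Solved in penalized
#' form with continuation on the penalty weight until the constraint is met;
#' if the constraint is unattainable the best penalized solution is returned
#' with a warning.
#'
#' @param traj full \code{Trajectory}
#' @param samples full \code{KSpaceSamples}
#' @param gridShape reconstruction grid
#' @param sigma estimated k-space noise level (>= 0)
#' @param frame optional \code{SparsifyingFrame} (built if NULL)
#' @param maxit,tol inner solver controls
#' @param op optional pre-built \code{NuftOperator}
#' @return list of per-coil \code{ImageGrid}
#' @export
l1FallbackImages <- function(traj, samples, gridShape, sigma = 0,
                             frame = NULL, maxit = 500L, tol = 1e-5,
                             op = NULL) {
  checkAligned(traj, samples)
  if (is.null(op)) op <- nuftOperator(traj, gridShape)
  if (is.null(frame)) frame <- waveletFrame(gridShape)
  n <- nSamples(traj)
  tau <- sigma * sqrt(2 * n)
  v <- sampleValues(samples)
  applyA <- function(x) nuftForward(op, x)
  applyAh <- function(p) nuftAdjoint(op, p)@data
  normA <- estimateOperatorNorm(applyA, applyAh, gridShape)
  out <- vector("list", ncol(v))
  for (c in seq_len(ncol(v))) {
    y <- v[, c]
    if (complexL2(y) == 0) { out[[c]] <- imageGrid(array(0i, gridShape)); next }
    scale <- max(Mod(frameForward(frame, applyAh(y)))) / max(normA^2, 1)
    # Continuation: start with a strongly sparsity-promoting weight and relax
    # it towards the datafit constraint, warm-starting every solve.
    lambda <- 0.05 * scale
    x0 <- NULL
    if (tau == 0) {
      for (outer in 1:6) {
        sol <- pdhgSolve(applyA, applyAh, frame, y, sigma = 1,
                         beta = 1 / lambda, gridShape = gridShape, x0 = x0,
                         maxit = maxit, tol = tol, normA = normA)
        x0 <- sol$x
        lambda <- lambda / 10
      }
    } else {
      for (outer in 1:8) {
        sol <- pdhgSolve(applyA, applyAh, frame, y, sigma = 1,
                         beta = 1 / lambda, gridShape = gridShape, x0 = x0,
                         maxit = maxit, tol = tol, normA = normA)
        x0 <- sol$x
        if (sol$residual > 1.05 * tau) {
          lambda <- lambda / 3
        } else if (sol$residual < 0.5 * tau) {
          lambda <- lambda * 2
        } else break
      }
    }
    if (tau > 0 && sol$residual > 1.05 * tau && lambda < 1e-12 * scale) {
      warning("datafit constraint unattainable; returning penalized solution")
    }
    out[[c]] <- imageGrid(sol$x)
  }
  out
}

# Neumann discrete Laplacian: adjoint-of-gradient of forward differences
# with N-1 taps per axis (constants are in the null space). Differences are
# taken per unit of (FOV-relative) distance, so on anisotropic grids a
# coarsely sampled axis is not over-penalized: axis weight (N_a / max N)^2.
gradSquared <- function(x) {
  d <- length(dim(x))
  N <- dim(x)
  wAx <- (N / max(N))^2
  out <- array(0i, N)
  for (a in seq_len(d)) {
    perm <- c(a, seq_len(d)[-a])
    xa <- aperm(x, perm)
    sh <- dim(xa)
    m <- matrix(xa, sh[1])
    g <- m[-1, , drop = FALSE] - m[-sh[1], , drop = FALSE]
    lap <- matrix(0i, sh[1], ncol(m))
    lap[-sh[1], ] <- lap[-sh[1], , drop = FALSE] - g
    lap[-1, ] <- lap[-1, , drop = FALSE] + g
    out <- out + wAx[a] * aperm(array(lap, sh), order(perm))
  }
  out
}

#' Estimate smooth high-bandwidth coil sensitivity profiles
#'
#' The calibration fit: per coil, minimize over the complex sensitivity map s
#'
#'   || F_Omega diag(xhat) s - y_c ||^2 + mu ||grad s||^2
#'
#' where xhat is the preliminary sum-of-squares image and grad the forward
#' finite-differences operator per axis. Smoothness is enforced softly by mu,
#' not by truncating the map's bandwidth: the estimated profiles are smooth
#' but not band-limited, matching the physics of a receive antenna. Solved by
#' conjugate gradients on the normal equations.
#'
#' @param prelim preliminary (sum-of-squares) \code{ImageGrid}, real
#' @param trajOmega calibration \code{Trajectory}
#' @param samplesOmega calibration \code{KSpaceSamples}
#' @param mu smoothness weight (>= 0); see \code{\link{selectMuLcurve}}
#' @param tol,maxit conjugate-gradient controls
#' @param op optional pre-built \code{NuftOperator}
#' @param warmStart optional \code{CoilProfiles} initial iterate
#' @return \code{CoilProfiles} (not sum-of-squares normalized)
#' @export
estimateCoilProfiles <- function(prelim, trajOmega, samplesOmega, mu,
                                 tol = 1e-8, maxit = 200L, op = NULL,
                                 warmStart = NULL) {
  checkAligned(trajOmega, samplesOmega)
  D <- Re(if (is(prelim, "ImageGrid")) prelim@data else as.array(prelim))
  if (max(abs(D)) == 0) stop("preliminary image is identically zero")
  stopifnot(mu >= 0)
  if (is.null(op)) op <- nuftOperator(trajOmega, dim(D))
  v <- sampleValues(samplesOmega)
  applyN <- function(s) {
    D * nuftAdjoint(op, nuftForward(op, D * s))@data + mu * gradSquared(s)
  }
  maps <- array(0i, c(dim(D), ncol(v)))
  idx <- rep(list(quote(expr = )), length(dim(D)))
  for (c in seq_len(ncol(v))) {
    rhs <- D * nuftAdjoint(op, v[, c])@data
    x0 <- if (!is.null(warmStart)) coilMap(warmStart, c) else NULL
    sol <- cgSolve(applyN, rhs, x0 = x0, tol = tol, maxit = maxit)
    maps <- do.call(`[<-`, c(list(maps), idx, list(c), list(sol$x)))
  }
  coilProfiles(maps)
}

#' Select the calibration smoothness weight by a noise-anchored L-curve
#'
#' Sweeps mu over a geometric grid (continuation: each solve warm-starts from
#' the previous), recording the datafit residual and the smoothness
#' seminorm. The selected mu is the largest weight whose residual stays
#' within a factor 2 of the noise-predicted level 2 sigma^2 |Omega| n_coils
#' (or of the attainable residual floor, whichever is larger): maximal
#' smoothing that does not degrade the datafit beyond what the noise already
#' imposes. With sigma = 0 and consistent data the selection degenerates to
#' the smallest mu on the grid.
#'
#' @param prelim preliminary sum-of-squares \code{ImageGrid}
#' @param trajOmega,samplesOmega calibration data
#' @param sigma estimated noise level (>= 0)
#' @param nMu grid length (default 16)
#' @param cgTol,cgMaxit inner conjugate-gradient controls (looser than the
#'   final fit; selection only needs the residual trend)
#' @param op optional pre-built \code{NuftOperator}
#' @param sweepCoils optional coil subset used for the sweep (the corner
#'   location is essentially coil-invariant; a single coil is much cheaper)
#' @return selected mu, with attributes \code{"muGrid"}, \code{"residuals"}
#' @export
selectMuLcurve <- function(prelim, trajOmega, samplesOmega, sigma,
                           nMu = 12L, cgTol = 1e-5, cgMaxit = 80L, op = NULL,
                           sweepCoils = NULL) {
  stopifnot(sigma >= 0)
  D <- Re(if (is(prelim, "ImageGrid")) prelim@data else as.array(prelim))
  if (is.null(op)) op <- nuftOperator(trajOmega, dim(D))
  n <- nSamples(trajOmega)
  v <- sampleValues(samplesOmega)
  if (!is.null(sweepCoils)) {
    # The corner location is essentially coil-invariant (coils share the
    # geometry that sets the smoothness scale); sweeping a subset is cheaper.
    v <- v[, sweepCoils, drop = FALSE]
    samplesOmega <- kspaceSamples(v)
  }
  muScale <- n * mean(D^2) / (2 * length(dim(D)))
  muGrid <- muScale * 10^seq(-3, 4, length.out = nMu)
  res <- numeric(nMu)
  reg <- numeric(nMu)
  warm <- NULL
  for (i in seq_along(muGrid)) {
    prof <- estimateCoilProfiles(prelim, trajOmega, samplesOmega, muGrid[i],
                                 tol = cgTol, maxit = cgMaxit, op = op,
                                 warmStart = warm)
    warm <- prof
    r2 <- 0; g2 <- 0
    for (c in seq_len(ncol(v))) {
      s <- coilMap(prof, c)
      r2 <- r2 + sum(Mod(nuftForward(op, D * s) - v[, c])^2)
      g2 <- g2 + Re(sum(Conj(s) * gradSquared(s)))
    }
    res[i] <- r2; reg[i] <- g2
  }
  target <- 2 * sigma^2 * n * ncol(v)
  # Noise-anchored corner: the largest weight whose residual stays within a
  # factor 2 of the larger of the noise-predicted level and the attainable
  # floor. Maximizes smoothness without fitting the calibration data worse
  # than the noise allows; degenerates to the smallest weight when sigma = 0
  # and the data are consistent.
  bound <- 2 * max(target, min(res))
  pick <- if (target == 0) 1L else max(which(res <= bound))
  # The residual must grow with mu (up to inner-solver wiggle).
  monotone <- all(diff(res) >= -0.03 * (abs(res[-nMu]) + 1e-300))
  if (!monotone) {
    warning("non-monotone residual curve in the mu sweep; corner selection may be unreliable")
  }
  mu <- muGrid[pick]
  attr(mu, "muGrid") <- muGrid
  attr(mu, "residuals") <- res
  attr(mu, "regNorms") <- reg
  mu
}

#' Sum-of-squares normalization of coil profiles
#'
#' Divides every coil map voxelwise by the combined sum-of-squares magnitude
#' on the support (voxels where the sos exceeds 1e-8 of its maximum); voxels
#' off the support are set to 0. The result satisfies
#' sum_c |s_c|^2 = 1 on the support, resolving the inherent global scale
#' ambiguity between the image and the profiles.
#'
#' @param profiles \code{CoilProfiles}
#' @param tol relative support threshold (default 1e-8)
#' @return normalized \code{CoilProfiles}
#' @export
normalizeProfiles <- function(profiles, tol = 1e-8) {
  sos <- sosMagnitude(profiles)
  mx <- max(sos)
  if (mx == 0) stop("all-zero coil profiles cannot be normalized")
  support <- sos > tol * mx
  maps <- profiles@maps
  nc <- nCoils(profiles)
  idx <- rep(list(quote(expr = )), length(dim(sos)))
  for (c in seq_len(nc)) {
    m <- coilMap(profiles, c)
    m[support] <- m[support] / sos[support]
    m[!support] <- 0
    maps <- do.call(`[<-`, c(list(maps), idx, list(c), list(m)))
  }
  coilProfiles(maps)
}
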