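# Automatic estimation of the noise level sigma and the signal level rho,
# replacing manual tuning of the regularization strength.

#' NoiseEstimate: robust k-space noise level
#'
#' @slot sigma estimated noise standard deviation per quadrature component
#' @slot nPointsUsed number of k-space samples in the high-frequency subset
#' @slot radialThreshold the 95 percent fractile of the sample radii
#' @export
setClass("NoiseEstimate",
  representation(sigma = "numeric", nPointsUsed = "integer",
                 radialThreshold = "numeric"))

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: sigma = %.5g (MAD on %d outer samples, |k| >= %.4f)\n",
              object@sigma, object@nPointsUsed, object@radialThreshold))
})

#' SignalEstimate: foreground gray level from a mixture fit
#'
#' @slot rho mean of the foreground (higher-mean) Gaussian component
#' @slot backgroundMean mean of the background component
#' @slot mixtureWeights the two component weights (sum to 1)
#' @export
setClass("SignalEstimate",
  representation(rho = "numeric", backgroundMean = "numeric",
                 mixtureWeights = "numeric"),
  validity = function(object) {
    if (object@rho < object@backgroundMean)
      return("foreground mean must be >= background mean")
    TRUE
  })

setMethod("show", "SignalEstimate", function(object) {
  cat(sprintf("SignalEstimate: rho = %.5g (background %.5g, weights %.2f/%.2f)\n",
              object@rho, object@backgroundMean,
              object@mixtureWeights[1], object@mixtureWeights[2]))
})

#' Estimate the k-space noise level by robust MAD
#'
#' MRI noise is white complex Gaussian on the k-space samples, while the
#' signal energy concentrates at low spatial frequencies. The estimator
#' therefore pools the real and imaginary parts of the 5 percent of samples
#' with the highest radial frequency (across all coils) and applies the
#' median-absolute-deviation scale estimate, sigma = MAD / 0.6745, so that
#' any sparse high-frequency signal content is rejected as outliers.
#'
#' @param traj \code{Trajectory}
#' @param samples matching \code{KSpaceSamples}
#' @return a \code{NoiseEstimate}
#' @export
estimateNoiseSigma <- function(traj, samples) {
  checkAligned(traj, samples)
  n <- nSamples(traj)
  if (n < 40L) stop("need at least 40 samples for a meaningful 5% subset")
  radii <- sqrt(rowSums(coords(traj)^2))
  thr <- stats::quantile(radii, 0.95, names = FALSE)
  sel <- radii >= thr
  if (sum(sel) < 2L) stop("fewer than 2 samples beyond the 95% fractile radius")
  v <- sampleValues(samples)[sel, , drop = FALSE]
  pooled <- c(Re(v), Im(v))
  sigma <- stats::median(abs(pooled - stats::median(pooled))) / 0.6745
  new("NoiseEstimate", sigma = sigma, nPointsUsed = sum(sel),
      radialThreshold = thr)
}

# Two-component Gaussian mixture fit by EM with fixed, deterministic
# initialization (means at the 10th/90th intensity percentiles).
fitTwoGaussians <- function(x, maxit = 500L, tol = 1e-8) {
  mu <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  if (diff(mu) <= 0 || stats::sd(x) == 0) {
    stop("degenerate intensity distribution: cannot fit a two-class mixture")
  }
  s <- rep(max(stats::sd(x) / 2, 1e-12), 2)
  w <- c(0.5, 0.5)
  ll <- -Inf
  for (it in seq_len(maxit)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    g <- d1 / tot
    llNew <- sum(log(tot))
    w1 <- mean(g); w2 <- 1 - w1
    if (w1 < 1e-9 || w2 < 1e-9) {
      stop("mixture collapsed to a single component")
    }
    mu1 <- sum(g * x) / sum(g)
    mu2 <- sum((1 - g) * x) / sum(1 - g)
    s1 <- sqrt(sum(g * (x - mu1)^2) / sum(g))
    s2 <- sqrt(sum((1 - g) * (x - mu2)^2) / sum(1 - g))
    mu <- c(mu1, mu2); s <- pmax(c(s1, s2), 1e-12); w <- c(w1, w2)
    if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(ll) + 1)) {
      ll <- llNew
      # Background is the lower-mean component, by definition.
      o <- order(mu)
      return(list(mu = mu[o], sd = s[o], w = w[o], loglik = ll, iters = it))
    }
    ll <- llNew
  }
  stop("EM for the intensity mixture did not converge within ", maxit,
       " iterations (loglik ", signif(ll, 6), ")")
}

#' Estimate the signal level from a crude reconstruction
#'
#' Fits a two-component Gaussian mixture to the voxel intensities of a crude
#' (sum-of-squares, possibly aliased) magnitude reconstruction. The component
#' with the lower mean captures the background; the mean of the other
#' component is the average foreground gray level rho that scales the
#' Laplacian prior.
#'
#' @param crudeImg non-negative magnitude \code{ImageGrid} (or array)
#' @return a \code{SignalEstimate}
#' @export
estimateSignalLevel <- function(crudeImg) {
  x <- if (is(crudeImg, "ImageGrid")) crudeImg@data else as.array(crudeImg)
  x <- as.vector(Re(x))
  if (any(x < -1e-9)) stop("expected a non-negative magnitude image")
  fit <- fitTwoGaussians(x)
  new("SignalEstimate", rho = fit$mu[2], backgroundMean = fit$mu[1],
      mixtureWeights = fit$w)
}

#' Laplacian prior scale from the signal level
#'
#' The prior scale is modeled as beta = s_rel * rho: MRI images share a
#' modality-independent relative contrast s_rel, so the only image-dependent
#' factor is the average foreground gray level rho. Doubling the image
#' intensities doubles beta.
#'
#' @param signal a \code{SignalEstimate}
#' @param sRel relative signal constant (> 0), default 0.02
#' @return beta (numeric scalar)
#' @export
computeBeta <- function(signal, sRel = 0.02) {
  stopifnot(sRel > 0)
  rho <- if (is(signal, "SignalEstimate")) signal@rho else as.numeric(signal)
  sRel * rho
}
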