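# Final image estimator: sparsity-regularized, noise-aware SENSE-like
# reconstruction with known or estimated coil sensitivity profiles.

#' ReconProblem: everything the MAP estimator needs
#'
#' Aggregates the acquisition (trajectory and samples), the coil sensitivity
#' profiles, the estimated scalar parameters, and solver settings for the
#' MAP objective
#'   1/(2 sigma^2) ||F S x - y||^2 + (1/beta) ||W x||_1 .
#'
#' @slot trajectory \code{Trajectory}
#' @slot samples \code{KSpaceSamples}
#' @slot profiles \code{CoilProfiles}
#' @slot params \code{ReconParams} (sigma and beta are the ones that matter)
#' @slot settings list: maxit, tol, accuracy, levels
#' @export
setClass("ReconProblem",
  representation(trajectory = "Trajectory", samples = "KSpaceSamples",
                 profiles = "CoilProfiles", params = "ReconParams",
                 settings = "list"))

#' @export
reconProblem <- function(traj, samples, profiles, params,
                         maxit = 300L, tol = 1e-6, accuracy = 1e-5,
                         levels = 3L) {
  checkAligned(traj, samples)
  stopDim(nCoils(samples) == nCoils(profiles),
          "samples and profiles disagree on the coil count")
  new("ReconProblem", trajectory = traj, samples = samples,
      profiles = profiles, params = params,
      settings = list(maxit = as.integer(maxit), tol = tol,
                      accuracy = accuracy, levels = as.integer(levels)))
}

setMethod("show", "ReconProblem", function(object) {
  cat(sprintf("ReconProblem: %d samples, %d coils, grid %s\n",
              nSamples(object@trajectory), nCoils(object@samples),
              paste(gridShape(object@profiles), collapse = "x")))
  show(object@params)
})

#' Solve the sparsity-regularized MAP reconstruction
#'
#' Minimizes 1/(2 sigma^2) ||F S x - y||^2 + (1/beta) ||W x||_1 by an
#' operator-splitting scheme (frame-coefficient splitting with warm-started
#' conjugate-gradient inner solves, exact handling of the nonsmooth
#' L1-of-frame term), run until the relative change of the best objective
#' stalls below \code{tol} or \code{maxit} iterations. The iterate with the
#' lowest objective is returned; the reported objective trace is
#' non-increasing.
#'
#' @param problem a \code{ReconProblem}
#' @return \code{ImageGrid} with attributes \code{"objective"},
#'   \code{"trace"} (best-so-far objective values), \code{"iters"}
#' @export
solveRecon <- function(problem) {
  traj <- problem@trajectory
  prof <- problem@profiles
  gs <- gridShape(prof)
  op <- nuftOperator(traj, gs, accuracy = problem@settings$accuracy)
  frame <- waveletFrame(gs, levels = problem@settings$levels)
  y <- as.vector(sampleValues(problem@samples))
  nc <- nCoils(prof)
  applyA <- function(x) as.vector(sampleValues(coilForward(op, prof, x)))
  applyAh <- function(p) coilAdjoint(op, prof, matrix(p, ncol = nc))
  sigma <- problem@params@sigma
  beta <- problem@params@beta
  stopifnot(beta > 0)
  sol <- admmSolve(applyA, applyAh, frame, y, sigma = sigma, beta = beta,
                   gridShape = gs, maxit = problem@settings$maxit,
                   tol = problem@settings$tol)
  out <- imageGrid(sol$x)
  attr(out, "objective") <- sol$objective
  attr(out, "trace") <- sol$traceBest
  attr(out, "iters") <- sol$iters
  out
}

#' Adjoint / least-squares sum-of-squares baseline reconstruction
#'
#' Per-coil Tikhonov-regularized least-squares NUFT images combined by sum
#' of squares. This is both the classical non-iterative baseline and the
#' crude image feeding the signal-level estimator (its aliasing is high-pass
#' only, since the k-space center is always densely sampled).
#'
#' @param traj \code{Trajectory}
#' @param samples \code{KSpaceSamples}
#' @param gridShape reconstruction grid
#' @param eps,tol,maxit see \code{\link{reconstructCalibrationImages}}
#' @param op optional pre-built operator
#' @return real non-negative \code{ImageGrid}
#' @export
adjointSosRecon <- function(traj, samples, gridShape, eps = NULL,
                            tol = 1e-8, maxit = 200L, op = NULL) {
  imgs <- reconstructCalibrationImages(traj, samples, gridShape, eps = eps,
                                       tol = tol, maxit = maxit, op = op)
  sosCombine(imgs)
}
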