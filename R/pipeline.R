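# End-to-end automatic reconstruction: orchestrates the full flow from raw
# k-space samples to the reconstructed image, with every parameter estimated
# from the data unless explicitly overridden.

stageRun <- function(report, name, expr) {
  t0 <- Sys.time()
  val <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  report$timings[[name]] <- as.numeric(Sys.time() - t0, units = "secs")
  list(report = report, value = val)
}

#' Run the automatic reconstruction pipeline
#'
#' Executes, in order: read/validate input, field-of-view estimation (unless
#' overridden), noise-level estimation, calibration-region detection,
#' calibration images (dense least-squares, or the L1-regularized failsafe
#' when no usable region exists), sum-of-squares combination, coil-profile
#' estimation with L-curve selection of the smoothness weight,
#' sum-of-squares normalization, crude baseline reconstruction, signal-level
#' estimation, and the final sparsity-regularized MAP reconstruction.
#' Supplying known coil profiles (SENSE mode) skips all autocalibration
#' stages. The run is fully deterministic for a fixed configuration.
#'
#' @param input path to a k-space container (see \code{\link{readKSpace}}) or
#'   a list with elements \code{trajectory} and \code{samples}
#' @param grid optional grid-size override (integer per axis); estimated from
#'   the sampling density when NULL
#' @param profiles optional known \code{CoilProfiles} (SENSE mode)
#' @param sRel relative signal constant for the prior scale (default 0.02)
#' @param centerRadius fully sampled k-space core radius for FOV estimation
#' @param minCalibRes minimum calibration resolution, in pixels, below which
#'   the L1 failsafe is used instead of dense least squares (default 4)
#' @param sigmaOverride,betaOverride,muOverride optional manual values
#'   replacing the corresponding automatic estimates
#' @param maxit,tol final solver controls
#' @param seed recorded in the report (the pipeline itself is deterministic)
#' @param output optional NIfTI output path for the reconstruction
#' @param reportPath optional JSON path for the machine-readable run report
#' @return list with \code{image} (\code{ImageGrid}), \code{report} (list),
#'   \code{profiles}, \code{crude} (baseline sos image), \code{params}
#' @export
runPipeline <- function(input, grid = NULL, profiles = NULL, sRel = 0.02,
                        centerRadius = 0.05, minCalibRes = 4L,
                        sigmaOverride = NULL, betaOverride = NULL,
                        muOverride = NULL, maxit = 100L, tol = 1e-6,
                        seed = 1L, output = NULL, reportPath = NULL) {
  report <- list(seed = seed, timings = list(), stages = character(0))
  note <- function(s) report$stages <<- c(report$stages, s)

  if (is.character(input)) input <- readKSpace(input)
  traj <- input$trajectory
  samples <- input$samples
  checkAligned(traj, samples)
  d <- nDim(traj)

  tess <- NULL
  needTess <- is.null(grid) || is.null(profiles)
  if (needTess && nSamples(traj) >= d + 2L) {
    st <- stageRun(report, "tessellate", voronoiTessellate(traj))
    report <- st$report; tess <- st$value
    note("tessellate")
  }

  if (is.null(grid)) {
    st <- stageRun(report, "estimate_fov",
                   estimateFov(tess, traj, centerRadius = centerRadius))
    report <- st$report; grid <- st$value
    note("estimate_fov")
  } else {
    grid <- as.integer(rep(grid, length.out = d))
    note("fov_override")
  }
  report$grid <- as.integer(grid)

  st <- stageRun(report, "estimate_noise", estimateNoiseSigma(traj, samples))
  report <- st$report; noise <- st$value
  note("estimate_noise")
  sigma <- if (is.null(sigmaOverride)) noise@sigma else sigmaOverride
  report$sigma <- sigma
  report$sigmaEstimated <- noise@sigma
  report$noisePointsUsed <- noise@nPointsUsed

  mu <- NA_real_
  if (is.null(profiles)) {
    st <- stageRun(report, "detect_calibration_region",
                   detectCalibrationRegion(tess, traj, grid))
    report <- st$report; region <- st$value
    note("detect_calibration_region")
    report$omegaSize <- length(region@indices)
    report$omegaFraction <- length(region@indices) / nSamples(traj)
    report$achievedFov <- region@achievedFov

    k <- coords(traj)
    calibRes <- if (length(region@indices) > 0L) {
      kk <- abs(k[region@indices, , drop = FALSE])
      floor(2 * apply(kk, 2L, max) * grid)
    } else rep(0L, d)
    report$calibResolution <- as.integer(calibRes)
    denseMode <- length(region@indices) >= 2L * d + 2L &&
      all(calibRes >= pmin(minCalibRes, grid))
    report$mode <- if (denseMode) "dense-LS" else "L1-fallback"

    if (denseMode) {
      trajC <- trajectory(k[region@indices, , drop = FALSE])
      sampC <- kspaceSamples(sampleValues(samples)[region@indices, , drop = FALSE])
      st <- stageRun(report, "calibration_images",
                     reconstructCalibrationImages(trajC, sampC, grid,
                                                  tol = 1e-6, maxit = 120L))
      report <- st$report; coilImgs <- st$value
      note("calibration_images_LS")
    } else {
      trajC <- traj; sampC <- samples
      st <- stageRun(report, "calibration_images_l1",
                     l1FallbackImages(traj, samples, grid, sigma = sigma))
      report <- st$report; coilImgs <- st$value
      note("calibration_images_L1")
    }
    prelim <- sosCombine(coilImgs)

    opC <- nuftOperator(trajC, grid)
    if (is.null(muOverride)) {
      st <- stageRun(report, "select_mu",
                     selectMuLcurve(prelim, trajC, sampC, sigma, op = opC,
                                    sweepCoils = 1L))
      report <- st$report; mu <- as.numeric(st$value)
      note("select_mu")
    } else {
      mu <- muOverride
      note("mu_override")
    }
    st <- stageRun(report, "estimate_profiles",
                   estimateCoilProfiles(prelim, trajC, sampC, mu, op = opC,
                                        tol = 5e-7, maxit = 150L))
    report <- st$report
    profiles <- normalizeProfiles(st$value)
    note("estimate_profiles")
  } else {
    report$mode <- "SENSE"
    note("sense_profiles_supplied (autocalibration skipped)")
  }
  report$mu <- mu

  st <- stageRun(report, "adjoint_sos",
                 adjointSosRecon(traj, samples, grid, tol = 1e-6, maxit = 60L))
  report <- st$report; crude <- st$value
  note("adjoint_sos")

  st <- stageRun(report, "estimate_signal", estimateSignalLevel(crude))
  report <- st$report; signal <- st$value
  note("estimate_signal")
  report$rho <- signal@rho
  beta <- if (is.null(betaOverride)) computeBeta(signal, sRel) else betaOverride
  report$beta <- beta
  report$sRel <- sRel

  params <- reconParams(sigma = sigma, rho = signal@rho, sRel = sRel,
                        beta = beta, mu = if (is.na(mu)) 0 else mu,
                        eps = 1e-3 * nSamples(traj))
  problem <- reconProblem(traj, samples, profiles, params,
                          maxit = maxit, tol = tol)
  st <- stageRun(report, "solve_recon", solveRecon(problem))
  report <- st$report; image <- st$value
  note("solve_recon")
  report$iterations <- attr(image, "iters")
  report$objective <- attr(image, "objective")
  report$objectiveTrace <- attr(image, "trace")

  if (!is.null(output)) {
    stageRun(report, "write_image", writeImage(image, output))
    note("write_image")
  }
  if (!is.null(reportPath)) {
    jsonlite::write_json(report, reportPath, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  list(image = image, report = report, profiles = profiles, crude = crude,
       params = params)
}
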