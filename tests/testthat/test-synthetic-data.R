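test_that("phantom generation matches the analytic membership oracle", {
  N <- c(24L, 24L)
  es <- data.frame(cx = 0.05, cy = -0.1, ax = 0.2, ay = 0.12, angle = 0.5,
                   intensity = 1)
  ph <- as.array(generatePhantom(phantomSpec(N, es)))
  U <- expand.grid(x = (seq_len(24) - 1 - 12) / 24, y = (seq_len(24) - 1 - 12) / 24)
  xr <- cos(0.5) * (U$x - 0.05) + sin(0.5) * (U$y + 0.1)
  yr <- -sin(0.5) * (U$x - 0.05) + cos(0.5) * (U$y + 0.1)
  member <- (xr / 0.2)^2 + (yr / 0.12)^2 <= 1
  expect_identical(as.vector(Re(ph) == 1), as.vector(member))
  # empty ellipse list gives the zero image; determinism is bit-exact
  e0 <- es[0, ]
  expect_true(all(as.array(generatePhantom(phantomSpec(N, e0))) == 0))
  expect_identical(as.array(generatePhantom(phantomSpec(N))),
                   as.array(generatePhantom(phantomSpec(N))))
  # default phantom: non-negative with an exact-zero background
  d <- Re(as.array(generatePhantom(phantomSpec(N))))
  expect_gte(min(d), 0)
  expect_true(any(d == 0))
})

test_that("coil profile generator produces unit sum-of-squares smooth maps", {
  pr <- generateCoilProfiles(c(32L, 32L), 8L, seed = 2)
  expect_lt(max(abs(sosMagnitude(pr) - 1)), 1e-10)
  one <- generateCoilProfiles(c(16L, 16L), 1L, seed = 2)
  expect_lt(max(abs(Mod(coilMap(one, 1)) - 1)), 1e-10)
  # magnitude along a ray follows 1/(r+a) up to the sos normalization
  a <- 0.15
  pr2 <- generateCoilProfiles(c(64L, 64L), 4L, a = a, seed = 3)
  m <- Mod(coilMap(pr2, 1))
  sos <- local({
    U <- lapply(1:2, function(ax) (slice.index(array(0, c(64, 64)), ax) - 1 - 32) / 64)
    set.seed(3)
    phi0 <- runif(1, 0, 2 * pi)
    mags <- lapply(0:3, function(ci) {
      ctr <- 0.75 * c(cos(phi0 + 2 * pi * ci / 4), sin(phi0 + 2 * pi * ci / 4))
      1 / (sqrt((U[[1]] - ctr[1])^2 + (U[[2]] - ctr[2])^2) + a)
    })
    ref <- mags[[1]] / sqrt(Reduce(`+`, lapply(mags, function(x) x^2)))
    ref
  })
  expect_lt(max(abs(m - sos)), 1e-8)
})

test_that("Cartesian trajectory generators count and place lines correctly", {
  tr <- generateTrajectory(trajectorySpec("cartesian_full", N = 32L))
  expect_equal(nSamples(tr), 1024L)
  expect_true(all(coords(tr) %in% (((0:31) - 16) / 32)))
  ts <- trajectorySpec("cartesian_phase_undersampled", N = 32L, keep = 0.5,
                       centerFraction = 0.125)
  tu <- generateTrajectory(ts)
  lines <- sort(unique(round(coords(tu)[, 2] * 32)))
  expect_length(lines, 16L)
  expect_true(all(c(-2L, -1L, 0L, 1L) %in% lines))   # contiguous center
  expect_error(trajectorySpec("cartesian_phase_undersampled", N = 32L,
                              keep = 0.3, centerFraction = 0.5), "fraction")
})

test_that("dense spirals are detected as calibration-capable almost everywhere", {
  N <- 16L
  tr <- generateTrajectory(trajectorySpec("archimedean_spiral", N = N,
                                          multiplier = 0.9, azimuthal = 0.4))
  tess <- voronoiTessellate(tr)
  reg <- detectCalibrationRegion(tess, tr, N)
  r <- sqrt(rowSums(coords(tr)^2))
  inner <- which(r < 0.4)   # away from the domain-corner boundary effects
  expect_gte(mean(inner %in% reg@indices), 0.95)
})

test_that("trajectory generators respect the coordinate range invariant", {
  for (spec in list(trajectorySpec("archimedean_spiral", N = 24L, multiplier = 2,
                                   azimuthal = 1.6),
                    trajectorySpec("radial_stack_3d", N = 12L, nz = 4L,
                                   spokes = 8L, seed = 2))) {
    k <- coords(generateTrajectory(spec))
    expect_true(all(k >= -0.5 & k < 0.5))
  }
})

test_that("simulated acquisitions are exact when noiseless and seeded when noisy", {
  set.seed(37)
  N <- c(16L, 16L)
  ph <- generatePhantom(phantomSpec(N))
  pr <- generateCoilProfiles(N, 2L, seed = 4)
  k <- matrix(runif(60, -0.5, 0.4999), 30, 2)
  tr <- trajectory(k)
  op <- nuftOperator(tr, N)
  y0 <- simulateAcquisition(ph, pr, tr, sigma = 0)
  expect_identical(sampleValues(y0),
                   sampleValues(coilForward(op, pr, as.array(ph))))
  y1 <- simulateAcquisition(ph, pr, tr, sigma = 0.5, seed = 42)
  y2 <- simulateAcquisition(ph, pr, tr, sigma = 0.5, seed = 42)
  expect_identical(sampleValues(y1), sampleValues(y2))
  expect_false(identical(sampleValues(y1), sampleValues(y0)))
})

test_that("simulated noise has the requested per-component variance", {
  n <- 120000L
  k <- matrix(runif(2 * n, -0.5, 0.4999), n, 2)
  tr <- trajectory(k)
  z <- imageGrid(array(0i, c(4, 4)))
  pr <- coilProfiles(array(1 + 0i, c(4, 4, 1)))
  y <- simulateAcquisition(z, pr, tr, sigma = 1, seed = 3)
  v <- sampleValues(y)
  expect_lt(abs(var(Re(v[, 1])) - 1), 0.02)
  expect_lt(abs(var(Im(v[, 1])) - 1), 0.02)
})

test_that("experiment presets exist for every study design", {
  for (nm in c("cartesian_full", "spiral_af_sweep", "grappa_noise",
               "phase_undersampled_34", "spiral_25_nocal", "radial_stack_3d")) {
    ps <- presetSpec(nm, N = 16L)
    tr <- generateTrajectory(ps$trajSpec)
    expect_s4_class(tr, "Trajectory")
    expect_gte(ps$nCoils, 1L)
    expect_length(ps$grid, nDim(tr))
  }
  # the no-calibration spiral really is ~25% Nyquist with no dense core
  ps <- presetSpec("spiral_25_nocal", N = 32L)
  tr <- generateTrajectory(ps$trajSpec)
  expect_lt(nSamples(tr) / 32^2, 0.32)
  reg <- detectCalibrationRegion(voronoiTessellate(tr), tr, 32L)
  expect_lt(length(reg@indices), 0.01 * nSamples(tr))
})
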