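test_that("interior Cartesian Voronoi cells are exact squares", {
  h <- 1 / 8
  g <- as.matrix(expand.grid((-2:2) * h, (-2:2) * h))
  tr <- trajectory(g)
  tess <- voronoiTessellate(tr)
  i <- tess@mergedIndex[which(g[, 1] == 0 & g[, 2] == 0)]
  V <- sortRows(tess@vertices[[i]])
  expect_equal(nrow(V), 4L)
  expect_equal(max(abs(abs(V) - h / 2)), 0, tolerance = 1e-12)
})

test_that("cell vertices match the circumcenter-enumeration oracle", {
  set.seed(9)
  pts <- matrix(runif(12, -0.3, 0.3), 6, 2)
  tess <- voronoiTessellate(trajectory(pts))
  for (i in 1:6) {
    ref <- voronoiVertexOracle2d(pts, i)
    got <- tess@vertices[[i]]
    expect_equal(nrow(got), nrow(ref))
    expect_lt(max(abs(sortRows(got) - sortRows(ref))), 1e-9)
  }
})

test_that("duplicate coordinates are merged with a warning", {
  pts <- rbind(matrix(runif(12, -0.3, 0.3), 6, 2), c(0, 0), c(0, 0))
  expect_warning(tess <- voronoiTessellate(trajectory(pts)), "merged")
  expect_equal(nrow(tess@points), 7L)
  expect_equal(tess@mergedIndex[7], tess@mergedIndex[8])
})

test_that("degenerate geometries are rejected", {
  line <- cbind(seq(-0.4, 0.4, length.out = 8), 0.1 * seq(-0.4, 0.4, length.out = 8))
  expect_error(voronoiTessellate(trajectory(line)), "collinear|coplanar|degenerate")
  expect_error(voronoiTessellate(trajectory(matrix(c(0, 0, 0.1, 0.1), 2, 2))),
               "at least")
})

test_that("FOV estimation is exact on Nyquist Cartesian grids", {
  for (N in c(16L, 32L)) {
    tr <- fullCartesianTraj(N)
    tess <- voronoiTessellate(tr)
    expect_identical(estimateFov(tess, tr), rep(N, 2L))
  }
})

test_that("halving line density halves the per-axis FOV estimate", {
  N <- 32L
  tr <- fullCartesianTraj(N)
  k <- coords(tr)
  keep <- (round(k[, 2] * N) %% 2) == 0
  tr2 <- trajectory(k[keep, ])
  tess2 <- voronoiTessellate(tr2)
  expect_identical(estimateFov(tess2, tr2, perAxis = TRUE), c(32L, 16L))
})

test_that("jittered Cartesian FOV estimate matches direct recomputation", {
  set.seed(10)
  N <- 32L
  k <- coords(fullCartesianTraj(N))
  k <- k + matrix(runif(length(k), -0.1 / N, 0.1 / N), nrow(k))
  k <- pmin(pmax(k, -0.5), 0.5 - 1e-9)
  tr <- trajectory(k)
  tess <- voronoiTessellate(tr)
  C <- which(sqrt(rowSums(tess@points^2)) <= 0.05)
  D <- max(vapply(C, function(i) {
    max(abs(sweep(tess@vertices[[i]], 2, tess@points[i, ], `-`)))
  }, 1))
  expect_identical(estimateFov(tess, tr),
                   rep(as.integer(floor(1 / (2 * D) + 1e-9)), 2L))
})

test_that("FOV estimation reports failure when the center is empty", {
  ring <- cbind(0.3 * cos(seq(0, 2 * pi, length.out = 13)[-13]),
                0.3 * sin(seq(0, 2 * pi, length.out = 13)[-13]))
  tr <- trajectory(ring)
  tess <- voronoiTessellate(tr)
  expect_error(estimateFov(tess, tr, centerRadius = 0.05), "center")
})

test_that("calibration region is everything on a Nyquist grid and empty in degenerate cases", {
  N <- 16L
  tr <- fullCartesianTraj(N)
  tess <- voronoiTessellate(tr)
  reg <- detectCalibrationRegion(tess, tr, N)
  expect_identical(reg@indices, seq_len(N * N))
  expect_identical(reg@achievedFov, c(N, N))
  # a single sample cannot be tessellated: empty region, no error
  single <- trajectory(matrix(c(0, 0), 1, 2))
  expect_length(detectCalibrationRegion(NULL, single, N)@indices, 0L)
})

test_that("dual-density spiral detection agrees with the density oracle", {
  N <- 24L
  tr <- generateTrajectory(trajectorySpec("archimedean_spiral", N = N,
                                          multiplier = 0.9, azimuthal = 0.4,
                                          outerMultiplier = 4, r0 = 0.25))
  tess <- voronoiTessellate(tr)
  reg <- detectCalibrationRegion(tess, tr, N)
  r <- sqrt(rowSums(coords(tr)^2))
  inner <- which(r < 0.25 - 1 / N)
  expect_true(all(inner %in% reg@indices))
  expect_length(intersect(reg@indices, which(r > 0.25 + 4 / N)), 0L)
  oracle <- densityOracle(tess, tr, N)
  agree <- mean(oracle == (seq_len(nSamples(tr)) %in% reg@indices))
  expect_gte(agree, 0.99)
})

test_that("calibration region shrinks monotonically with the target FOV", {
  N <- 24L
  tr <- generateTrajectory(trajectorySpec("archimedean_spiral", N = N,
                                          multiplier = 0.9, azimuthal = 0.4,
                                          outerMultiplier = 4, r0 = 0.25))
  tess <- voronoiTessellate(tr)
  prev <- NULL
  for (f in c(12L, 16L, 24L, 32L)) {
    idx <- detectCalibrationRegion(tess, tr, f)@indices
    if (!is.null(prev)) expect_true(all(idx %in% prev))
    prev <- idx
  }
})

test_that("detection is invariant to input sample ordering", {
  set.seed(11)
  N <- 16L
  tr <- generateTrajectory(trajectorySpec("archimedean_spiral", N = N,
                                          multiplier = 0.9, azimuthal = 0.4))
  k <- coords(tr)
  perm <- sample(nrow(k))
  reg1 <- detectCalibrationRegion(voronoiTessellate(tr), tr, N)
  tr2 <- trajectory(k[perm, ])
  reg2 <- detectCalibrationRegion(voronoiTessellate(tr2), tr2, N)
  expect_identical(sort(perm[reg2@indices]), reg1@indices)
})

test_that("3D stack detection matches 2D behaviour axis-wise", {
  # identical 2D pattern stacked at Nyquist kz spacing: per-slice result
  # equals the 2D result, and the z axis passes at its own Nyquist target
  N <- 12L; nz <- 4L
  ax <- (seq_len(N) - 1 - floor(N / 2)) / N
  g2 <- as.matrix(expand.grid(ax, ax))
  tr2 <- trajectory(g2)
  reg2 <- detectCalibrationRegion(voronoiTessellate(tr2), tr2, N)
  kz <- (seq_len(nz) - 1 - floor(nz / 2)) / nz
  g3 <- do.call(rbind, lapply(kz, function(z) cbind(g2, z)))
  tr3 <- trajectory(g3)
  reg3 <- detectCalibrationRegion(voronoiTessellate(tr3), tr3, c(N, N, nz))
  expect_identical(length(reg3@indices), nz * length(reg2@indices))
  expect_identical(reg3@achievedFov, c(N, N, nz))
})

test_that("density diagnostics table labels the region consistently", {
  N <- 16L
  tr <- fullCartesianTraj(N)
  tess <- voronoiTessellate(tr)
  reg <- detectCalibrationRegion(tess, tr, N)
  df <- calibrationDiagnostics(tess, tr, reg)
  expect_equal(nrow(df), N * N)
  expect_true(all(df$inRegion))
  expect_equal(max(abs(df$maxChebyshev - 1 / (2 * N))), 0, tolerance = 1e-12)
})
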