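test_that("calibration images reduce to the inverse FFT on a full Cartesian region", {
  set.seed(19)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  ph <- generatePhantom(phantomSpec(N))
  pr <- generateCoilProfiles(N, 2L, seed = 5)
  y <- simulateAcquisition(ph, pr, tr, sigma = 0)
  imgs <- reconstructCalibrationImages(tr, y, N, eps = 1e-9)
  for (c in 1:2) {
    expect_lt(relErrC(as.array(imgs[[c]]), coilMap(pr, c) * as.array(ph)), 1e-5)
  }
})

test_that("calibration CG matches a dense direct solve of the normal equations", {
  set.seed(20)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  sel <- sort(sample(256, 154))   # random 60% of the grid
  trS <- trajectory(coords(tr)[sel, ])
  v <- matrix(complex(real = rnorm(154), imaginary = rnorm(154)), 154, 1)
  yS <- kspaceSamples(v)
  got <- reconstructCalibrationImages(trS, yS, N, eps = 1e-3,
                                      tol = 1e-10, maxit = 500)
  E <- exp(-2i * pi * (coords(trS) %*%
         t(as.matrix(expand.grid(-8:7, -8:7)))))
  A <- Conj(t(E)) %*% E + diag(1e-3, 256)
  ref <- solve(A, as.vector(Conj(t(E)) %*% v))
  expect_lt(relErrC(as.vector(as.array(got[[1]])), ref), 1e-6)
})

test_that("a dominant Tikhonov term shrinks the calibration image", {
  set.seed(21)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  v <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 256, 1)
  img <- reconstructCalibrationImages(tr, kspaceSamples(v), N, eps = 1e6)
  op <- nuftOperator(tr, N)
  rhs <- as.array(nuftAdjoint(op, v[, 1]))
  expect_lt(sqrt(sum(Mod(as.array(img[[1]]))^2)),
            1e-4 * sqrt(sum(Mod(rhs)^2)))
})

test_that("sum-of-squares combination is correct and strict about inputs", {
  expect_error(sosCombine(list()), "empty")
  x <- array(3 + 0i, c(2, 2)); z <- array(0 + 4i, c(2, 2))
  expect_equal(as.array(sosCombine(list(x, z))), array(5 + 0i, c(2, 2)))
  expect_equal(as.array(sosCombine(list(imageGrid(-2i * x)))),
               array(6 + 0i, c(2, 2)))
  # sos-normalized profiles applied to a phantom recombine to its magnitude
  set.seed(22)
  N <- c(16L, 16L)
  pr <- generateCoilProfiles(N, 8L, seed = 7)
  ph <- generatePhantom(phantomSpec(N))
  imgs <- lapply(1:8, function(c) coilMap(pr, c) * as.array(ph))
  expect_lt(max(abs(Re(as.array(sosCombine(imgs))) - Mod(as.array(ph)))), 1e-10)
})

test_that("L1 fallback recovers the inverse FFT limit and zero data", {
  set.seed(23)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  ph <- generatePhantom(phantomSpec(N))
  pr1 <- coilProfiles(array(1 + 0i, c(16, 16, 1)))
  y <- simulateAcquisition(ph, pr1, tr, sigma = 0)
  out <- l1FallbackImages(tr, y, N, sigma = 0)
  expect_lt(relErrC(as.array(out[[1]]), as.array(ph)), 1e-4)
  z <- l1FallbackImages(tr, kspaceSamples(matrix(0i, 256, 1)), N, sigma = 0)
  expect_true(all(as.array(z[[1]]) == 0))
})

test_that("L1 fallback beats adjoint reconstruction on undersampled variable-density data", {
  set.seed(24)
  N <- c(32L, 32L)
  es <- data.frame(cx = c(0, 0.1, -0.12), cy = c(0, -0.05, 0.1),
                   ax = c(0.35, 0.12, 0.08), ay = c(0.3, 0.1, 0.1),
                   angle = c(0, 0.4, 0), intensity = c(1, 0.5, 0.4))
  ph <- generatePhantom(phantomSpec(N, es))
  k <- coords(fullCartesianTraj(32L))
  r <- sqrt(rowSums(k^2))
  sel <- runif(1024) < pmin(1, 0.1 / (r + 0.02))   # ~25-30%, center-weighted
  tr <- trajectory(k[sel, ])
  pr1 <- coilProfiles(array(1 + 0i, c(32, 32, 1)))
  y <- simulateAcquisition(ph, pr1, tr, sigma = 0)
  out <- l1FallbackImages(tr, y, N, sigma = 0, maxit = 400)
  errL1 <- relErrC(as.array(out[[1]]), as.array(ph))
  op <- nuftOperator(tr, N)
  adj <- as.array(nuftAdjoint(op, sampleValues(y)[, 1]))
  a <- sum(Conj(adj) * as.array(ph)) / sum(Mod(adj)^2)   # best-scaled adjoint
  errAdj <- relErrC(a * adj, as.array(ph))
  expect_lt(errL1, 0.10)
  expect_gt(errAdj, 2 * errL1)
})

test_that("profile estimation recovers a constant profile and the smooth limit", {
  set.seed(25)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  ph <- generatePhantom(phantomSpec(N))
  pr1 <- coilProfiles(array(1 + 0i, c(16, 16, 1)))
  y <- simulateAcquisition(ph, pr1, tr, sigma = 0)
  est <- estimateCoilProfiles(imageGrid(Mod(as.array(ph))), tr, y, mu = 1e-6)
  supp <- Mod(as.array(ph)) > 0
  expect_lt(max(Mod(coilMap(est, 1) - 1)[supp]), 1e-4)
  # smoothness-dominated limit: spatially (near) constant map
  big <- estimateCoilProfiles(imageGrid(Mod(as.array(ph))), tr, y,
                              mu = 1e8 * 256 * mean(Mod(as.array(ph))^2))
  s <- Mod(coilMap(big, 1))
  expect_lt(sd(s) / mean(s), 1e-3)
  expect_error(estimateCoilProfiles(imageGrid(array(0, N)), tr, y, 1), "zero")
})

test_that("profile estimation CG matches a dense solve of the convex fit", {
  set.seed(26)
  N <- c(12L, 12L)
  tr <- fullCartesianTraj(12L)
  ph <- generatePhantom(phantomSpec(N))
  D <- Mod(as.array(ph)) + 0.1      # keep the fit well-conditioned everywhere
  v <- matrix(complex(real = rnorm(144), imaginary = rnorm(144)), 144, 1)
  mu <- 0.5
  got <- estimateCoilProfiles(imageGrid(D), tr, kspaceSamples(v), mu,
                              tol = 1e-12, maxit = 1000)
  # dense operator assembled column by column from the same normal equations
  applyN <- function(s) {
    op <- nuftOperator(tr, N, method = "direct")
    D * as.array(nuftAdjoint(op, nuftForward(op, D * s))) +
      mu * autopmri:::gradSquared(s)
  }
  M <- matrix(0i, 144, 144)
  for (j in 1:144) {
    e <- array(0i, N); e[j] <- 1
    M[, j] <- as.vector(applyN(e))
  }
  op <- nuftOperator(tr, N, method = "direct")
  rhs <- as.vector(D * as.array(nuftAdjoint(op, v[, 1])))
  ref <- solve(M, rhs)
  expect_lt(relErrC(as.vector(coilMap(got, 1)), ref), 1e-6)
})

test_that("smooth synthetic coil profiles are recovered within tolerance", {
  set.seed(27)
  N <- c(64L, 64L)
  ph <- generatePhantom(phantomSpec(N, psfSigma = 1.5))
  pr <- generateCoilProfiles(N, 8L, seed = 3)
  tr <- fullCartesianTraj(64L)
  peak <- max(Mod(as.array(ph)))
  y <- simulateAcquisition(ph, pr, tr, sigma = 0.01 * peak, seed = 11)
  op <- nuftOperator(tr, N)
  prelim <- sosCombine(reconstructCalibrationImages(tr, y, N, op = op))
  mu <- selectMuLcurve(prelim, tr, y, sigma = 0.01 * peak, op = op,
                       sweepCoils = 1L)
  prof <- normalizeProfiles(estimateCoilProfiles(prelim, tr, y,
                                                 as.numeric(mu), op = op))
  supp <- Mod(as.array(ph)) > 0.05 * peak
  rmse <- sqrt(mean(vapply(1:8, function(c) {
    mean(Mod(coilMap(prof, c) - coilMap(pr, c))[supp]^2)
  }, 1)))
  expect_lt(rmse, 0.05)
})

test_that("mu selection degenerates to the smallest weight for noiseless data", {
  set.seed(28)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  ph <- generatePhantom(phantomSpec(N))
  pr <- generateCoilProfiles(N, 2L, seed = 9)
  y <- simulateAcquisition(ph, pr, tr, sigma = 0)
  prelim <- sosCombine(reconstructCalibrationImages(tr, y, N, eps = 1e-9))
  mu <- selectMuLcurve(prelim, tr, y, sigma = 0)
  expect_equal(as.numeric(mu), min(attr(mu, "muGrid")))
  # residuals grow with mu (up to solver wiggle)
  res <- attr(mu, "residuals")
  expect_true(all(diff(res) >= -0.03 * abs(res[-length(res)])))
})

test_that("sos normalization produces unit combined magnitude and is idempotent", {
  set.seed(29)
  maps <- array(complex(real = rnorm(4 * 64), imaginary = rnorm(4 * 64)),
                c(8, 8, 4))
  pr <- normalizeProfiles(coilProfiles(maps))
  expect_lt(max(abs(sosMagnitude(pr) - 1)), 1e-10)
  pr2 <- normalizeProfiles(pr)
  expect_lt(max(Mod(pr2@maps - pr@maps)), 1e-12)
  one <- normalizeProfiles(coilProfiles(array(2 + 0i, c(4, 4, 1))))
  expect_lt(max(abs(Mod(coilMap(one, 1)) - 1)), 1e-12)
  expect_error(normalizeProfiles(coilProfiles(array(0i, c(4, 4, 2)))), "zero")
})

test_that("the global image/profile scale ambiguity is resolved by normalization", {
  set.seed(30)
  N <- c(16L, 16L)
  tr <- fullCartesianTraj(16L)
  ph <- generatePhantom(phantomSpec(N))
  pr <- generateCoilProfiles(N, 4L, seed = 13)
  y <- simulateAcquisition(ph, pr, tr, sigma = 0)
  prelim <- imageGrid(Mod(as.array(ph)))
  p1 <- normalizeProfiles(estimateCoilProfiles(prelim, tr, y, mu = 1e-3))
  p2 <- normalizeProfiles(estimateCoilProfiles(imageGrid(3 * Mod(as.array(ph))),
                                               tr, y, mu = 1e-3 / 9))
  supp <- Mod(as.array(ph)) > 0.05 * max(Mod(as.array(ph)))
  for (c in 1:4) {
    expect_lt(max(Mod(coilMap(p1, c) - coilMap(p2, c))[supp]), 1e-4)
  }
})

test_that("estimated profiles keep energy outside a truncated k-space block", {
  set.seed(31)
  N <- c(32L, 32L)
  pr <- generateCoilProfiles(N, 4L, seed = 17)
  for (c in 1:2) {
    S <- centeredFft(coilMap(pr, c))
    block <- matrix(FALSE, 32, 32); block[14:20, 14:20] <- TRUE  # central 7x7
    outside <- sum(Mod(S[!block])^2)
    expect_gt(outside, 1e-6 * sum(Mod(S)^2))
    # truncating to the block loses real energy: the profile is not 7x7-bandlimited
    St <- S; St[!block] <- 0
    trunc <- centeredFft(array(St, dim(S)), inverse = TRUE) / prod(N)
    expect_gt(sqrt(mean(Mod(trunc - coilMap(pr, c))^2)), 1e-3)
  }
})
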