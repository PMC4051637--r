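# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own fast paths: the DFT oracle is a double loop over
# grid voxels, the Voronoi oracle enumerates circumcenters of point triples,
# and the density oracle re-derives cell extents sample by sample.

# Direct DFT: s_i = sum_r x(r) exp(-2 pi i k_i . r), centered grid.
dftOracle <- function(k, x) {
  N <- dim(x)
  axes <- lapply(N, function(n) seq_len(n) - 1 - floor(n / 2))
  R <- as.matrix(expand.grid(axes))
  s <- complex(nrow(k))
  xv <- as.vector(x)
  for (i in seq_len(nrow(k))) {
    s[i] <- sum(xv * exp(-2i * pi * as.vector(R %*% k[i, ])))
  }
  s
}

dftAdjointOracle <- function(k, y, N) {
  axes <- lapply(N, function(n) seq_len(n) - 1 - floor(n / 2))
  R <- as.matrix(expand.grid(axes))
  x <- complex(nrow(R))
  for (i in seq_len(nrow(k))) {
    x <- x + y[i] * exp(2i * pi * as.vector(R %*% k[i, ]))
  }
  array(x, N)
}

# Voronoi vertices of 2D points on the periodic unit cell, by circumcenter
# enumeration: a point is a Voronoi vertex iff it is equidistant from >= 3
# sites and no site is closer. Returns the vertex set of the cell of site i
# (of the unpadded set).
voronoiVertexOracle2d <- function(pts, i, tol = 1e-9) {
  offs <- as.matrix(expand.grid(c(-1, 0, 1), c(-1, 0, 1)))
  all <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o) {
    sweep(pts, 2, as.numeric(offs[o, ]), `+`)
  }))
  owner <- rep(seq_len(nrow(pts)), nrow(offs))
  n <- nrow(all)
  verts <- NULL
  combs <- utils::combn(n, 3)
  for (c in seq_len(ncol(combs))) {
    tri <- all[combs[, c], ]
    # circumcenter via perpendicular bisector intersection
    A <- 2 * rbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (abs(det(A)) < 1e-14) next
    b <- c(sum(tri[2, ]^2) - sum(tri[1, ]^2), sum(tri[3, ]^2) - sum(tri[1, ]^2))
    ctr <- solve(A, b)
    r2 <- sum((tri[1, ] - ctr)^2)
    d2 <- colSums((t(all) - ctr)^2)
    if (min(d2) < r2 - tol) next          # some site strictly closer
    # vertex of the base copy's cell iff the base copy itself is nearest
    if (sum((pts[i, ] - ctr)^2) <= r2 + tol) verts <- rbind(verts, ctr)
  }
  if (is.null(verts)) return(matrix(numeric(0), 0, 2))
  # dedupe
  keep <- rep(TRUE, nrow(verts))
  for (a in seq_len(nrow(verts) - 1)) {
    if (!keep[a]) next
    for (b in (a + 1):nrow(verts)) {
      if (max(abs(verts[a, ] - verts[b, ])) < 1e-7) keep[b] <- FALSE
    }
  }
  verts[keep, , drop = FALSE]
}

# Sort vertex rows for comparison.
sortRows <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]

relErrC <- function(x, ref) {
  nr <- sqrt(sum(Mod(ref)^2))
  if (nr == 0) return(sqrt(sum(Mod(x)^2)))
  sqrt(sum(Mod(x - ref)^2)) / nr
}

fullCartesianTraj <- function(N, d = 2L) {
  ax <- (seq_len(N) - 1 - floor(N / 2)) / N
  trajectory(as.matrix(expand.grid(rep(list(ax), d))))
}

randomComplexArray <- function(N) {
  array(complex(real = rnorm(prod(N)), imaginary = rnorm(prod(N))), N)
}

# Centered 2D FFT matching the package's phase convention.
centeredFft <- function(x, inverse = FALSE) {
  N <- dim(x)
  sh <- lapply(N, function(n) {
    c((floor(n / 2) + 1):n, 1:floor(n / 2))
  })
  unshift <- function(v) do.call(`[`, c(list(v), sh))
  unshift(fft(unshift(x), inverse = inverse))
}

# Per-sample Chebyshev density verdict straight from the tessellation.
densityOracle <- function(tess, traj, targetFov) {
  d <- ncol(tess@points)
  thr <- 1 / (2 * rep(targetFov, length.out = d))
  pass <- vapply(seq_len(nrow(tess@points)), function(i) {
    off <- abs(sweep(tess@vertices[[i]], 2, tess@points[i, ], `-`))
    all(apply(sweep(off, 2, thr + 1e-12, `/`), 1, max) <= 1) && !tess@unbounded[i]
  }, TRUE)
  pass[tess@mergedIndex]
}
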