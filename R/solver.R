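# Convex solvers for the sparsity-regularized MAP objective
#
#   J(x) = 1/(2 sigma^2) ||A x - y||^2 + (1/beta) ||W x||_1
#
# with A the (multi-coil) NUFT forward model and W a Parseval frame.
# Two engines share the objective:
#  * admmSolve - variable splitting w = Wx with warm-started conjugate-
#    gradient inner solves; the inner linear algebra absorbs the 1/sigma^2
#    stiffness of the datafit, so convergence does not degrade at low noise.
#    This is the engine behind solveRecon.
#  * pdhgSolve - a Chambolle-Pock primal-dual iteration on the whitened
#    operator; matrix-free with the cheapest per-iteration cost, used for
#    the milder penalized subproblems of the L1 calibration fallback.
# Both return the best-objective iterate, so the reported objective trace is
# non-increasing by construction.

estimateOperatorNorm <- function(applyA, applyAh, gridShape, iters = 20L) {
  # Deterministic power iteration on A^H A.
  v <- array(complex(real = 1, imaginary = 0.1), gridShape)
  v <- v + 1e-3 * array(seq_len(prod(gridShape)), gridShape) / prod(gridShape)
  lam <- 1
  for (i in seq_len(iters)) {
    w <- applyAh(applyA(v))
    lam <- complexL2(w) / complexL2(v)
    v <- w / complexL2(w)
  }
  sqrt(lam)
}

pdhgSolve <- function(applyA, applyAh, frame, y, sigma, beta, gridShape,
                      x0 = NULL, maxit = 300L, tol = 1e-6, normA = NULL,
                      objWindow = 10L, gamma = 1) {
  if (sigma <= 0) {
    warning("sigma <= 0 supplied to the MAP solver; flooring at 1e-12")
    sigma <- 1e-12
  }
  stopifnot(beta > 0)
  if (is.null(normA)) normA <- estimateOperatorNorm(applyA, applyAh, gridShape)
  # Work with the noise-whitened operator A/sigma: the quadratic dual block
  # is then 1-strongly damped and the step sizes are well balanced. The
  # objective below is algebraically identical to the unscaled MAP objective.
  ys <- y / sigma
  L <- sqrt((normA / sigma)^2 + 1)   # ||[A/sigma; W]||, W is Parseval
  tau <- 0.95 * gamma / L
  sdu <- 0.95 / (gamma * L)
  x <- if (is.null(x0)) array(0i, gridShape) else x0
  Ax <- applyA(x) / sigma; Wx <- frameForward(frame, x)
  AxPrev <- Ax; WxPrev <- Wx
  p <- ys * 0i; q <- Wx * 0i
  objective <- function(Axc, Wxc) {
    sum(Mod(Axc - ys)^2) / 2 + sum(Mod(Wxc)) / beta
  }
  obj <- objective(Ax, Wx)
  best <- list(x = x, obj = obj)
  traceRaw <- obj
  traceBest <- obj
  for (it in seq_len(maxit)) {
    Axbar <- 2 * Ax - AxPrev
    Wxbar <- 2 * Wx - WxPrev
    p <- (p + sdu * (Axbar - ys)) / (1 + sdu)
    q <- clampMagnitude(q + sdu * Wxbar, 1 / beta)
    xNew <- x - tau * (applyAh(p) / sigma + frameAdjoint(frame, q))
    AxPrev <- Ax; WxPrev <- Wx
    x <- xNew
    Ax <- applyA(x) / sigma; Wx <- frameForward(frame, x)
    obj <- objective(Ax, Wx)
    if (!is.finite(obj)) stop("non-finite objective in the MAP solver")
    if (obj < best$obj) best <- list(x = x, obj = obj)
    traceRaw <- c(traceRaw, obj)
    traceBest <- c(traceBest, best$obj)
    # Primal-dual iterates plateau transiently; stop only once the best
    # objective has been flat over a window scaled to the iteration budget.
    W <- max(objWindow, maxit %/% 20L)
    n <- length(traceBest)
    if (it > 5L * W && n > W) {
      if (abs(traceBest[n - W] - traceBest[n]) <=
            tol * (abs(traceBest[n]) + 1e-300)) break
    }
  }
  # `objective` is computed in the whitened parametrization and equals
  # 1/(2 sigma^2)||Ax-y||^2 + (1/beta)||Wx||_1 identically.
  list(x = best$x, objective = best$obj, iters = it,
       traceBest = traceBest, traceRaw = traceRaw,
       residual = sqrt(sum(Mod(applyA(best$x) - y)^2)))
}

admmSolve <- function(applyA, applyAh, frame, y, sigma, beta, gridShape,
                      x0 = NULL, maxit = 300L, tol = 1e-6, normA = NULL,
                      rho = NULL, innerTol = 1e-6, innerMaxit = 15L) {
  if (sigma <= 0) {
    warning("sigma <= 0 supplied to the MAP solver; flooring at 1e-12")
    sigma <- 1e-12
  }
  stopifnot(beta > 0)
  if (is.null(normA)) normA <- estimateOperatorNorm(applyA, applyAh, gridShape)
  ys <- y / sigma
  Lf <- (normA / sigma)^2
  if (is.null(rho)) rho <- max(Lf / 20, 1e-12)
  Aty <- applyAh(ys) / sigma
  x <- if (is.null(x0)) array(0i, gridShape) else x0
  Wx <- frameForward(frame, x)
  w <- Wx; u <- Wx * 0
  objective <- function(Axc, Wxc) sum(Mod(Axc - ys)^2) / 2 + sum(Mod(Wxc)) / beta
  Ax <- applyA(x) / sigma
  obj <- objective(Ax, Wx)
  best <- list(x = x, obj = obj)
  traceBest <- obj; traceRaw <- obj
  for (it in seq_len(maxit)) {
    rhs <- Aty + rho * frameAdjoint(frame, w - u)
    sol <- cgSolve(function(z) applyAh(applyA(z)) / sigma^2 + rho * z,
                   rhs, x0 = x, tol = innerTol, maxit = innerMaxit)
    x <- sol$x
    Wx <- frameForward(frame, x)
    w_old <- w
    w <- softThreshold(Wx + u, 1 / (beta * rho))
    u <- u + Wx - w
    Ax <- applyA(x) / sigma
    obj <- objective(Ax, Wx)
    if (!is.finite(obj)) stop("non-finite objective in the MAP solver")
    if (obj < best$obj) best <- list(x = x, obj = obj)
    traceRaw <- c(traceRaw, obj)
    traceBest <- c(traceBest, best$obj)
    # Residual balancing keeps the splitting penalty in a productive range.
    rp <- complexL2(Wx - w)
    rd <- rho * complexL2(frameAdjoint(frame, w - w_old))
    if (rp > 10 * rd) {
      rho <- rho * 2; u <- u / 2
    } else if (rd > 10 * rp) {
      rho <- rho / 2; u <- u * 2
    }
    # Stall detection: the best objective must be flat over a window AND the
    # splitting constraint must be met (plateaus during penalty rebalancing
    # are not convergence).
    W <- max(25L, maxit %/% 10L)
    n <- length(traceBest)
    if (it > 3L * W && n > W && rp <= 1e-3 * (complexL2(Wx) + 1e-300)) {
      if (abs(traceBest[n - W] - traceBest[n]) <=
            tol * (abs(traceBest[n]) + 1e-300)) break
    }
  }
  list(x = best$x, objective = best$obj, iters = it,
       traceBest = traceBest, traceRaw = traceRaw,
       residual = sqrt(sum(Mod(applyA(best$x) - y)^2)))
}
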