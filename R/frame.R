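# Sparsifying Parseval frame: an undecimated (stationary) separable Haar
# wavelet frame, implemented through per-subband FFT transfer functions.
#
# At level l the orthonormal Haar pair is upsampled a trous and scaled by
# 1/sqrt(2) per axis application, which makes the per-axis transfer functions
# satisfy |H|^2 + |G|^2 = 1 pointwise. The telescoping product over levels
# then gives sum_b |T_b|^2 = 1 exactly: W is a Parseval tight frame, so
# ||Wx|| = ||x|| and the synthesis operator W^H is a left inverse
# (W^H W = Identity). Piecewise-constant images have detail coefficients
# supported only on edges, matching the Laplacian marginal model of the
# reconstruction prior.

#' SparsifyingFrame: undecimated wavelet Parseval frame
#'
#' @slot gridShape image grid shape the frame is built for
#' @slot levels number of decomposition levels
#' @slot transfers list of complex per-subband transfer-function arrays
#'   (the approximation band last); their squared magnitudes sum to 1
#' @export
setClass("SparsifyingFrame",
  representation(gridShape = "integer", levels = "integer",
                 transfers = "list"))

setMethod("show", "SparsifyingFrame", function(object) {
  cat(sprintf("SparsifyingFrame: undecimated Haar, %d levels, %d subbands on %s\n",
              object@levels, length(object@transfers),
              paste(object@gridShape, collapse = "x")))
})

#' Build the undecimated Haar Parseval frame for a grid
#'
#' @param gridShape integer grid shape (2D or 3D)
#' @param levels decomposition levels (default 3)
#' @return a \code{SparsifyingFrame}
#' @export
waveletFrame <- function(gridShape, levels = 3L) {
  N <- as.integer(gridShape)
  d <- length(N)
  omega <- lapply(N, function(n) 2 * pi * (seq_len(n) - 1L) / n)
  expandAxis <- function(vals, a) array(vals[slice.index(array(0L, N), a)], N)
  transfers <- list()
  approx <- array(1 + 0i, N)
  for (l in seq_len(levels)) {
    sh <- 2^(l - 1)
    H <- lapply(seq_len(d), function(a) (1 + exp(-1i * sh * omega[[a]])) / 2)
    G <- lapply(seq_len(d), function(a) (1 - exp(-1i * sh * omega[[a]])) / 2)
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    for (r in seq_len(nrow(combos))) {
      if (!any(combos[r, ])) next  # all-lowpass continues to the next level
      Tb <- approx
      for (a in seq_len(d)) {
        f <- if (combos[r, a]) G[[a]] else H[[a]]
        Tb <- Tb * expandAxis(f, a)
      }
      transfers[[length(transfers) + 1L]] <- Tb
    }
    for (a in seq_len(d)) approx <- approx * expandAxis(H[[a]], a)
  }
  transfers[[length(transfers) + 1L]] <- approx
  new("SparsifyingFrame", gridShape = N, levels = as.integer(levels),
      transfers = transfers)
}

#' Frame analysis: image to coefficient vector
#'
#' @param frame a \code{SparsifyingFrame}
#' @param img \code{ImageGrid} or complex array on the frame grid
#' @return complex coefficient vector (subbands concatenated)
#' @export
frameForward <- function(frame, img) {
  x <- if (is(img, "ImageGrid")) img@data else as.array(img)
  stopDim(all(dim(x) == frame@gridShape), "image shape does not match frame grid")
  X <- fft(x)
  nt <- prod(frame@gridShape)
  out <- vector("list", length(frame@transfers))
  for (b in seq_along(frame@transfers)) {
    out[[b]] <- as.vector(fft(X * frame@transfers[[b]], inverse = TRUE)) / nt
  }
  unlist(out)
}

#' Frame synthesis (adjoint): coefficient vector to image
#'
#' Exact adjoint of \code{\link{frameForward}}; because the frame is
#' Parseval, it is also a left inverse of the analysis operator.
#'
#' @param frame a \code{SparsifyingFrame}
#' @param coeffs complex coefficient vector from \code{frameForward}
#' @return complex array on the frame grid
#' @export
frameAdjoint <- function(frame, coeffs) {
  N <- frame@gridShape
  nt <- prod(N)
  nb <- length(frame@transfers)
  stopDim(length(coeffs) == nb * nt, "coefficient vector has the wrong length")
  acc <- array(0i, N)
  for (b in seq_len(nb)) {
    w <- array(coeffs[((b - 1L) * nt + 1L):(b * nt)], N)
    acc <- acc + fft(fft(w) * Conj(frame@transfers[[b]]), inverse = TRUE) / nt
  }
  acc
}
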