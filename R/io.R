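# Raw k-space container and image output.
#
# Raw container: a documented JSON layout (one object per file) holding
#   dim      : trajectory dimensionality (2 or 3)
#   n_coils  : number of receiver coils
#   coords   : n_samples x dim array of normalized k-space coordinates
#   data_re, data_im : n_samples x n_coils real/imaginary sample parts
# Numbers are written at full precision, so a write/read roundtrip is
# bit-identical. Images are written as NIfTI-1 via RNifti; complex images go
# out either as magnitude or as a real/imaginary volume pair.

#' Write a raw k-space container
#'
#' @param traj \code{Trajectory}
#' @param samples matching \code{KSpaceSamples}
#' @param path output file path (conventionally .kspace.json)
#' @export
writeKSpace <- function(traj, samples, path) {
  checkAligned(traj, samples)
  v <- sampleValues(samples)
  obj <- list(
    format = "autopmri-kspace-v1",
    dim = nDim(traj),
    n_coils = ncol(v),
    n_samples = nSamples(traj),
    coords = unclass(coords(traj)),
    data_re = Re(v),
    data_im = Im(v)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raw k-space container
#'
#' Validates the declared dimensionality, coil and sample counts against the
#' stored arrays; coordinates outside [-0.5, 0.5) are rejected, not wrapped.
#'
#' @param path container path written by \code{\link{writeKSpace}}
#' @return list with elements \code{trajectory} and \code{samples}
#' @export
readKSpace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("dim", "n_coils", "coords", "data_re", "data_im")
  if (!all(need %in% names(obj))) {
    stop("malformed k-space container: missing field(s) ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  k <- as.matrix(obj$coords)
  if (ncol(k) != obj$dim) {
    stop(sprintf("container declares dim=%d but coords have %d column(s)",
                 obj$dim, ncol(k)))
  }
  re <- as.matrix(obj$data_re); im <- as.matrix(obj$data_im)
  if (!is.null(obj$n_samples) && obj$n_samples != nrow(k)) {
    stop("container declares a sample count inconsistent with its coords")
  }
  if (nrow(re) != nrow(k) || ncol(re) != obj$n_coils ||
      any(dim(re) != dim(im))) {
    stop("container data matrices inconsistent with declared dimensions")
  }
  if (!all(is.finite(k)) || !all(is.finite(re)) || !all(is.finite(im))) {
    stop("non-finite values in k-space container")
  }
  list(trajectory = trajectory(k),
       samples = kspaceSamples(matrix(complex(real = re, imaginary = im),
                                      nrow(re), ncol(re))))
}

#' Write an image as NIfTI-1
#'
#' Complex data are stored as magnitude when \code{magnitudeOnly}, otherwise
#' as a real/imaginary pair stacked along an extra dimension. Voxel spacing
#' is set to gridsize/fovPixels (1 when the FOV equals the grid).
#'
#' @param img \code{ImageGrid}
#' @param path output path (.nii or .nii.gz)
#' @param magnitudeOnly store |img| only (default TRUE)
#' @export
writeImage <- function(img, path, magnitudeOnly = TRUE) {
  stopifnot(is(img, "ImageGrid"))
  pix <- dim(img@data) / as.numeric(fovPixels(img))
  arr <- if (magnitudeOnly) {
    Mod(img@data)
  } else {
    d <- dim(img@data)
    out <- array(0, c(d, 2L))
    idx <- rep(list(quote(expr = )), length(d))
    out <- do.call(`[<-`, c(list(out), idx, list(1L), list(Re(img@data))))
    do.call(`[<-`, c(list(out), idx, list(2L), list(Im(img@data))))
  }
  nii <- RNifti::asNifti(arr, pixdim = c(pix, rep(1, length(dim(arr)) - length(pix))))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a NIfTI image written by \code{\link{writeImage}}
#'
#' @param path NIfTI path
#' @param complexPair interpret the last dimension as a real/imaginary pair
#' @return \code{ImageGrid}
#' @export
readImage <- function(path, complexPair = FALSE) {
  arr <- as.array(RNifti::readNifti(path))
  if (complexPair) {
    d <- dim(arr)
    nd <- length(d) - 1L
    idx <- rep(list(quote(expr = )), nd)
    re <- do.call(`[`, c(list(arr), idx, list(1L)))
    im <- do.call(`[`, c(list(arr), idx, list(2L)))
    return(imageGrid(array(complex(real = re, imaginary = im), d[seq_len(nd)])))
  }
  imageGrid(arr)
}
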