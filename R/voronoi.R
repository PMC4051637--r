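# Voronoi tessellation of a k-space sampling pattern.
#
# The normalized k-space domain is periodic: coordinates live on the torus
# [-0.5, 0.5)^d (a frequency of -0.5 is the same alias as +0.5). Cells are
# therefore computed against one layer of periodic translates of the sampling
# pattern, which makes a full Cartesian Nyquist grid uniformly dense (every
# cell an exact 1/N cube) with no special-casing of the convex hull. A cell is
# flagged "unbounded" when its extent reaches half the unit bandwidth: such a
# cell can never certify any sampling density.

mergeDuplicates <- function(k, tol = 1e-12) {
  key <- apply(round(k / tol) * tol, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  cellOf <- match(key, key[first])
  if (any(!first)) {
    warning(sprintf("merged %d duplicate k-space coordinate(s) before tessellation",
                    sum(!first)))
  }
  list(points = k[first, , drop = FALSE], mergedIndex = as.integer(cellOf))
}

# One layer of periodic translates, filtered to a shell around the domain.
periodicPool <- function(pts, margin = 0.35) {
  d <- ncol(pts)
  offs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), d)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  extra <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    sweep(pts, 2L, offs[i, ], `+`)
  }))
  keep <- apply(abs(extra) <= 0.5 + margin, 1L, all)
  list(shell = rbind(pts, extra[keep, , drop = FALSE]),
       full = rbind(pts, extra))
}

#' Voronoi tessellation of k-space sample coordinates
#'
#' Builds the Voronoi cell (vertex set plus unbounded flag) of every sampling
#' coordinate, on the periodic unit-bandwidth domain. Exact duplicate
#' coordinates (within 1e-12) are merged first with a warning. Cells are
#' computed by half-space clipping against neighbours in increasing distance
#' order, stopping once no farther point can cut the cell; the construction is
#' exact up to floating-point rounding.
#'
#' @param traj a \code{Trajectory} with at least d+2 distinct samples
#' @return a \code{VoronoiTessellation}
#' @export
voronoiTessellate <- function(traj) {
  k <- coords(traj)
  d <- ncol(k)
  m <- mergeDuplicates(k)
  pts <- m$points
  n <- nrow(pts)
  if (n < d + 2L) stop("need at least d+2 distinct samples to tessellate")
  sv <- svd(scale(pts, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[d] <= 1e-10 * max(sv[1], 1e-300)) {
    stop("degenerate geometry: sample coordinates are collinear/coplanar")
  }
  pool <- periodicPool(pts)
  cellFun <- if (d == 2L) voronoi_cell_2d else voronoi_cell_3d
  vertices <- vector("list", n)
  unbounded <- logical(n)
  K <- min(nrow(pool$shell) - 1L, 48L)
  chunk <- 256L
  for (s in seq(1L, n, by = chunk)) {
    e <- s:min(s + chunk - 1L, n)
    D <- matrix(0, length(e), nrow(pool$shell))
    for (a in seq_len(d)) D <- D + outer(pts[e, a], pool$shell[, a], `-`)^2
    for (ii in seq_along(e)) {
      i <- e[ii]
      di <- D[ii, ]
      ord <- order(di)
      ord <- ord[di[ord] > 1e-20][seq_len(min(K, nrow(pool$shell) - 1L))]
      res <- cellFun(pts[i, ], pool$shell[ord, , drop = FALSE],
                     sqrt(di[ord]), 1.0)
      if (isTRUE(res$exhausted)) {
        # Rare: very sparse pattern; redo against the full translate pool.
        df <- colSums((t(pool$full) - pts[i, ])^2)
        ordf <- order(df)
        ordf <- ordf[df[ordf] > 1e-20]
        res <- cellFun(pts[i, ], pool$full[ordf, , drop = FALSE],
                       sqrt(df[ordf]), 1.0)
      }
      V <- res$vertices
      vertices[[i]] <- V
      cheb <- max(abs(sweep(V, 2L, pts[i, ], `-`)))
      unbounded[i] <- isTRUE(res$touchesBox) || cheb >= 0.5 - 1e-9
    }
  }
  new("VoronoiTessellation", points = pts, vertices = vertices,
      unbounded = unbounded, mergedIndex = m$mergedIndex)
}

# Assign integer ids to points that coincide within tol (per-axis gaps),
# used to identify Voronoi vertices shared between neighbouring cells.
clusterPoints <- function(V, tol = 1e-7) {
  n <- nrow(V)
  ids <- integer(n)
  nextId <- 0L
  recurse <- function(idx, axis) {
    if (axis > ncol(V)) {
      nextId <<- nextId + 1L
      ids[idx] <<- nextId
      return(invisible())
    }
    o <- idx[order(V[idx, axis])]
    vals <- V[o, axis]
    breaks <- which(diff(vals) > tol)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(o))
    for (g in seq_along(starts)) recurse(o[starts[g]:ends[g]], axis + 1L)
  }
  if (n > 0) recurse(seq_len(n), 1L)
  ids
}
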