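#' @useDynLib geoclick, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

connectivity_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (!connectivity %in% c(4, 8)) {
      stop("2D connectivity must be 4 or 8", call. = FALSE)
    }
  } else if (!connectivity %in% c(6, 26)) {
    stop("3D connectivity must be 6 or 26", call. = FALSE)
  }
  full <- as.matrix(do.call(expand.grid, rep(list(-1:1), ndim)))
  full <- full[rowSums(abs(full)) > 0L, , drop = FALSE]
  if (connectivity %in% c(4, 6)) {
    full <- full[rowSums(abs(full)) == 1L, , drop = FALSE]
  }
  storage.mode(full) <- "integer"
  unname(full)
}

default_connectivity <- function(ndim) if (ndim == 2L) 8 else 26

coords_to_linear0 <- function(coords, dims) {
  if (!is.matrix(coords)) coords <- matrix(coords, nrow = 1L)
  if (ncol(coords) != length(dims)) {
    stop("seed coordinates have wrong dimensionality", call. = FALSE)
  }
  if (any(coords < 1L) || any(t(coords) > dims)) {
    stop("seed coordinates out of image bounds", call. = FALSE)
  }
  stride <- cumprod(c(1L, dims[-length(dims)]))
  as.integer((coords - 1L) %*% stride)
}

#' Geodesic distance map from a seed set
#'
#' Shortest accumulated intensity-difference cost from every pixel to the
#' nearest seed, over the 4/8-connected (2D) or 6/26-connected (3D) pixel
#' graph.  The per-edge cost between adjacent pixels is `|I(a) - I(b)|`
#' (a discretization of the intensity-gradient line integral), so the
#' distance is contrast-sensitive and parameter-free: constant regions cost
#' nothing to cross while strong edges are expensive.  Computed by exact
#' multi-source Dijkstra, not an approximate raster sweep.
#'
#' @param img [intensity_image()] or matrix/array.
#' @param seeds Integer matrix of 1-based seed coordinates (one per row),
#'   or a [click_set()] whose foreground clicks are used.
#' @param connectivity 4 or 8 in 2D, 6 or 26 in 3D (defaults 8 / 26).
#' @return Numeric array of distances with class `distance_map`; 0 at the
#'   seeds, `Inf` only for pixels disconnected from every seed.
#' @export
geodesic_distance_map <- function(img, seeds, connectivity = NULL) {
  img <- as_image(img)
  if (inherits(seeds, "click_set")) seeds <- seeds$fg
  if (is.null(seeds) || length(seeds) == 0L) {
    stop("seed set is empty", call. = FALSE)
  }
  if (!is.matrix(seeds)) seeds <- matrix(seeds, nrow = 1L)
  d <- dim(img$values)
  if (is.null(connectivity)) connectivity <- default_connectivity(length(d))
  off <- connectivity_offsets(length(d), connectivity)
  lin <- coords_to_linear0(seeds, d)
  dist <- .dijkstra_geodesic(as.numeric(img$values), as.integer(d), lin, off)
  out <- array(dist, dim = d)
  class(out) <- c("distance_map", class(out))
  out
}

#' Exponentialized geodesic distance (EGD) cue map
#'
#' `exp(-min_j D_geo(i, j))` over the seed set: a parameter-free encoding of
#' user clicks that equals 1 exactly at the seeds, decays with geodesic
#' (contrast-aware) distance, and is 0 only for disconnected pixels.
#'
#' @inheritParams geodesic_distance_map
#' @return Numeric array in `[0, 1]` with class `cue_map`.
#' @export
egd_cue_map <- function(img, seeds, connectivity = NULL) {
  d <- geodesic_distance_map(img, seeds, connectivity)
  out <- exp(-unclass(d))
  out[is.infinite(unclass(d))] <- 0
  class(out) <- c("cue_map", class(out))
  out
}
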