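#' Construct an intensity image
#'
#' The basic container for scalar 2D or 3D image data.  Values are held as a
#' numeric matrix (2D, rows = image rows) or 3D array (slice, row, column),
#' together with optional physical voxel spacing and origin in millimetres.
#'
#' @param values Numeric matrix or 3D array of finite intensities.
#' @param spacing Numeric vector of per-axis physical sizes (mm), one entry
#'   per array dimension.  Defaults to unit spacing.
#' @param origin Numeric vector of physical offsets, same length as
#'   `spacing`.  Defaults to zero.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, spacing = NULL, origin = NULL) {
  if (is.vector(values) && !is.array(values)) {
    values <- matrix(values, nrow = 1L)
  }
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) {
    stop("intensity_image requires a 2D matrix or 3D array, got ",
         nd, " dimensions", call. = FALSE)
  }
  if (!is.numeric(values)) stop("image values must be numeric", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("image values must all be finite", call. = FALSE)
  }
  if (is.null(spacing)) spacing <- rep(1, nd)
  if (is.null(origin)) origin <- rep(0, nd)
  stopifnot(length(spacing) == nd, length(origin) == nd, all(spacing > 0))
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  d <- dim(x$values)
  cat("<intensity_image> ", paste(d, collapse = " x "),
      "  range [", format(min(x$values)), ", ", format(max(x$values)), "]",
      "  spacing (", paste(format(x$spacing), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$values)

#' @export
as.array.intensity_image <- function(x, ...) x$values

is_image <- function(x) inherits(x, "intensity_image")

as_image <- function(x, like = NULL) {
  if (is_image(x)) return(x)
  if (!is.null(like) && is_image(like)) {
    return(intensity_image(x, spacing = like$spacing, origin = like$origin))
  }
  intensity_image(x)
}

#' Construct a binary mask
#'
#' @param values Matrix or array with values in `{0, 1}` (logical accepted,
#'   any nonzero value is coerced to 1).
#' @return An integer matrix/array of 0/1 with class `binary_mask`.
#' @export
binary_mask <- function(values) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) {
    stop("binary_mask requires a 2D or 3D array", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("mask values must be finite", call. = FALSE)
  out <- array(as.integer(values != 0), dim = dim(values))
  class(out) <- c("binary_mask", class(out))
  out
}

mask_values <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "integer"
  m
}

#' Min-max normalization to a target interval
#'
#' Affinely rescales intensities so that the observed minimum maps to `ef1`
#' and the observed maximum maps to `ef2`.  A constant image (zero dynamic
#' range) maps to `ef1` everywhere rather than dividing by zero.
#'
#' @param img An [intensity_image()] (a bare matrix/array is accepted).
#' @param ef1,ef2 Target lower and upper bounds, `ef1 < ef2`.
#'   Defaults to the unit interval.
#' @return An `intensity_image` with values in `[ef1, ef2]`.
#' @export
normalize_intensity <- function(img, ef1 = 0, ef2 = 1) {
  if (!(is.numeric(ef1) && is.numeric(ef2) && ef1 < ef2)) {
    stop("normalization bounds require ef1 < ef2", call. = FALSE)
  }
  img <- as_image(img)
  v <- img$values
  lo <- min(v)
  hi <- max(v)
  out <- if (hi > lo) ef1 + (ef2 - ef1) * (v - lo) / (hi - lo)
         else array(ef1, dim = dim(v))
  intensity_image(out, spacing = img$spacing, origin = img$origin)
}

#' Geometric augmentation of an image
#'
#' The four slice-wise augmentations used to enlarge small CT training sets:
#' 90-degree rotation, transposition, horizontal flip and vertical flip.
#' All four are pixel permutations, so the value histogram is unchanged.
#' 3D inputs are transformed slice-by-slice in the in-plane (last two) axes.
#'
#' @param img An [intensity_image()] or matrix/array.
#' @param op One of `"rot90"`, `"transpose"`, `"hflip"`, `"vflip"`.
#' @return The augmented `intensity_image`.
#' @export
augment <- function(img, op = c("rot90", "transpose", "hflip", "vflip")) {
  op <- match.arg(op)
  img <- as_image(img)
  v <- img$values
  f2d <- switch(op,
    rot90     = function(m) t(m)[ncol(m):1, , drop = FALSE],
    transpose = function(m) t(m),
    hflip     = function(m) m[, ncol(m):1, drop = FALSE],
    vflip     = function(m) m[nrow(m):1, , drop = FALSE]
  )
  if (length(dim(v)) == 2L) {
    out <- f2d(v)
  } else {
    slices <- lapply(seq_len(dim(v)[1L]), function(z) f2d(v[z, , ]))
    out <- array(0, dim = c(dim(v)[1L], dim(slices[[1L]])))
    for (z in seq_along(slices)) out[z, , ] <- slices[[z]]
  }
  sp <- img$spacing
  if (op %in% c("rot90", "transpose")) {
    nd <- length(sp)
    sp[c(nd - 1L, nd)] <- sp[c(nd, nd - 1L)]
  }
  intensity_image(out, spacing = sp, origin = img$origin)
}
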