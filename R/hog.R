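#' Per-pixel gradient fields and unsigned orientation
#'
#' Forward differences `dx = I(x+1, y) - I(x, y)` (horizontal, x = column)
#' and `dy = I(x, y+1) - I(x, y)` (vertical, y = row), zero at the last
#' column/row (edge replication).  Orientation is the unsigned angle
#' `atan(dy/dx)` mapped to degrees in `[0, 180)`; a zero gradient gets
#' orientation 0 by convention.
#'
#' @param img 2D [intensity_image()] or matrix.
#' @return List of matrices `dx`, `dy`, `theta` (class `gradient_field`).
#' @export
gradient_fields <- function(img) {
  v <- if (is_image(img)) img$values else as.matrix(img)
  if (length(dim(v)) != 2L) stop("gradients are 2D-only", call. = FALSE)
  h <- nrow(v)
  w <- ncol(v)
  dx <- matrix(0, h, w)
  dy <- matrix(0, h, w)
  if (w > 1L) dx[, -w] <- v[, -1L, drop = FALSE] - v[, -w, drop = FALSE]
  if (h > 1L) dy[-h, ] <- v[-1L, , drop = FALSE] - v[-h, , drop = FALSE]
  theta <- (atan2(dy, dx) * 180 / pi) %% 180
  theta[dx == 0 & dy == 0] <- 0
  theta[theta >= 180] <- 0
  structure(list(dx = dx, dy = dy, theta = theta), class = "gradient_field")
}

#' Tile a gradient field into overlapping blocks
#'
#' 8x8-pixel cells scanned by a 16x16-pixel window at stride 8 (each block
#' covers four adjacent cells), in row-major order.  The canonical 64-wide
#' by 128-high window yields `(64/8 - 1) * (128/8 - 1) = 105` blocks.
#'
#' @param field A `gradient_field` (or a plain orientation matrix).
#' @param cell Cell side in pixels (default 8).
#' @return List of blocks, each a list with the block's `theta` (and
#'   magnitude `mag`) and its top-left position; attribute `grid` holds the
#'   block grid dimensions.
#' @export
tile_blocks <- function(field, cell = 8L) {
  theta <- if (inherits(field, "gradient_field")) field$theta else
    as.matrix(field)
  mag <- if (inherits(field, "gradient_field")) {
    sqrt(field$dx^2 + field$dy^2)
  } else matrix(1, nrow(theta), ncol(theta))
  h <- nrow(theta)
  w <- ncol(theta)
  if (h %% cell != 0L || w %% cell != 0L) {
    stop("image dimensions must be multiples of the cell size", call. = FALSE)
  }
  if (h < 2L * cell || w < 2L * cell) {
    stop("image too small for a ", 2L * cell, "-pixel window", call. = FALSE)
  }
  nby <- h %/% cell - 1L   # block rows
  nbx <- w %/% cell - 1L   # block cols
  blocks <- vector("list", nby * nbx)
  k <- 1L
  for (by in seq_len(nby)) {
    for (bx in seq_len(nbx)) {
      r0 <- (by - 1L) * cell
      c0 <- (bx - 1L) * cell
      rows <- r0 + seq_len(2L * cell)
      cols <- c0 + seq_len(2L * cell)
      blocks[[k]] <- list(theta = theta[rows, cols],
                          mag = mag[rows, cols],
                          top_left = c(r0 + 1L, c0 + 1L))
      k <- k + 1L
    }
  }
  attr(blocks, "grid") <- c(nby, nbx)
  blocks
}

#' Orientation histogram of one block
#'
#' Hard-assignment vote of every pixel's orientation into `n_bins` uniform
#' bins over `[0, 180)`; unweighted by default, so the histogram total
#' equals the number of pixels in the block.
#'
#' @param block_theta Matrix of orientations in `[0, 180)`.
#' @param n_bins Number of bins (`>= 1`).
#' @param weights Optional matrix of vote weights (e.g. gradient
#'   magnitudes); default 1 per pixel.
#' @return Numeric vector of length `n_bins`.
#' @export
block_histogram <- function(block_theta, n_bins, weights = NULL) {
  if (!is.numeric(n_bins) || n_bins < 1L) {
    stop("n_bins must be a positive integer", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  th <- as.numeric(block_theta) %% 180
  bin <- pmin(floor(th / (180 / n_bins)) + 1L, n_bins)
  w <- if (is.null(weights)) rep(1, length(th)) else as.numeric(weights)
  as.numeric(tapply(w, factor(bin, levels = seq_len(n_bins)), sum,
                    default = 0))
}

#' Selective-bin HOG descriptor
#'
#' Concatenated per-block orientation histograms, with a finer bin count on
#' blocks flagged "high" (regions expected to carry the object) and a
#' coarser count elsewhere, trading feature size against orientation
#' detail.  The default flags every block high.
#'
#' @param img 2D image, typically 128 rows by 64 columns (dimensions must
#'   be multiples of 8).
#' @param block_mask Logical/0-1 vector, one flag per block (row-major);
#'   `NULL` means all high.
#' @param high_bins,low_bins Bin counts for flagged / unflagged blocks.
#' @param weighted If `TRUE`, votes are weighted by gradient magnitude
#'   instead of counting 1 per pixel.
#' @return Object of class `hog_descriptor`: list with `feature_vector`,
#'   `block_histograms`, `bin_plan` and the block `grid`.
#' @export
hog_descriptor <- function(img, block_mask = NULL, high_bins = 9L,
                           low_bins = 4L, weighted = FALSE) {
  gf <- gradient_fields(img)
  blocks <- tile_blocks(gf)
  nb <- length(blocks)
  if (is.null(block_mask)) block_mask <- rep(TRUE, nb)
  block_mask <- as.logical(block_mask)
  if (length(block_mask) != nb) {
    stop("block_mask length ", length(block_mask),
         " does not match block count ", nb, call. = FALSE)
  }
  bin_plan <- ifelse(block_mask, as.integer(high_bins), as.integer(low_bins))
  hists <- lapply(seq_len(nb), function(k) {
    block_histogram(blocks[[k]]$theta, bin_plan[k],
                    weights = if (weighted) blocks[[k]]$mag else NULL)
  })
  structure(
    list(feature_vector = unlist(hists, use.names = FALSE),
         block_histograms = hists,
         bin_plan = bin_plan,
         grid = attr(blocks, "grid")),
    class = "hog_descriptor"
  )
}

#' Extract HOG features for a batch of crops
#'
#' Classifier-facing feature layer: each crop is min-max normalized to
#' `[0, 1]`, resized to the canonical 128x64 window (bilinear) and
#' described by [hog_descriptor()].  By default votes are weighted by
#' gradient magnitude and divided by the block pixel count, which keeps
#' the features on a unit scale and retains edge-strength information --
#' in low-texture CT-like crops the lesion signal lives mostly in edge
#' strength, not orientation alone.
#'
#' @param crops List of 2D images (any sizes).
#' @param weighted Weight votes by gradient magnitude (default `TRUE`
#'   here, unlike the raw descriptor).
#' @param rescale Normalize each crop to `[0, 1]` and divide histograms by
#'   the block pixel count.
#' @param ... Passed to [hog_descriptor()].
#' @return Numeric matrix, one row per crop.
#' @export
hog_feature_matrix <- function(crops, weighted = TRUE, rescale = TRUE, ...) {
  rows <- lapply(crops, function(cr) {
    v <- if (is_image(cr)) cr$values else as.matrix(cr)
    if (rescale) v <- normalize_intensity(v)$values
    f <- hog_descriptor(resize_bilinear(v, 128L, 64L),
                        weighted = weighted, ...)$feature_vector
    if (rescale) f <- f / 256
    f
  })
  do.call(rbind, rows)
}

# Bilinear resize of a matrix to (rows, cols) via EBImage; EBImage images
# index (x, y) so the matrix is transposed going in and out.
resize_bilinear <- function(m, rows, cols) {
  t(EBImage::resize(t(m), w = cols, h = rows))
}

# Nearest-neighbour resize for masks.
resize_nearest <- function(m, rows, cols) {
  r_idx <- pmin(pmax(round((seq_len(rows) - 0.5) * nrow(m) / rows + 0.5), 1L),
                nrow(m))
  c_idx <- pmin(pmax(round((seq_len(cols) - 0.5) * ncol(m) / cols + 0.5), 1L),
                ncol(m))
  m[r_idx, c_idx, drop = FALSE]
}
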