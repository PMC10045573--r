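#' Construct a set of user clicks
#'
#' Foreground and background click coordinates, stored as integer matrices
#' with one row per click and one column per image axis (1-based array
#' indices: row/column in 2D, slice/row/column in 3D).
#'
#' @param fg,bg Integer matrices of coordinates (or `NULL` for none).
#' @return An object of class `click_set`.
#' @export
click_set <- function(fg = NULL, bg = NULL) {
  norm <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
    storage.mode(x) <- "integer"
    x
  }
  fg <- norm(fg)
  bg <- norm(bg)
  if (!is.null(fg) && !is.null(bg)) {
    if (ncol(fg) != ncol(bg)) {
      stop("fg and bg clicks must share dimensionality", call. = FALSE)
    }
    dup <- intersect(apply(fg, 1L, paste, collapse = ","),
                     apply(bg, 1L, paste, collapse = ","))
    if (length(dup) > 0L) {
      stop("clicks cannot be both foreground and background: ",
           paste(dup, collapse = "; "), call. = FALSE)
    }
  }
  structure(list(fg = fg, bg = bg), class = "click_set")
}

n_clicks <- function(clicks) {
  nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)
  nrow2(clicks$fg) + nrow2(clicks$bg)
}

#' @export
print.click_set <- function(x, ...) {
  n <- function(m) if (is.null(m)) 0L else nrow(m)
  cat("<click_set> ", n(x$fg), " foreground, ", n(x$bg),
      " background clicks\n", sep = "")
  invisible(x)
}

#' Merge two click sets
#'
#' @param a,b `click_set` objects.
#' @return The cumulative `click_set` (duplicates removed).
#' @export
merge_clicks <- function(a, b) {
  cat2 <- function(x, y) {
    m <- rbind(x, y)
    if (is.null(m)) return(NULL)
    unique(m)
  }
  click_set(fg = cat2(a$fg, b$fg), bg = cat2(a$bg, b$bg))
}

#' Serialize clicks to JSON
#'
#' The interchange layout is 0-based and row-major:
#' `{"fg": [[r,c],...], "bg": [[r,c],...]}` (slice index first for 3D).
#'
#' @param clicks A [click_set()].
#' @param path Optional file to write to.
#' @return JSON string (invisibly when `path` given).
#' @export
clicks_to_json <- function(clicks, path = NULL) {
  conv <- function(m) {
    if (is.null(m)) return(list())
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ] - 1L))
  }
  js <- jsonlite::toJSON(list(fg = conv(clicks$fg), bg = conv(clicks$bg)),
                         auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize clicks from JSON
#'
#' @param x JSON string or path to a JSON file.
#' @return A [click_set()] with 1-based coordinates.
#' @export
clicks_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyMatrix = TRUE)
  conv <- function(m) {
    if (is.null(m) || length(m) == 0L) return(NULL)
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.integer(m), ncol = ncol(m)) + 1L
  }
  click_set(fg = conv(obj$fg), bg = conv(obj$bg))
}

# Inner boundary: mask pixels 4-adjacent (2D) / 6-adjacent (3D) to background.
inner_boundary <- function(mask) {
  m <- mask_values(mask)
  nd <- length(dim(m))
  d <- dim(m)
  shift_bg <- function(offset) {
    out <- array(TRUE, dim = d)  # outside the frame counts as background
    idx_src <- lapply(seq_len(nd), function(k) {
      i <- seq_len(d[k]) + offset[k]
      i[i < 1L | i > d[k]] <- NA
      i
    })
    valid <- lapply(idx_src, function(i) !is.na(i))
    dst <- lapply(seq_len(nd), function(k) which(valid[[k]]))
    src <- lapply(seq_len(nd), function(k) idx_src[[k]][valid[[k]]])
    out_idx <- as.matrix(do.call(expand.grid, dst))
    src_idx <- as.matrix(do.call(expand.grid, src))
    out[out_idx] <- m[src_idx] == 0L
    out
  }
  offsets <- rbind(diag(nd), -diag(nd))
  near_bg <- array(FALSE, dim = d)
  for (i in seq_len(nrow(offsets))) {
    near_bg <- near_bg | shift_bg(offsets[i, ])
  }
  which(m == 1L & near_bg, arr.ind = TRUE)
}

#' Simulate inner-margin clicks from a ground-truth mask
#'
#' Emulates the click pattern a user would place just inside an object's
#' boundary: one point near each axis-aligned extreme of the boundary (so a
#' bounding box of the clicks covers the whole object), plus `n_extra`
#' random boundary points for shape context, all shifted a small random
#' distance towards the object centroid to mimic slightly inaccurate clicks.
#'
#' @param mask [binary_mask()] of the target object (nonempty).
#' @param n_extra Number of additional random boundary points.
#' @param inward_shift_range Integer range (min, max) of the inward shift in
#'   pixels; the walk stops early rather than leave the mask.
#' @param seed RNG seed for reproducible simulation.
#' @return A [click_set()] with foreground clicks only.
#' @export
simulate_inner_margin_points <- function(mask, n_extra = 5,
                                         inward_shift_range = c(1, 3),
                                         seed = NULL) {
  m <- mask_values(mask)
  if (sum(m) == 0L) stop("mask has no foreground pixels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bd <- inner_boundary(m)
  if (nrow(bd) == 0L) bd <- which(m == 1L, arr.ind = TRUE)
  nd <- ncol(bd)

  # one boundary point at each axis-aligned extreme, lexicographic tie-break
  ord <- do.call(order, as.data.frame(bd))
  bd <- bd[ord, , drop = FALSE]
  extreme_rows <- integer(0)
  for (ax in seq_len(nd)) {
    extreme_rows <- c(extreme_rows,
                      which.max(bd[, ax] == min(bd[, ax])),
                      which.max(bd[, ax] == max(bd[, ax])))
  }
  extreme_rows <- unique(extreme_rows)
  centroid <- colMeans(which(m == 1L, arr.ind = TRUE))
  lo <- as.integer(min(inward_shift_range))
  hi <- as.integer(max(inward_shift_range))
  shift_inward <- function(p) {
    steps <- sample(seq.int(lo, hi), 1L)
    cur <- p
    dirv <- centroid - p
    nv <- sqrt(sum(dirv^2))
    if (nv < 1e-9) return(cur)
    u <- dirv / nv
    for (k in seq_len(steps)) {
      nxt <- as.integer(round(p + k * u))
      inside <- all(nxt >= 1L) && all(nxt <= dim(m)) &&
        m[matrix(nxt, nrow = 1L)] == 1L
      if (!inside) break
      cur <- nxt
    }
    cur
  }
  # extreme points (and their shifts) are drawn before the extras, so a
  # larger n_extra only ever adds points: the tight bbox cannot shrink
  shifted <- t(apply(bd[extreme_rows, , drop = FALSE], 1L, shift_inward))
  rest <- setdiff(seq_len(nrow(bd)), extreme_rows)
  n_extra <- min(n_extra, length(rest))
  if (n_extra > 0L) {
    extra_rows <- sample(rest, n_extra)
    shifted <- rbind(
      shifted,
      t(apply(bd[extra_rows, , drop = FALSE], 1L, shift_inward))
    )
  }
  click_set(fg = unique(shifted))
}

#' Relaxed bounding box of a click set
#'
#' Coordinate-wise min/max of the foreground clicks, expanded outward by
#' `expand` pixels per side and clipped to the image bounds.
#'
#' @param clicks A [click_set()] with at least one foreground click.
#' @param expand Outward expansion per side, in pixels.
#' @param image_shape Integer vector of image dimensions used for clipping.
#' @return A `bounding_box`: list with integer vectors `lo` and `hi`
#'   (inclusive, 1-based).
#' @export
relaxed_bbox <- function(clicks, expand = 5, image_shape) {
  pts <- clicks$fg
  if (is.null(pts) || nrow(pts) == 0L) {
    stop("cannot build a bounding box from an empty click set", call. = FALSE)
  }
  stopifnot(ncol(pts) == length(image_shape))
  lo <- pmax(apply(pts, 2L, min) - expand, 1L)
  hi <- pmin(apply(pts, 2L, max) + expand, as.integer(image_shape))
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat("<bounding_box> ",
      paste(sprintf("[%d,%d]", x$lo, x$hi), collapse = " x "), "\n", sep = "")
  invisible(x)
}

bbox_slices <- function(box) {
  mapply(function(a, b) seq.int(a, b), box$lo, box$hi, SIMPLIFY = FALSE)
}

#' Crop an image (or mask) to a bounding box
#'
#' The crop records its offset so results computed on it can be pasted back
#' with [paste_into()].
#'
#' @param img [intensity_image()], [binary_mask()] or bare array.
#' @param box A `bounding_box` from [relaxed_bbox()].
#' @return Object of the same kind, restricted to the box, with an
#'   `"offset"` attribute (1-based position of the crop's first voxel).
#' @export
crop <- function(img, box) {
  arr <- if (is_image(img)) img$values else as.array(img)
  d <- dim(arr)
  if (length(d) != length(box$lo)) {
    stop("bounding box dimensionality does not match image", call. = FALSE)
  }
  if (any(box$lo < 1L) || any(box$hi > d) || any(box$lo > box$hi)) {
    stop("bounding box lies outside the image", call. = FALSE)
  }
  idx <- bbox_slices(box)
  sub <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  out <- if (is_image(img)) {
    intensity_image(sub, spacing = img$spacing, origin = img$origin)
  } else if (inherits(img, "binary_mask")) {
    binary_mask(sub)
  } else sub
  attr(out, "offset") <- box$lo
  out
}

#' Paste a cropped result back into a full-size array
#'
#' @param full Full-size array/mask to paste into (unchanged outside the box).
#' @param sub Cropped array (same shape as the box).
#' @param box The `bounding_box` used for the crop.
#' @return The full-size object with the boxed region replaced.
#' @export
paste_into <- function(full, sub, box) {
  arr <- if (is_image(full)) full$values else as.array(full)
  subv <- if (is_image(sub)) sub$values else as.array(sub)
  idx <- bbox_slices(box)
  arr <- do.call(`[<-`, c(list(arr), idx, list(value = subv)))
  if (is_image(full)) {
    intensity_image(arr, spacing = full$spacing, origin = full$origin)
  } else if (inherits(full, "binary_mask")) {
    binary_mask(arr)
  } else arr
}

#' Shift click coordinates into a crop's frame
#'
#' @param clicks A [click_set()] in full-image coordinates.
#' @param box The crop's `bounding_box`.
#' @return A `click_set` in crop coordinates; clicks outside the box are
#'   dropped.
#' @export
clicks_in_box <- function(clicks, box) {
  conv <- function(m) {
    if (is.null(m)) return(NULL)
    keep <- apply(m, 1L, function(p) all(p >= box$lo) && all(p <= box$hi))
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    sweep(m, 2L, box$lo - 1L)
  }
  click_set(fg = conv(clicks$fg), bg = conv(clicks$bg))
}
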