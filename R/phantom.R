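#' Specification of a synthetic low-contrast phantom
#'
#' Emulates the abdominal-CT regime the segmentation pipeline targets: a
#' large smooth liver-like region whose interior holds a few small
#' tumour-like blobs of nearly identical intensity (low contrast), with a
#' smooth multiplicative bias field and additive Gaussian noise.
#'
#' Defaults: a 256 x 256 slice, liver covering 25-45% of the frame at +60
#' intensity over a background of 40, two tumours of radius 5-15 px at
#' +20 contrast over the liver, noise sigma 5 and 5% bias amplitude -- a
#' tumour-to-liver contrast of about 4 noise standard deviations, i.e.
#' visible but weak, matching the "practically identical" attenuation of
#' real liver lesions while leaving the task solvable without learning.
#'
#' @param shape Integer grid dimensions, length 2 (rows, cols) or 3
#'   (slices, rows, cols).
#' @param n_tumours Number of tumour blobs to place.
#' @param tumour_radius_range Min/max tumour semi-axis in pixels.
#' @param contrast Mean intensity offset of tumour over liver.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param bias_amplitude Relative amplitude of the smooth multiplicative
#'   bias field.
#' @param seed RNG seed; every random element derives from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(256, 256), n_tumours = 2,
                         tumour_radius_range = c(5, 15), contrast = 20,
                         noise_sigma = 5, bias_amplitude = 0.05, seed = 1) {
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 8),
            n_tumours >= 0, all(tumour_radius_range >= 1),
            noise_sigma >= 0, bias_amplitude >= 0)
  structure(list(shape = as.integer(shape), n_tumours = as.integer(n_tumours),
                 tumour_radius_range = tumour_radius_range,
                 contrast = contrast, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, seed = seed),
            class = "phantom_spec")
}

# smooth star-shaped blob mask: radius R0 * (1 + sum_k a_k cos(k t + ph_k))
blob_mask_2d <- function(shape, centre, r0, wobble = 0.18, orders = 2:5) {
  a <- stats::runif(length(orders), 0, wobble / length(orders) * 2)
  ph <- stats::runif(length(orders), 0, 2 * pi)
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dy <- rr - centre[1L]
  dx <- cc - centre[2L]
  t <- atan2(dy, dx)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_along(orders), function(k) {
    a[k] * cos(orders[k] * t + ph[k])
  })))
  sqrt(dy^2 + dx^2) <= rad
}

ellipsoid_mask <- function(shape, centre, radii, angle = 0) {
  nd <- length(shape)
  if (nd == 2L) {
    rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    dy <- rr - centre[1L]
    dx <- cc - centre[2L]
    u <- cos(angle) * dx + sin(angle) * dy
    v <- -sin(angle) * dx + cos(angle) * dy
    (u / radii[2L])^2 + (v / radii[1L])^2 <= 1
  } else {
    idx <- as.matrix(do.call(expand.grid, lapply(shape, seq_len)))
    dd <- sweep(idx, 2L, centre)
    q <- rowSums(sweep(dd, 2L, radii, `/`)^2)
    array(q <= 1, dim = shape)
  }
}

smooth_bias_field <- function(shape, amplitude) {
  nd <- length(shape)
  grids <- lapply(seq_len(nd), function(k) {
    (seq_len(shape[k]) - 0.5) / shape[k] - 0.5
  })
  coef <- stats::runif(nd, -1, 1)
  phase <- stats::runif(nd, 0, 2 * pi)
  field <- array(0, dim = shape)
  idx <- as.matrix(do.call(expand.grid, lapply(shape, seq_len)))
  vals <- rep(0, nrow(idx))
  for (k in seq_len(nd)) {
    g <- grids[[k]][idx[, k]]
    vals <- vals + coef[k] * g + 0.5 * sin(2 * pi * g + phase[k])
  }
  vals <- vals / max(abs(vals), 1e-9)
  field[] <- vals
  1 + amplitude * field
}

#' Generate a synthetic low-contrast phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([intensity_image()]), `liver` and `tumours`
#'   ([binary_mask()]s), and `tumour_labels` (integer array, one label per
#'   placed tumour).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  nd <- length(shape)

  # liver: smooth blob covering 20-50% of the frame
  liver <- NULL
  for (try in 1:20) {
    frac <- stats::runif(1, 0.25, 0.45)
    if (nd == 2L) {
      r0 <- sqrt(frac * prod(shape) / pi)
      centre <- shape / 2 + stats::runif(2, -0.05, 0.05) * shape
      cand <- blob_mask_2d(shape, centre, r0)
    } else {
      r0 <- (frac * prod(shape) * 3 / (4 * pi))^(1 / 3)
      centre <- shape / 2 + stats::runif(3, -0.05, 0.05) * shape
      radii <- r0 * stats::runif(3, 0.8, 1.25)
      cand <- ellipsoid_mask(shape, centre, radii)
    }
    got <- mean(cand)
    if (got >= 0.2 && got <= 0.5) {
      liver <- cand
      break
    }
  }
  if (is.null(liver)) stop("failed to generate a liver blob", call. = FALSE)

  # tumours: ellipsoids fully inside the liver, pairwise disjoint
  tum_labels <- array(0L, dim = shape)
  placed <- 0L
  rr <- spec$tumour_radius_range
  liver_idx <- which(liver, arr.ind = TRUE)
  for (j in seq_len(spec$n_tumours)) {
    ok <- FALSE
    for (try in 1:200) {
      radii <- stats::runif(nd, min(rr), max(rr))
      centre <- liver_idx[sample.int(nrow(liver_idx), 1L), ]
      angle <- if (nd == 2L) stats::runif(1, 0, pi) else 0
      cand <- ellipsoid_mask(shape, centre, radii, angle)
      if (all(liver[cand]) && !any(tum_labels[cand] > 0L)) {
        tum_labels[cand] <- j
        placed <- placed + 1L
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place tumour ", j, " of ", spec$n_tumours,
           " (", placed, " placed)", call. = FALSE)
    }
  }

  img <- array(40, dim = shape)
  img[liver] <- 100
  img[tum_labels > 0L] <- 100 + spec$contrast
  img <- img * smooth_bias_field(shape, spec$bias_amplitude)
  img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)

  list(image = intensity_image(array(img, dim = shape)),
       liver = binary_mask(liver),
       tumours = binary_mask(tum_labels > 0L),
       tumour_labels = tum_labels)
}

# bounding box (as used by crop/paste) of a nonempty mask
mask_bbox <- function(mask, expand = 0L, image_shape = dim(mask)) {
  idx <- which(mask_values(binary_mask(mask)) == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  lo <- pmax(apply(idx, 2L, min) - expand, 1L)
  hi <- pmin(apply(idx, 2L, max) + expand, as.integer(image_shape))
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "bounding_box")
}

#' Generate a labeled HOG feature set from phantoms
#'
#' Positive samples are crops around a tumour, negatives are tumour-free
#' liver crops of comparable size; each crop is resized to the canonical
#' 128 x 64 window and described by the selective-bin HOG descriptor.
#'
#' @param n_pos,n_neg Numbers of positive / negative samples.
#' @param spec [phantom_spec()] describing the imaging regime (its seed is
#'   ignored; `seed` below drives everything).
#' @param seed RNG seed.
#' @param margin Crop margin around the tumour bounding box, pixels.
#' @return List with feature matrix `X`, 0/1 vector `y`, and the `crops`.
#' @export
generate_classification_set <- function(n_pos, n_neg, spec = phantom_spec(),
                                        seed = 1, margin = 6L) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(spec$shape) == 2L)
  crops <- list()
  labels <- integer(0)
  k <- 0L
  while (length(crops) < n_pos + n_neg) {
    k <- k + 1L
    sp <- spec
    sp$seed <- seed * 10000 + k
    sp$n_tumours <- max(spec$n_tumours, 1L)
    ph <- tryCatch(generate_phantom(sp), error = function(e) NULL)
    if (is.null(ph)) next
    need_pos <- sum(labels == 1L) < n_pos
    if (need_pos) {
      lab <- sample.int(max(ph$tumour_labels), 1L)
      box <- mask_bbox(ph$tumour_labels == lab, expand = margin,
                      image_shape = sp$shape)
      crops[[length(crops) + 1L]] <- crop(ph$image, box)$values
      labels <- c(labels, 1L)
    } else {
      # a tumour-free liver crop of typical tumour size
      size <- round(mean(spec$tumour_radius_range) * 2) + 2L * margin
      placed <- FALSE
      liver_idx <- which(mask_values(ph$liver) == 1L, arr.ind = TRUE)
      for (try in 1:100) {
        ctr <- liver_idx[sample.int(nrow(liver_idx), 1L), ]
        lo <- ctr - size %/% 2L
        hi <- lo + size - 1L
        if (any(lo < 1L) || any(hi > sp$shape)) next
        box <- structure(list(lo = as.integer(lo), hi = as.integer(hi)),
                         class = "bounding_box")
        sub_liver <- crop(ph$liver, box)
        sub_tum <- crop(ph$tumours, box)
        if (all(mask_values(sub_liver) == 1L) &&
            !any(mask_values(sub_tum) == 1L)) {
          crops[[length(crops) + 1L]] <- crop(ph$image, box)$values
          labels <- c(labels, 0L)
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }
  X <- hog_feature_matrix(crops)
  list(X = X, y = labels, crops = crops)
}

#' Sample two well-separated Gaussian classes
#'
#' A small benchmark set for comparing classifier variants: two isotropic
#' Gaussian clouds in `n` dimensions whose means are `separation` standard
#' deviations apart.
#'
#' @param n_samples Total samples (split evenly).
#' @param n_features Dimensionality.
#' @param separation Distance between class means in units of sigma.
#' @param seed RNG seed.
#' @return List with matrix `X` and 0/1 labels `y`.
#' @export
two_gaussians_set <- function(n_samples = 200, n_features = 4,
                              separation = 3, seed = 1) {
  set.seed(seed)
  n1 <- n_samples %/% 2L
  n0 <- n_samples - n1
  mu <- rep(separation / sqrt(n_features), n_features)
  X <- rbind(
    matrix(stats::rnorm(n0 * n_features), n0),
    matrix(stats::rnorm(n1 * n_features), n1) +
      matrix(mu, n1, n_features, byrow = TRUE)
  )
  y <- c(rep(0L, n0), rep(1L, n1))
  ord <- sample.int(n_samples)
  list(X = X[ord, , drop = FALSE], y = y[ord])
}
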