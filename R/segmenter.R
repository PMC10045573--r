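#' Construct a foreground/background probability pair
#'
#' @param Pf,Pb Arrays of per-pixel probabilities; must be congruent, lie in
#'   `[0, 1]` and satisfy `Pf + Pb = 1` elementwise (tolerance `1e-9`).
#' @return Object of class `probability_pair`.
#' @export
probability_pair <- function(Pf, Pb = NULL) {
  Pf <- as.array(Pf)
  if (is.null(Pb)) Pb <- 1 - Pf
  Pb <- as.array(Pb)
  if (!identical(dim(Pf), dim(Pb))) {
    stop("Pf and Pb must have identical shape", call. = FALSE)
  }
  if (any(Pf < -1e-9) || any(Pf > 1 + 1e-9)) {
    stop("Pf outside [0, 1]", call. = FALSE)
  }
  if (max(abs(Pf + Pb - 1)) > 1e-9) {
    stop("Pf + Pb must equal 1 elementwise", call. = FALSE)
  }
  structure(list(Pf = Pf, Pb = Pb), class = "probability_pair")
}

gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  blur2d <- function(m) {
    # pad so EBImage's circular filtering does not wrap content
    pad <- ceiling(3 * sigma)
    pm <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
    pm[] <- mean(m)
    pm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
    # replicate edges into the pad
    pm[seq_len(pad), ] <- pm[rep(pad + 1L, pad), ]
    pm[pad + nrow(m) + seq_len(pad), ] <- pm[rep(pad + nrow(m), pad), ]
    pm[, seq_len(pad)] <- pm[, rep(pad + 1L, pad)]
    pm[, pad + ncol(m) + seq_len(pad)] <- pm[, rep(pad + ncol(m), pad)]
    sm <- EBImage::gblur(pm, sigma = sigma)
    sm[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
  }
  if (length(d) == 2L) return(blur2d(arr))
  out <- arr
  for (z in seq_len(d[1L])) out[z, , ] <- blur2d(arr[z, , ])
  out
}

#' Baseline initial segmenter
#'
#' A deterministic, non-learned stand-in for the initial-segmentation stage:
#' the foreground probability is a convex mix of the click cue map and an
#' intensity-similarity term.  Seed statistics (mean and standard deviation)
#' are taken from pixels where the cue is essentially 1 (`cue >= 0.99`,
#' i.e. the clicked pixels and their free-to-reach neighbourhood);
#' similarity is `exp(-(I - mu)^2 / (2 s^2))`, Gaussian-smoothed.  Any
#' learned model honouring the same (image, cue) -> probability-pair
#' contract can be substituted via [run_initial()]'s `segmenter` argument.
#'
#' @param img Cropped [intensity_image()].
#' @param cue [egd_cue_map()] congruent with `img`.
#' @param smooth_sigma Gaussian sigma (pixels) applied to the similarity
#'   term; 0 disables smoothing.
#' @param mix_weight Weight of the cue map in the mix, in `[0, 1]`.
#' @return A [probability_pair()].
#' @export
baseline_predict <- function(img, cue, smooth_sigma = 2, mix_weight = 0.5) {
  img <- as_image(img)
  cue <- unclass(as.array(cue))
  if (!identical(dim(img$values), dim(cue))) {
    stop("image and cue map must be congruent", call. = FALSE)
  }
  if (all(cue == 0)) {
    return(probability_pair(array(0.5, dim = dim(cue))))
  }
  seedpix <- img$values[cue >= 0.99]
  if (length(seedpix) == 0L) {
    return(probability_pair(pmin(pmax(cue, 0), 1)))
  }
  mu <- mean(seedpix)
  s <- stats::sd(seedpix)
  if (!is.finite(s) || s < 1e-8) {
    rng <- diff(range(img$values))
    s <- max(1e-3 * rng, 1e-8)
  }
  sim <- exp(-(img$values - mu)^2 / (2 * s^2))
  sim <- gaussian_smooth(sim, smooth_sigma)
  Pf <- pmin(pmax(mix_weight * cue + (1 - mix_weight) * sim, 0), 1)
  probability_pair(array(Pf, dim = dim(cue)))
}

#' Look up a registered segmenter by name
#'
#' @param name Currently `"baseline"`.
#' @return A function `(img, cue, ...) -> probability_pair`.
#' @export
segmenter_fn <- function(name = "baseline") {
  switch(name,
    baseline = baseline_predict,
    stop("unknown segmenter: ", name, call. = FALSE)
  )
}
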