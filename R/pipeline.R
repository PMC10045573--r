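#' Pipeline run configuration
#'
#' @param segmenter Name of the initial segmenter (see [segmenter_fn()]).
#' @param segmenter_args Extra arguments passed to the segmenter.
#' @param connectivity Pixel-graph connectivity for cue maps and the CRF
#'   (`NULL` = 8 in 2D / 26 in 3D).
#' @param expand Relaxed-bounding-box expansion in pixels.
#' @param crf [crf_params()] for the refinement stage.
#' @param threshold Probability threshold for the initial mask.
#' @param normalize_to Target interval for the per-crop min-max
#'   normalization applied before cue computation, or `NULL` to skip.
#' @return A `run_config` list.
#' @export
run_config <- function(segmenter = "baseline", segmenter_args = list(),
                       connectivity = NULL, expand = 5,
                       crf = crf_params(), threshold = 0.5,
                       normalize_to = c(0, 1)) {
  structure(list(segmenter = segmenter, segmenter_args = segmenter_args,
                 connectivity = connectivity, expand = expand, crf = crf,
                 threshold = threshold, normalize_to = normalize_to),
            class = "run_config")
}

#' Initial interactive segmentation from inner-margin clicks
#'
#' Phase one of the two-phase flow: the foreground clicks define a relaxed
#' bounding box; the crop is min-max normalized, the clicks are encoded as
#' an EGD cue map, the segmenter turns (crop, cue) into a probability
#' pair, and thresholding gives the initial mask (pasted back into the
#' full frame).
#'
#' @param img Full-frame [intensity_image()].
#' @param clicks [click_set()] with at least one foreground click.
#' @param config [run_config()].
#' @return A `geoclick_session` holding the crop, probabilities, cue map,
#'   clicks, and the initial full-frame mask in `$masks[[1]]`.
#' @export
run_initial <- function(img, clicks, config = run_config()) {
  img <- as_image(img)
  if (is.null(clicks$fg) || nrow(clicks$fg) == 0L) {
    stop("initial segmentation needs foreground clicks", call. = FALSE)
  }
  box <- relaxed_bbox(clicks, expand = config$expand,
                      image_shape = dim(img$values))
  sub <- crop(img, box)
  work <- if (is.null(config$normalize_to)) sub else
    normalize_intensity(sub, config$normalize_to[1L], config$normalize_to[2L])
  local_clicks <- clicks_in_box(clicks, box)
  cue <- egd_cue_map(work, local_clicks$fg, config$connectivity)
  seg <- segmenter_fn(config$segmenter)
  P <- do.call(seg, c(list(work, cue), config$segmenter_args))
  mask_crop <- binary_mask(P$Pf >= config$threshold)
  full <- binary_mask(array(0L, dim = dim(img$values)))
  full <- paste_into(full, mask_crop, box)
  structure(
    list(image = img, box = box, crop = work, crop_raw = sub, cue = cue,
         P = P, clicks = clicks, config = config,
         masks = list(full), energies = numeric(0),
         click_log = list(clicks)),
    class = "geoclick_session"
  )
}

#' @export
print.geoclick_session <- function(x, ...) {
  cat("<geoclick_session> ", length(x$masks), " round(s), ",
      n_clicks(x$clicks), " cumulative clicks, crop ",
      paste(dim(x$crop$values), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' One refinement round from correction clicks
#'
#' Adds the new clicks to the cumulative set, derives refinement cue maps
#' and the fusion weight from geodesic distances to the clicks, fuses them
#' with the *original* initial probabilities, and solves the hard-
#' constrained CRF by graph cut.  The refined full-frame mask and its CRF
#' energy are appended to the session; with no new clicks the mask is
#' unchanged.
#'
#' @param session A `geoclick_session` from [run_initial()].
#' @param new_clicks [click_set()] of correction clicks (full-frame
#'   coordinates); may be empty.
#' @return The updated session.
#' @export
run_refine <- function(session, new_clicks = click_set()) {
  stopifnot(inherits(session, "geoclick_session"))
  config <- session$config
  session$clicks <- merge_clicks(session$clicks, new_clicks)
  session$click_log <- c(session$click_log, list(new_clicks))
  # cue maps come from the cumulative *correction* clicks (the initial
  # inner-margin clicks already shaped P through the first-phase cue map);
  # the hard label constraints cover every clicked pixel, initial included.
  local_all <- clicks_in_box(session$clicks, session$box)
  correction <- Reduce(merge_clicks, session$click_log[-1L], click_set())
  local_corr <- clicks_in_box(correction, session$box)
  # distances and CRF contrast run on the raw-intensity crop: in raw units
  # the image noise keeps each click's geodesic influence local, which is
  # the fusion rule's intent (probabilities far from clicks stay unaltered)
  maps <- refinement_cue_maps(session$crop_raw, local_corr,
                              connectivity = config$connectivity)
  R <- fuse_probabilities(session$P, maps)
  refined <- graph_cut_refine(R, session$crop_raw, local_all, config$crf)
  energy <- crf_energy(refined, R, session$crop_raw, local_all, config$crf)
  full <- binary_mask(array(0L, dim = dim(session$image$values)))
  full <- paste_into(full, refined, session$box)
  session$masks <- c(session$masks, list(full))
  session$energies <- c(session$energies, energy)
  session$R <- R
  session
}

#' Current mask of a session
#'
#' @param session A `geoclick_session`.
#' @return The latest full-frame [binary_mask()].
#' @export
session_mask <- function(session) {
  session$masks[[length(session$masks)]]
}

#' Classify the segmented crop
#'
#' The session's bounding-box crop is resized to the canonical 128 x 64
#' window, described by the selective-bin HOG descriptor, and labeled by
#' the trained ELM.
#'
#' @param session A `geoclick_session`.
#' @param model A trained `elm_model`.
#' @param ... Passed to [hog_descriptor()] (e.g. a block mask).
#' @return Integer label (0 = no tumour, 1 = tumour for binary models).
#' @export
run_classify <- function(session, model, ...) {
  if (is.null(model$beta)) stop("model has no output weights", call. = FALSE)
  v <- session$crop$values
  if (length(dim(v)) == 3L) {
    # classify the central slice of a 3D crop
    v <- v[ceiling(dim(v)[1L] / 2), , ]
  }
  feat <- hog_feature_matrix(list(v), ...)
  as.integer(elm_predict(model, feat))
}

label_components_2d <- function(mask) {
  m <- mask_values(binary_mask(mask))
  EBImage::bwlabel(m)
}

#' Oracle correction clicks from ground truth
#'
#' Emulates an ideal user's refinement round: one foreground click at the
#' most interior pixel of the largest false-negative component and one
#' background click at the most interior pixel of the largest
#' false-positive component (components below `min_size` pixels are left
#' alone).  2D only.
#'
#' @param pred Current predicted [binary_mask()].
#' @param truth Ground-truth [binary_mask()].
#' @param min_size Smallest error component worth a click.
#' @return A [click_set()] (possibly empty when the masks agree).
#' @export
simulate_correction_clicks <- function(pred, truth, min_size = 4L) {
  p <- mask_values(binary_mask(pred))
  g <- mask_values(binary_mask(truth))
  stopifnot(length(dim(p)) == 2L)
  pick <- function(err) {
    if (sum(err) == 0L) return(NULL)
    lab <- label_components_2d(err)
    sizes <- tabulate(lab[lab > 0L])
    if (max(sizes) < min_size) return(NULL)
    comp <- lab == which.max(sizes)
    dm <- EBImage::distmap(matrix(as.numeric(comp), nrow(comp)))
    which(dm == max(dm), arr.ind = TRUE)[1L, , drop = FALSE]
  }
  fg <- pick(g == 1L & p == 0L)   # missed tumour -> foreground click
  bg <- pick(g == 0L & p == 1L)   # spurious region -> background click
  click_set(fg = fg, bg = bg)
}
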