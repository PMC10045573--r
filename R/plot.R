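need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

array_to_df <- function(m, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value_name]] <- as.numeric(m)
  df
}

#' Plot an image slice with optional mask overlays
#'
#' @param img [intensity_image()] or matrix (3D input: central slice).
#' @param truth,pred Optional [binary_mask()]s drawn as contour-style
#'   overlays.
#' @return A ggplot object.
#' @export
plot_slice <- function(img, truth = NULL, pred = NULL) {
  need_ggplot()
  v <- if (is_image(img)) img$values else as.matrix(img)
  if (length(dim(v)) == 3L) v <- v[ceiling(dim(v)[1L] / 2), , ]
  df <- array_to_df(v, "intensity")
  p <- ggplot2::ggplot(df, ggplot2::aes(col, row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  add_mask <- function(p, mask, colour) {
    m <- mask_values(binary_mask(mask))
    if (length(dim(m)) == 3L) m <- m[ceiling(dim(m)[1L] / 2), , ]
    mdf <- array_to_df(m, "m")
    mdf <- mdf[mdf$m == 1, ]
    p + ggplot2::geom_tile(data = mdf, fill = NA, colour = colour,
                           linewidth = 0.1)
  }
  if (!is.null(truth)) p <- add_mask(p, truth, "green")
  if (!is.null(pred)) p <- add_mask(p, pred, "red")
  p
}

#' Plot the convergence trace of a COA run
#'
#' @param fit A `coa_fit` from [coa_minimize()].
#' @return A ggplot object (log-scaled fitness axis).
#' @export
plot_convergence <- function(fit) {
  need_ggplot()
  df <- tidy(fit)
  ggplot2::ggplot(df,
                  ggplot2::aes(iteration, best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best-so-far fitness")
}
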