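#' Read a medical image from disk
#'
#' Supported containers: a directory of single-frame DICOM slices (sorted by
#' InstanceNumber), a NIfTI volume (`.nii` / `.nii.gz`), or an 8/16-bit
#' greyscale PNG.  Spacing is taken from file metadata when present and
#' defaults to unit spacing otherwise.
#'
#' @param path File (PNG/NIfTI) or directory (DICOM series) path.
#' @param format `"auto"` (from the extension / directory-ness) or one of
#'   `"png"`, `"nifti"`, `"dicom"`.
#' @return An [intensity_image()]; 2D for PNG or single-slice input, 3D
#'   (slice, row, column) for DICOM series and NIfTI volumes.
#' @export
read_image <- function(path, format = c("auto", "png", "nifti", "dicom")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    png = read_png_image(path),
    nifti = read_nifti_image(path),
    dicom = read_dicom_series(path)
  )
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom")
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  low <- tolower(path)
  if (grepl("\\.png$", low)) return("png")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.dcm$", low)) return("dicom")
  stop("cannot infer image format for ", path, call. = FALSE)
}

read_png_image <- function(path) {
  raw <- tryCatch(png::readPNG(path, info = TRUE), error = function(e) {
    stop("unreadable PNG file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  info <- attr(raw, "info")
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]  # drop colour channels
  bits <- if (!is.null(info)) info$bit.depth else 8
  scale <- if (isTRUE(all.equal(as.numeric(bits), 16))) 65535 else 255
  vals <- round(raw * scale)
  attributes(vals) <- list(dim = dim(raw))
  intensity_image(vals)
}

read_nifti_image <- function(path) {
  vol <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop("unreadable NIfTI file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  arr <- as.array(vol)
  pix <- RNifti::niftiHeader(vol)$pixdim
  nd <- length(dim(arr))
  spacing <- pix[seq_len(nd) + 1L]
  if (nd == 3L) {
    # NIfTI stores x,y,z fastest-first; present as (slice, row, col)
    arr <- aperm(arr, c(3L, 2L, 1L))
    spacing <- rev(spacing)
  } else if (nd == 2L) {
    arr <- t(arr)
    spacing <- rev(spacing)
  } else {
    stop("only 2D/3D NIfTI supported, got ", nd, " dims", call. = FALSE)
  }
  spacing[!is.finite(spacing) | spacing <= 0] <- 1
  intensity_image(arr, spacing = spacing)
}

#' Write an image to disk
#'
#' Inverse of [read_image()] for the same three containers.  PNG output is
#' 8-bit (integer values in `[0, 255]`; 16-bit PNGs are read, not written);
#' NIfTI and DICOM store the values as given (DICOM as unsigned 16-bit
#' integers).
#'
#' @param img [intensity_image()] or matrix/array.
#' @param path Output file path (directory for a DICOM series).
#' @param format One of `"png"`, `"nifti"`, `"dicom"`; `"auto"` infers from
#'   the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path,
                        format = c("auto", "png", "nifti", "dicom")) {
  format <- match.arg(format)
  img <- as_image(img)
  if (format == "auto") {
    low <- tolower(path)
    format <- if (grepl("\\.png$", low)) "png"
      else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
      else "dicom"
  }
  switch(format,
    png = {
      # 8-bit output; 16-bit PNGs are supported on the read side only
      stopifnot(length(dim(img$values)) == 2L)
      v <- img$values
      if (min(v) < 0 || max(v) > 255) {
        stop("PNG output expects values in [0, 255]", call. = FALSE)
      }
      png::writePNG(v / 255, target = path, dpi = NULL)
    },
    nifti = {
      arr <- img$values
      nd <- length(dim(arr))
      spacing <- img$spacing
      if (nd == 3L) {
        arr <- aperm(arr, c(3L, 2L, 1L))
        spacing <- rev(spacing)
      } else {
        arr <- t(arr)
        spacing <- rev(spacing)
      }
      vol <- RNifti::asNifti(arr)
      RNifti::pixdim(vol) <- spacing
      RNifti::writeNifti(vol, file = path, datatype = "double")
    },
    dicom = write_dicom_series(img, path)
  )
  invisible(path)
}

#' Read a binary mask from disk
#'
#' Same containers as [read_image()]; any nonzero value is foreground.
#'
#' @inheritParams read_image
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, format = c("auto", "png", "nifti", "dicom")) {
  binary_mask(read_image(path, format)$values != 0)
}
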