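# Minimal DICOM (PS3.10) support: uncompressed, Explicit VR Little Endian,
# single-frame MONOCHROME2 slices with 16-bit unsigned pixels.  Enough to
# round-trip the CT-style series this package works with; not a general
# DICOM implementation.

dcm_short_vrs <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD",
                   "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                   "UI", "UL", "US")

dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1L))

dcm_raw16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

dcm_raw32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_encode_element <- function(group, elem, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    if (length(payload) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      payload <- c(payload, pad)
    }
  }
  head <- c(dcm_raw16(group), dcm_raw16(elem), charToRaw(vr))
  if (vr %in% dcm_short_vrs) {
    c(head, dcm_raw16(length(payload)), payload)
  } else {
    c(head, as.raw(c(0L, 0L)), dcm_raw32(length(payload)), payload)
  }
}

dcm_us <- function(group, elem, value) {
  dcm_encode_element(group, elem, "US", dcm_raw16(value))
}

# Write one slice matrix as a Part-10 file.
write_dicom_slice <- function(values, path, instance, spacing_rc,
                              slice_thickness) {
  if (min(values) < 0 || max(values) > 65535 ||
      any(values != round(values))) {
    stop("DICOM output expects integer values in [0, 65535]", call. = FALSE)
  }
  rows <- nrow(values)
  cols <- ncol(values)
  pix <- as.integer(t(values))  # DICOM pixel order: row by row
  pix_raw <- as.raw(rbind(pix %% 256L, pix %/% 256L))

  meta <- c(
    dcm_encode_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(
    dcm_encode_element(0x0002, 0x0000, "UL", dcm_raw32(length(meta))),
    meta
  )
  body <- c(
    dcm_encode_element(0x0008, 0x0060, "CS", "CT"),
    dcm_encode_element(0x0018, 0x0050, "DS", format(slice_thickness)),
    dcm_encode_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, rows),
    dcm_us(0x0028, 0x0011, cols),
    dcm_encode_element(0x0028, 0x0030, "DS",
                       paste(format(spacing_rc), collapse = "\\")),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_us(0x0028, 0x0101, 16L),
    dcm_us(0x0028, 0x0102, 15L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_encode_element(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

write_dicom_series <- function(img, dir_path) {
  img <- as_image(img)
  v <- img$values
  if (length(dim(v)) == 2L) v <- array(v, dim = c(1L, dim(v)))
  sp <- img$spacing
  if (length(sp) == 2L) sp <- c(1, sp)
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  for (z in seq_len(dim(v)[1L])) {
    write_dicom_slice(v[z, , ], file.path(dir_path, sprintf("%04d.dcm", z)),
                      instance = z, spacing_rc = sp[2:3],
                      slice_thickness = sp[1L])
  }
  invisible(dir_path)
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  }
  pos <- 133L
  tags <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_uint(raw[pos:(pos + 1L)])
    elem <- dcm_uint(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% dcm_short_vrs) {
      len <- dcm_uint(raw[(pos + 6L):(pos + 7L)])
      data_start <- pos + 8L
    } else {
      len <- dcm_uint(raw[(pos + 8L):(pos + 11L)])
      data_start <- pos + 12L
    }
    if (!is.finite(len) || data_start + len - 1L > n) {
      stop("corrupt DICOM element in ", path, call. = FALSE)
    }
    payload <- if (len > 0L) raw[data_start:(data_start + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, payload = payload)
    pos <- data_start + len
  }
  tags
}

dcm_tag_string <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) return(default)
  trimws(rawToChar(t$payload))
}

dcm_tag_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) stop("missing required DICOM tag ", key, call. = FALSE)
  dcm_uint(t$payload[1:2])
}

read_dicom_slice <- function(path) {
  tags <- parse_dicom_file(path)
  rows <- dcm_tag_us(tags, "0028,0010")
  cols <- dcm_tag_us(tags, "0028,0011")
  bits <- dcm_tag_us(tags, "0028,0100")
  if (bits != 16L) {
    stop("only 16-bit DICOM pixel data supported (", path, ")", call. = FALSE)
  }
  px <- tags[["7FE0,0010"]]
  if (is.null(px) || length(px$payload) != 2L * rows * cols) {
    stop("corrupt DICOM pixel data in ", path, call. = FALSE)
  }
  ints <- as.integer(px$payload)
  vals <- ints[seq(1L, length(ints), by = 2L)] +
    256L * ints[seq(2L, length(ints), by = 2L)]
  m <- t(matrix(vals, nrow = cols, ncol = rows))
  spacing <- dcm_tag_string(tags, "0028,0030")
  spacing <- if (is.null(spacing)) c(1, 1)
    else as.numeric(strsplit(spacing, "\\\\")[[1L]])
  thick <- as.numeric(dcm_tag_string(tags, "0018,0050", "1"))
  inst <- as.integer(dcm_tag_string(tags, "0020,0013", "0"))
  list(values = m, spacing = spacing, thickness = thick, instance = inst)
}

read_dicom_series <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.dcm$", full.names = TRUE,
               ignore.case = TRUE)
  } else path
  if (length(files) == 0L) {
    stop("no .dcm files found under ", path, call. = FALSE)
  }
  slices <- lapply(files, read_dicom_slice)
  ord <- order(vapply(slices, `[[`, integer(1), "instance"))
  slices <- slices[ord]
  shapes <- vapply(slices, function(s) dim(s$values), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("DICOM series has mixed slice shapes under ", path, call. = FALSE)
  }
  if (length(slices) == 1L) {
    s <- slices[[1L]]
    return(intensity_image(s$values, spacing = s$spacing))
  }
  arr <- array(0, dim = c(length(slices), dim(slices[[1L]]$values)))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]$values
  s1 <- slices[[1L]]
  intensity_image(arr, spacing = c(s1$thickness, s1$spacing))
}
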