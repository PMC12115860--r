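#' Read and write grayscale spot images
#'
#' Single-channel 8-bit PNG and TIFF are supported. Multi-channel inputs are
#' collapsed to one channel by averaging the color channels (luminance
#' average); a warning reports the conversion. Writing quantizes to the 8-bit
#' grid first, so a write/read round trip reproduces the raster exactly.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_gray_image()`: a [gray_image()] with the path as provenance.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  arr <- switch(file_format(path),
    png = tryCatch(png::readPNG(path), error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)), call. = FALSE)
    }),
    tiff = tryCatch(tiff::readTIFF(path), error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)), call. = FALSE)
    })
  )
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    # drop an alpha channel before averaging color planes
    keep <- if (nch %in% c(2L, 4L)) seq_len(nch - 1L) else seq_len(nch)
    warning(sprintf("'%s' has %d channels; converted to gray by channel average", path, nch))
    arr <- apply(arr[, , keep, drop = FALSE], c(1, 2), mean)
  }
  gray_image(pmin(pmax(arr, 0), 1), provenance = path)
}

#' @rdname read_gray_image
#' @param img A [gray_image()].
#' @export
write_gray_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  m <- as.matrix(quantize_image(img))
  switch(file_format(path),
    png = png::writePNG(m, target = path),
    tiff = tiff::writeTIFF(m, where = path, bits.per.sample = 8L)
  )
  invisible(path)
}

#' Read and write pixel classification masks
#'
#' Masks are single-channel 8-bit images with the palette 0 (background),
#' 128 (diffraction), 255 (main spot).
#'
#' @param classes Integer matrix of pixel class codes (see [pixel-classes]).
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_mask <- function(classes, path) {
  stopifnot(is.matrix(classes), all(classes %in% 0:2))
  palette <- c(0, 128, 255) / 255
  m <- matrix(palette[classes + 1L], nrow(classes), ncol(classes))
  switch(file_format(path),
    png = png::writePNG(m, target = path),
    tiff = tiff::writeTIFF(m, where = path, bits.per.sample = 8L)
  )
  invisible(path)
}

#' @rdname write_mask
#' @return `read_mask()`: an integer matrix of pixel class codes.
#' @export
read_mask <- function(path) {
  img <- suppressWarnings(read_gray_image(path))
  lv <- round(as.matrix(img) * 255)
  classes <- matrix(PX_BACKGROUND, nrow(lv), ncol(lv))
  classes[lv == 128] <- PX_DIFFRACTION
  classes[lv == 255] <- PX_MAIN_SPOT
  if (!all(lv %in% c(0, 128, 255))) {
    warning(sprintf("'%s' holds gray levels outside the mask palette; mapped to background", path))
  }
  storage.mode(classes) <- "integer"
  classes
}

#' Write and read a CSV ring report
#'
#' One record per ring with columns `ring_id`, `center_row`, `center_col`,
#' `inner_radius_px`, `ring_width_px`, `orientation`, `z_relative`.
#'
#' @param stack A [surface_stack()] or the tibble returned by
#'   [generics::tidy()] on one.
#' @param path Output CSV path.
#' @export
write_ring_report <- function(stack, path) {
  tb <- if (inherits(stack, "surface_stack")) generics::tidy(stack) else tibble::as_tibble(stack)
  cols <- c(
    "ring_id", "center_row", "center_col", "inner_radius_px",
    "ring_width_px", "orientation", "z_relative"
  )
  missing <- setdiff(cols, names(tb))
  if (length(missing) > 0) {
    stop(sprintf("ring report misses columns: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(as.data.frame(tb[, cols]), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ring_report
#' @return `read_ring_report()`: a tibble with the report columns.
#' @export
read_ring_report <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read ring report: no such file '%s'", path), call. = FALSE)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '%s' for '%s' (use png or tiff)", ext, path), call. = FALSE)
}
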