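#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of gray values in `[0, 1]` (M rows by
#' N columns, row 1 at the top) with a free-text `provenance` attribute
#' recording where the raster came from (a file path, `"synthetic"`, ...).
#' All other functions in the package consume and produce this container and
#' never mutate their input raster.
#'
#' @param pixels Numeric matrix with all values finite and in `[0, 1]`.
#' @param provenance Free-text tag, e.g. a file path or `"synthetic"`.
#' @return A `gray_image` object (a classed numeric matrix).
#' @examples
#' img <- gray_image(matrix(0.5, 8, 8))
#' dim(img)
#' @export
gray_image <- function(pixels, provenance = "in-memory") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("all gray values must be finite", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 1)) {
    stop("gray values must lie in [0, 1]", call. = FALSE)
  }
  structure(unclass(pixels), class = "gray_image", provenance = as.character(provenance)[1])
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, gray range [%.3f, %.3f], provenance: %s\n",
    nrow(x), ncol(x), min(x), max(x), attr(x, "provenance") %||% "?"
  ))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) {
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  class(m) <- NULL
  m
}

#' Normalize an 8-bit raster to the unit gray scale
#'
#' Maps integer gray values 0--255 linearly onto `[0, 1]` by dividing by 255,
#' the working scale used by every algorithm in the package.
#' `denormalize_image()` inverts the map back to whole 8-bit levels;
#' the round trip is the identity on any 8-bit input.
#'
#' @param raw Matrix of values in `[0, 255]` (integer-valued).
#' @param provenance Provenance tag passed to [gray_image()].
#' @return A [gray_image()] with `pixels = raw / 255`.
#' @examples
#' normalize_image(matrix(c(0, 255, 128, 64), 2, 2))
#' @export
normalize_image <- function(raw, provenance = "in-memory") {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("`raw` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(raw) || any(raw < 0) || any(raw > 255)) {
    stop("raw gray values must lie in [0, 255]", call. = FALSE)
  }
  gray_image(raw / 255, provenance = provenance)
}

#' @rdname normalize_image
#' @param img A [gray_image()].
#' @return `denormalize_image()`: an integer matrix of 8-bit levels.
#' @export
denormalize_image <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  m <- round(as.matrix(img) * 255)
  storage.mode(m) <- "integer"
  m
}

#' Quantize a gray image to the 8-bit grid
#'
#' Snaps every value to the nearest multiple of 1/255, the representable
#' gray levels of the package's 8-bit file formats.
#'
#' @param img A [gray_image()].
#' @return A [gray_image()] on the 8-bit grid.
#' @export
quantize_image <- function(img) {
  gray_image(round(as.matrix(img) * 255) / 255, provenance = attr(img, "provenance"))
}

# Pixel class codes used in classification maps (integer matrices):
# background 0, diffraction 1, main spot 2. Mask files store the 8-bit
# palette 0 / 128 / 255 respectively.
#' Pixel class codes
#'
#' Integer codes used in per-pixel classification maps:
#' `PX_BACKGROUND = 0`, `PX_DIFFRACTION = 1`, `PX_MAIN_SPOT = 2`.
#' Mask files on disk use the 8-bit palette 0 / 128 / 255.
#'
#' @name pixel-classes
#' @export
PX_BACKGROUND <- 0L

#' @rdname pixel-classes
#' @export
PX_DIFFRACTION <- 1L

#' @rdname pixel-classes
#' @export
PX_MAIN_SPOT <- 2L

#' @rdname pixel-classes
#' @param label Character vector of class labels.
#' @export
pixel_class_code <- function(label) {
  codes <- c(background = PX_BACKGROUND, diffraction = PX_DIFFRACTION, main_spot = PX_MAIN_SPOT)
  out <- codes[match(label, names(codes))]
  if (anyNA(out)) stop("unknown pixel class label", call. = FALSE)
  unname(out)
}

#' @rdname pixel-classes
#' @param code Integer vector of class codes.
#' @export
pixel_class_label <- function(code) {
  labels <- c("background", "diffraction", "main_spot")
  if (any(!code %in% 0:2)) stop("unknown pixel class code", call. = FALSE)
  labels[code + 1L]
}

#' Convert a gray image to a long tibble
#'
#' One row per pixel with columns `row`, `col`, `value`; convenient for
#' dplyr summaries and ggplot2 rasters.
#'
#' @param x A [gray_image()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value`.
#' @export
as_tibble.gray_image <- function(x, ...) {
  m <- as.matrix(x)
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
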