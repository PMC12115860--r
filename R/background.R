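#' Local-mean background model
#'
#' The background gray level at a pixel is predicted as the equal-weight mean
#' of the 40 pixels that lie inside the 7x7 window centred on the pixel but
#' outside its 3x3 neighbourhood. A pixel whose residual (actual minus
#' predicted gray) exceeds `tau_e` is flagged as a target (spot) pixel; at
#' this stage no distinction is made between main-spot and diffraction
#' pixels. Near the image border the offset set is clipped to in-bounds
#' pixels and the weight rescaled so the weights still sum to one.
#'
#' @param tau_e Residual threshold in normalized gray units, in `(0, 1)`.
#'   Default 0.08: safely below the dimmest ring contrast the synthetic
#'   scenes produce (about 0.1) yet above background noise.
#' @param min_component_px Connected components of the target mask smaller
#'   than this are discarded as noise (default 20).
#' @param merge_radius Components closer than `2 * merge_radius` pixels are
#'   merged into one spot interval (default 8). This absorbs diffraction
#'   debris and the hollow inner/outer edge traces of a wide ring (the
#'   local-mean screen flags only pixels near edges of structures wider than
#'   its 7x7 window) while keeping well-separated nested rings distinct.
#' @return A `background_model` object.
#' @export
background_model <- function(tau_e = 0.08, min_component_px = 20L, merge_radius = 8L) {
  stopifnot(is.numeric(tau_e), length(tau_e) == 1, tau_e > 0, tau_e < 1)
  stopifnot(min_component_px >= 1, merge_radius >= 0)
  offs <- sj_offsets()
  structure(
    list(
      offsets = offs,
      weight = 1 / nrow(offs),
      tau_e = tau_e,
      min_component_px = as.integer(min_component_px),
      merge_radius = as.integer(merge_radius)
    ),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> |Sj| = %d, W = 1/%d, tau_e = %g, min_component_px = %d, merge_radius = %d\n",
    nrow(x$offsets), nrow(x$offsets), x$tau_e, x$min_component_px, x$merge_radius
  ))
  invisible(x)
}

#' Offsets of the background pixel set Sj
#'
#' The 7x7 window minus the 3x3 core: 49 - 9 = 40 offsets `(l, k)` with
#' `|l| <= 3`, `|k| <= 3` and not both `|l| <= 1` and `|k| <= 1`.
#'
#' @return A 40-row matrix with columns `l` (row offset) and `k` (column offset).
#' @export
sj_offsets <- function() {
  grid <- expand.grid(l = -3:3, k = -3:3)
  grid <- grid[!(abs(grid$l) <= 1 & abs(grid$k) <= 1), ]
  as.matrix(grid[, c("l", "k")])
}

#' Predict the local background gray level
#'
#' Computes `Y(m, n) = sum W(l, k) f(m - l, n - k)` over the offset set Sj
#' for every pixel (or one pixel). At the border, out-of-bounds offsets are
#' dropped and the weight rescaled to the surviving count.
#'
#' @param img A [gray_image()].
#' @param model A [background_model()].
#' @param pixel Optional `c(row, col)` (1-based); if given, the scalar
#'   prediction at that pixel is returned instead of the full matrix.
#' @return Numeric matrix of predictions (or a scalar if `pixel` is given).
#' @export
predict_background <- function(img, model = background_model(), pixel = NULL) {
  stopifnot(inherits(img, "gray_image"), inherits(model, "background_model"))
  f <- as.matrix(img)
  M <- nrow(f); N <- ncol(f)
  acc <- matrix(0, M, N)
  cnt <- matrix(0, M, N)
  for (i in seq_len(nrow(model$offsets))) {
    l <- model$offsets[i, 1L]; k <- model$offsets[i, 2L]
    # target rows m where the source row m - l is in bounds
    mr <- max(1L, 1L + l):min(M, M + l)
    nc <- max(1L, 1L + k):min(N, N + k)
    acc[mr, nc] <- acc[mr, nc] + f[mr - l, nc - k, drop = FALSE]
    cnt[mr, nc] <- cnt[mr, nc] + 1
  }
  y <- acc / cnt
  if (is.null(pixel)) y else y[pixel[1], pixel[2]]
}

#' Residual of a pixel against its predicted background
#'
#' `E(m, n) = f(m, n) - Y(m, n)`; a large positive residual marks a spot
#' pixel.
#'
#' @inheritParams predict_background
#' @return Numeric matrix of residuals in `[-1, 1]` (or a scalar).
#' @export
residual_background <- function(img, model = background_model(), pixel = NULL) {
  y <- predict_background(img, model)
  e <- as.matrix(img) - y
  if (is.null(pixel)) e else e[pixel[1], pixel[2]]
}

#' Flag target (spot) pixels against the predicted background
#'
#' A pixel is a target pixel when its residual exceeds `tau_e`. Both
#' main-spot and diffraction pixels are flagged here; they are separated
#' later by the gradient classifier.
#'
#' @inheritParams predict_background
#' @return Logical matrix, `TRUE` at target pixels.
#' @export
screen_targets <- function(img, model = background_model()) {
  residual_background(img, model) > model$tau_e
}

#' Detect rectangular spot intervals from a target mask
#'
#' Labels the 8-connected components of the mask, discards components
#' smaller than `min_component_px`, merges components whose pixel sets lie
#' within `2 * merge_radius` of each other, and returns one rectangular
#' interval per surviving group, ordered by decreasing radial extent. The
#' number of intervals is the number of imaged reflective surfaces the
#' screen can distinguish.
#'
#' @param mask Logical matrix from [screen_targets()].
#' @param model A [background_model()] supplying `min_component_px` and
#'   `merge_radius`.
#' @return A tibble with one row per interval: `surface_index` (1 =
#'   radially smallest, i.e. closest to focus), `row_min`, `row_max`,
#'   `col_min`, `col_max` (1-based, inclusive), `n_px`, `extent_px`.
#' @export
detect_spot_intervals <- function(mask, model = background_model()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  empty <- tibble::tibble(
    surface_index = integer(), row_min = integer(), row_max = integer(),
    col_min = integer(), col_max = integer(), n_px = integer(), extent_px = integer()
  )
  if (!any(mask)) return(empty)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= model$min_component_px)
  if (length(keep) == 0L) return(empty)
  lab[!(lab %in% keep)] <- 0L

  # proximity merge: components within 2 * merge_radius share a dilated blob
  group <- seq_along(sizes)
  if (model$merge_radius > 0L) {
    brush <- EBImage::makeBrush(2L * model$merge_radius + 1L, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(matrix(as.numeric(lab > 0L), nrow(lab), ncol(lab))), brush)
    dlab <- label_components8(matrix(dil > 0, nrow(lab), ncol(lab)))
    for (cmp in keep) {
      px <- which(lab == cmp)[1]
      group[cmp] <- dlab[px]
    }
  }

  boxes <- lapply(unique(group[keep]), function(g) {
    members <- keep[group[keep] == g]
    idx <- which(lab %in% members)
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    tibble::tibble(
      row_min = min(rows), row_max = max(rows),
      col_min = min(cols), col_max = max(cols),
      n_px = length(idx)
    )
  })
  out <- dplyr::bind_rows(boxes)
  # the interval is an approximate spot-encompassing region: pad by the
  # adhesion scale so dim spot fringes (and clinging speckle) are covered
  out$row_min <- pmax(1L, out$row_min - model$merge_radius)
  out$row_max <- pmin(nrow(mask), out$row_max + model$merge_radius)
  out$col_min <- pmax(1L, out$col_min - model$merge_radius)
  out$col_max <- pmin(ncol(mask), out$col_max + model$merge_radius)
  out$extent_px <- pmax(out$row_max - out$row_min, out$col_max - out$col_min) + 1L
  out <- dplyr::arrange(out, dplyr::desc(.data$extent_px), dplyr::desc(.data$n_px))
  out$surface_index <- rev(seq_len(nrow(out)))
  out[, c("surface_index", "row_min", "row_max", "col_min", "col_max", "n_px", "extent_px")]
}

# Sj-window mean over a restricted (background-only) pixel set; NA where the
# window holds no such pixel.
background_restricted_mean <- function(f, use, model) {
  M <- nrow(f); N <- ncol(f)
  acc <- matrix(0, M, N)
  cnt <- matrix(0, M, N)
  fu <- f * use
  for (i in seq_len(nrow(model$offsets))) {
    l <- model$offsets[i, 1L]; k <- model$offsets[i, 2L]
    mr <- max(1L, 1L + l):min(M, M + l)
    nc <- max(1L, 1L + k):min(N, N + k)
    acc[mr, nc] <- acc[mr, nc] + fu[mr - l, nc - k, drop = FALSE]
    cnt[mr, nc] <- cnt[mr, nc] + use[mr - l, nc - k, drop = FALSE]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  M <- nrow(lab); N <- ncol(lab)
  for (dc in c(-1L, 1L)) {
    a <- lab[1:(M - 1L), intersect(seq_len(N), seq_len(N) + dc) , drop = FALSE]
    b <- lab[2:M, intersect(seq_len(N), seq_len(N) - dc), drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    for (h in hit) union2(a[h], b[h])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}
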