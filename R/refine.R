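#' Ideal annulus membership mask
#'
#' Pixels whose distance to the optical-axis center lies in `[r, r + d)`
#' and that sit in the ring's half-plane (for a focused point spot the disc
#' of diameter `d`).
#'
#' @param ring A [ring_model()].
#' @param dims Image dimensions `c(M, N)`.
#' @return Logical matrix of the ideal annulus footprint.
#' @export
annulus_mask <- function(ring, dims) {
  M <- dims[1]; N <- dims[2]
  rowd <- matrix(seq_len(M) - ring$center_row, M, N)
  cold <- matrix(seq_len(N) - ring$center_col, M, N, byrow = TRUE)
  rho <- sqrt(rowd^2 + cold^2)
  if (is.na(ring$orientation)) {
    return(rho < ring$ring_width / 2 + 0.5)
  }
  half <- if (ring$orientation == "right") cold >= 0 else cold <= 0
  rho >= ring$inner_radius & rho < outer_radius(ring) & half
}

ring_region <- function(ring, dims, margin = 4L) {
  R <- outer_radius(ring) + margin
  rows <- max(1L, floor(ring$center_row - R)):min(dims[1], ceiling(ring$center_row + R))
  if (is.na(ring$orientation)) {
    cols <- max(1L, floor(ring$center_col - R)):min(dims[2], ceiling(ring$center_col + R))
  } else if (ring$orientation == "right") {
    cols <- max(1L, floor(ring$center_col - margin)):min(dims[2], ceiling(ring$center_col + R))
  } else {
    cols <- max(1L, floor(ring$center_col - R)):min(dims[2], ceiling(ring$center_col + margin))
  }
  reg <- matrix(FALSE, dims[1], dims[2])
  reg[rows, cols] <- TRUE
  reg
}

default_background_value <- function(f, annulus) {
  stats::median(f[!annulus])
}

#' Beautify a degraded ring against its ideal annulus
#'
#' Snaps a de-diffracted but degraded spot to the ideal semi-annulus of its
#' ring model. Pixels in the ring's neighbourhood but outside the ideal
#' annulus are assigned the background gray value (removing burrs and
#' protrusions). In-annulus pixels dimmer than `tau_low` take the gray of
#' the adjacent longitudinal pixel (same column, one row toward the ring's
#' bright center row; on the center row the brighter vertical neighbour);
#' if that reference is itself dimmer than `tau_low` the pixel is set to 1,
#' maximum brightness, so the spot stands out against the background.
#'
#' @param img A [gray_image()].
#' @param ring A reliable or corrected [ring_model()] with `d > 0`.
#' @param tau_low Dim-pixel threshold in `(0, 1)` (default 0.1, just above
#'   the background noise ceiling of the synthetic scenes).
#' @param background_value Gray value for out-of-annulus pixels; default is
#'   the median gray outside the ideal annulus.
#' @param region Logical matrix delimiting where the rules apply; default
#'   is the ring's bounding box plus a 4 px margin.
#' @return A beautified [gray_image()]; idempotent (given a fixed
#'   `background_value`).
#' @export
beautify_ring <- function(img, ring, tau_low = 0.1, background_value = NULL,
                          region = NULL) {
  stopifnot(inherits(img, "gray_image"), inherits(ring, "ring_model"))
  if (is.na(ring$ring_width) || ring$ring_width <= 0) {
    stop("cannot beautify a degenerate ring (d <= 0)", call. = FALSE)
  }
  stopifnot(tau_low > 0, tau_low < 1)
  f <- as.matrix(img)
  annulus <- annulus_mask(ring, dim(f))
  if (is.null(region)) region <- ring_region(ring, dim(f))
  if (is.null(background_value)) background_value <- default_background_value(f, annulus)

  out <- f
  out[region & !annulus] <- background_value

  dim_idx <- which(annulus & f < tau_low, arr.ind = TRUE)
  if (nrow(dim_idx) > 0) {
    cr <- ring$center_row
    for (i in seq_len(nrow(dim_idx))) {
      m <- dim_idx[i, 1]; n <- dim_idx[i, 2]
      towards <- if (m < cr - 0.5) m + 1L else if (m > cr + 0.5) m - 1L else {
        up <- if (m > 1L) f[m - 1L, n] else -Inf
        dn <- if (m < nrow(f)) f[m + 1L, n] else -Inf
        if (up >= dn) m - 1L else m + 1L
      }
      ref <- if (towards >= 1L && towards <= nrow(f)) f[towards, n] else -Inf
      out[m, n] <- if (ref >= tau_low) ref else 1
    }
  }
  gray_image(pmin(pmax(out, 0), 1), provenance = attr(img, "provenance"))
}

#' Beautify every ring of a stack
#'
#' Applies [beautify_ring()] ring by ring while protecting the other
#' rings' annuli (and any focused point spot) from the background
#' assignment, so nested spots survive each other's clean-up.
#'
#' @param img A [gray_image()].
#' @param rings List of [ring_model()]s (a [surface_stack()]'s `rings`).
#' @param tau_low,background_value As in [beautify_ring()];
#'   `background_value` defaults to the median gray outside all annuli.
#' @return A [gray_image()].
#' @export
beautify_rings <- function(img, rings, tau_low = 0.1, background_value = NULL) {
  stopifnot(inherits(img, "gray_image"))
  rings <- purrr::keep(rings, function(r) !is.na(r$ring_width) && r$ring_width > 0)
  if (length(rings) == 0) return(img)
  annuli <- purrr::map(rings, annulus_mask, dims = dim(img))
  total <- Reduce(`|`, annuli)
  if (is.null(background_value)) {
    background_value <- stats::median(as.matrix(img)[!total])
  }
  for (i in seq_along(rings)) {
    if (is.na(rings[[i]]$orientation)) next # point spots are only protected
    others <- total & !annuli[[i]]
    region <- ring_region(rings[[i]], dim(img)) & !others
    img <- beautify_ring(img, rings[[i]],
      tau_low = tau_low, background_value = background_value, region = region
    )
  }
  img
}

#' Trim and fill a spot against the standard annulus
#'
#' Uses the ideal annulus as the standard line: spot mass beyond it is
#' adjusted to the background, and voids inside it (pixels dimmer than
#' `tau_low`) are filled with the mean gray of their 8-connected, in-annulus,
#' non-void neighbours. Filling sweeps alternate top-down and bottom-up
#' until no fillable void remains (at most `max_sweeps` sweeps).
#'
#' @inheritParams beautify_ring
#' @param max_sweeps Maximum fill sweeps (default 100).
#' @return A [gray_image()]; idempotent. A fully void annulus cannot be
#'   filled and is reported with a warning.
#' @export
trim_to_standard_line <- function(img, ring, tau_low = 0.1,
                                  background_value = NULL, region = NULL,
                                  max_sweeps = 100L) {
  stopifnot(inherits(img, "gray_image"), inherits(ring, "ring_model"))
  if (is.na(ring$ring_width) || ring$ring_width <= 0) {
    stop("cannot refine a degenerate ring (d <= 0)", call. = FALSE)
  }
  f <- as.matrix(img)
  annulus <- annulus_mask(ring, dim(f))
  if (is.null(region)) region <- ring_region(ring, dim(f))
  if (is.null(background_value)) background_value <- default_background_value(f, annulus)

  out <- f
  out[region & !annulus] <- background_value

  void <- annulus & out < tau_low
  if (all(void[annulus])) {
    warning("annulus is fully void: nothing to fill from")
    return(gray_image(pmin(pmax(out, 0), 1), provenance = attr(img, "provenance")))
  }
  M <- nrow(f)
  for (sweep in seq_len(max_sweeps)) {
    idx <- which(void, arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    ord <- order(if (sweep %% 2L == 1L) idx[, 1] else -idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    filled_any <- FALSE
    for (i in seq_len(nrow(idx))) {
      m <- idx[i, 1]; n <- idx[i, 2]
      mm <- max(1L, m - 1L):min(M, m + 1L)
      nn <- max(1L, n - 1L):min(ncol(f), n + 1L)
      nb <- annulus[mm, nn] & !void[mm, nn]
      nb[match(m, mm), match(n, nn)] <- FALSE
      if (any(nb)) {
        out[m, n] <- mean(out[mm, nn][nb])
        void[m, n] <- FALSE
        filled_any <- TRUE
      }
    }
    if (!filled_any) break
  }
  gray_image(pmin(pmax(out, 0), 1), provenance = attr(img, "provenance"))
}
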