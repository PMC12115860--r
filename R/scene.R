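#' Synthetic semi-annular autofocus scene specification
#'
#' Describes a synthetic CCD frame of nested semi-annular laser spots with
#' ground truth. Ring geometry follows the defocus proportionality laws by
#' construction: surface `i` at defocus `z_i` is drawn as a half-annulus
#' with inner radius `kappa_r * z_i` and width `kappa_d * z_i` around the
#' shared optical-axis center. Intensity peaks on the center row and falls
#' off as a Gaussian in the vertical offset (the spot center is bright, the
#' upper and lower arm ends dim). Diffraction speckle is drawn as short
#' horizontal runs of chaotic intensity packed into a band hugging the
#' outer side of each ring, giving the rapidly sign-alternating gradients
#' of real speckle; the model is phenomenological, not wave optics.
#'
#' The defaults echo the reference instrument's worked examples: scales of
#' 64 px (radius) and 17 px (width) per defocus unit, two surfaces at
#' defocus ratio 1:2, and 8-bit quantization applied last.
#'
#' @param size `c(M, N)` image size in pixels.
#' @param center `c(row, col)` optical-axis center.
#' @param surfaces Data frame with columns `z` (relative defocus, `>= 0`,
#'   strictly increasing; `z = 0` is a focused surface drawn as a point
#'   spot), `orientation` (`"right"`/`"left"`), `peak` (peak intensity in
#'   `(0, 1]`).
#' @param kappa_r,kappa_d Pixels of inner radius / ring width per defocus
#'   unit.
#' @param vertical_falloff Gaussian sigma (px) of the vertical intensity
#'   falloff; `NULL` (default) scales it to three quarters of the largest
#'   ring's outer radius, leaving the arm ends dim but still screenable.
#' @param speckle_count Diffraction speckles per out-of-focus surface;
#'   `NULL` picks a density that packs the outer band closely (1.2
#'   speckles' worth of pixels per band pixel area unit).
#' @param speckle_width Speckle grain length in px (horizontal).
#' @param speckle_height Speckle grain height in px (vertical, default 2).
#' @param speckle_amplitude Peak speckle intensity (0 disables diffraction).
#' @param outer_band Width (px) of the speckle band outside each ring.
#' @param noise_sigma Additive Gaussian background noise (normalized gray).
#' @param focus_footprint_px Diameter of the focused point spot in px.
#' @param seed Integer seed; rendering is bit-identical under a fixed seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(size = c(360, 200), center = c(180, 12),
                       surfaces = data.frame(z = c(1, 2), orientation = "right", peak = 0.85),
                       kappa_r = 64, kappa_d = 17,
                       vertical_falloff = NULL,
                       speckle_count = NULL, speckle_width = 4, speckle_height = 2,
                       speckle_amplitude = 0.55, outer_band = 12,
                       noise_sigma = 0.004,
                       focus_footprint_px = 2L, seed = 1L) {
  stopifnot(length(size) == 2, size >= 8, length(center) == 2)
  surfaces <- tibble::as_tibble(surfaces)
  if (!"orientation" %in% names(surfaces)) surfaces$orientation <- "right"
  if (!"peak" %in% names(surfaces)) surfaces$peak <- 0.85
  if (is.null(vertical_falloff)) {
    vertical_falloff <- max(0.75 * (kappa_r + kappa_d) * max(surfaces$z), 10)
  }
  stopifnot(
    all(surfaces$z >= 0), !is.unsorted(surfaces$z, strictly = TRUE),
    all(surfaces$peak > 0 & surfaces$peak <= 1),
    kappa_r > 0, kappa_d > 0, vertical_falloff > 0,
    speckle_width >= 1, speckle_height >= 1, speckle_amplitude >= 0,
    outer_band >= 0, noise_sigma >= 0
  )
  spec <- structure(
    list(
      size = as.integer(size), center = as.numeric(center), surfaces = surfaces,
      kappa_r = kappa_r, kappa_d = kappa_d, vertical_falloff = vertical_falloff,
      speckle_count = speckle_count, speckle_width = as.integer(speckle_width),
      speckle_height = as.integer(speckle_height),
      speckle_amplitude = speckle_amplitude, outer_band = outer_band,
      noise_sigma = noise_sigma, focus_footprint_px = as.integer(focus_footprint_px),
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
  # every ring (plus its speckle band) must fit in the frame
  for (i in seq_len(nrow(surfaces))) {
    ext <- (kappa_r + kappa_d) * surfaces$z[i] +
      if (speckle_amplitude > 0) outer_band else 0
    ext <- max(ext, focus_footprint_px)
    fits_rows <- center[1] - ext >= 1 && center[1] + ext <= size[1]
    fits_cols <- if (identical(surfaces$orientation[i], "left")) {
      center[2] - ext >= 1
    } else {
      center[2] + ext <= size[2]
    }
    if (!fits_rows || !fits_cols) {
      stop(sprintf("surface %d (z = %g) exceeds the frame", i, surfaces$z[i]), call. = FALSE)
    }
  }
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d x %d px, center (%g, %g), %d surface(s) at z = %s; kappa_r = %g, kappa_d = %g\n",
    x$size[1], x$size[2], x$center[1], x$center[2], nrow(x$surfaces),
    paste(x$surfaces$z, collapse = ", "), x$kappa_r, x$kappa_d
  ))
  invisible(x)
}

#' Render a synthetic scene with ground truth
#'
#' @param spec A [scene_spec()].
#' @return A list of class `scene` with `image` (a [gray_image()]),
#'   `classes` (ground-truth pixel class matrix), `rings` (list of
#'   ground-truth [ring_model()]s) and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  M <- spec$size[1]; N <- spec$size[2]
  cr <- spec$center[1]; cc <- spec$center[2]
  rowd <- matrix(seq_len(M) - cr, M, N)
  cold <- matrix(seq_len(N) - cc, M, N, byrow = TRUE)
  rho <- sqrt(rowd^2 + cold^2)
  falloff <- exp(-rowd^2 / (2 * spec$vertical_falloff^2))

  img <- matrix(0, M, N)
  classes <- matrix(PX_BACKGROUND, M, N)
  rings <- vector("list", nrow(spec$surfaces))

  for (i in seq_len(nrow(spec$surfaces))) {
    z <- spec$surfaces$z[i]
    ori <- spec$surfaces$orientation[i]
    peak <- spec$surfaces$peak[i]
    if (z == 0) {
      member <- rho < spec$focus_footprint_px / 2 + 0.5
      rings[[i]] <- ring_model(cr, cc, 0, spec$focus_footprint_px,
        orientation = NA, z = 0
      )
    } else {
      r <- spec$kappa_r * z
      d <- spec$kappa_d * z
      half <- if (ori == "left") cold <= 0 else cold >= 0
      member <- rho >= r & rho < r + d & half
      rings[[i]] <- ring_model(cr, cc, r, d, orientation = ori, z = z)
    }
    img[member] <- pmax(img[member], (peak * falloff)[member])
    classes[member] <- PX_MAIN_SPOT
  }

  withr::with_seed(spec$seed, {
    # diffraction speckle: chaotic short runs packed against the outer edge
    if (spec$speckle_amplitude > 0 && spec$outer_band > 0) {
      for (i in seq_len(nrow(spec$surfaces))) {
        z <- spec$surfaces$z[i]
        if (z == 0) next
        ori <- spec$surfaces$orientation[i]
        band_in <- (spec$kappa_r + spec$kappa_d) * z
        band_out <- band_in + spec$outer_band
        count <- spec$speckle_count %||%
          round(1.2 * pi * (band_out^2 - band_in^2) / 2 /
            (spec$speckle_width * spec$speckle_height))
        theta <- stats::runif(count, -pi / 2, pi / 2)
        rr <- sqrt(stats::runif(count, band_in^2, band_out^2))
        srow <- round(cr + rr * sin(theta))
        scol <- round(cc + rr * cos(theta) * if (ori == "left") -1 else 1)
        for (s in seq_len(count)) {
          grows <- srow[s]:(srow[s] + spec$speckle_height - 1L)
          grows <- grows[grows >= 1 & grows <= M]
          cols <- scol[s]:(scol[s] + spec$speckle_width - 1L)
          cols <- cols[cols >= 1 & cols <= N]
          if (length(cols) == 0 || length(grows) == 0) next
          for (gr in grows) {
            # speckle brightness is comparable to the main spot throughout
            # the band, so no vertical dimming is applied to it
            val <- spec$speckle_amplitude * stats::runif(length(cols), 0.5, 1)
            # grains overwrite each other (chaotic texture even when dense)
            # but never the main spot; only visibly bright grain pixels are
            # recorded as planted diffraction in the truth map
            write_to <- classes[gr, cols] != PX_MAIN_SPOT
            img[gr, cols][write_to] <- val[write_to]
            visible <- write_to & val > 0.05
            classes[gr, cols][visible] <- PX_DIFFRACTION
            dimmed <- write_to & val <= 0.05 & classes[gr, cols] == PX_DIFFRACTION
            classes[gr, cols][dimmed] <- PX_BACKGROUND
          }
        }
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(M * N, 0, spec$noise_sigma), M, N)
    }
  })
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255

  structure(
    list(
      image = gray_image(img, provenance = "synthetic"),
      classes = classes,
      rings = rings,
      spec = spec
    ),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  print(x$spec)
  print(x$image)
  invisible(x)
}

#' Minimum resolvable surface separation, raw vs processed
#'
#' Renders a two-surface scene at each trial separation, asks whether the
#' two rings are resolved on the raw frame and again after the cleaning
#' pipeline (screen, de-diffract, beautify), and reports the smallest
#' resolvable separation for each. On the raw frame the rings count as
#' resolved when the center row carries two distinct bright runs (chaotic
#' speckle leaves pinholes in its band, so gaps of up to 4 px are bridged;
#' runs under 3 px are noise) --
#' with speckle hugging the outer edges, the bands bridge the gap long
#' before the rings themselves touch. After processing, the rings measured
#' from the main-spot runs must satisfy the geometric resolvability
#' criterion of [are_rings_resolved()].
#'
#' @param spec A two-surface [scene_spec()] template; the first surface's
#'   defocus is kept, the second is set to `z1 + separation`.
#' @param separations Numeric vector of trial separations (defocus units).
#' @param params A [classifier_params()].
#' @param model A [background_model()].
#' @param raw_tau Bright threshold for the raw-frame run test.
#' @return A list with `grid` (tibble: `separation`, `raw_resolved`,
#'   `processed_resolved`), `raw_min` and `processed_min` (the smallest
#'   resolvable separations; `NA` if none in the grid).
#' @export
resolution_probe <- function(spec, separations,
                             params = classifier_params(),
                             model = background_model(),
                             raw_tau = 0.08) {
  stopifnot(inherits(spec, "scene_spec"), nrow(spec$surfaces) == 2)
  z1 <- spec$surfaces$z[1]
  cr <- round(spec$center[1]); cc <- spec$center[2]

  runs_of <- function(flag, merge_gap, min_len) {
    r <- rle(flag)
    short_gap <- !r$values & r$lengths <= merge_gap
    inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[short_gap & inner] <- TRUE
    r2 <- rle(rep(r$values, r$lengths))
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths + 1L
    keep <- which(r2$values & r2$lengths >= min_len)
    cbind(start = starts[keep], end = ends[keep])
  }

  eval_sep <- function(sep) {
    sp <- spec
    sp$surfaces$z[2] <- z1 + sep
    sc <- tryCatch(render_scene(sp), error = function(e) NULL)
    if (is.null(sc)) {
      return(c(raw = NA, processed = NA))
    }
    raw_runs <- runs_of(as.matrix(sc$image)[cr, ] > raw_tau, 4L, 3L)
    raw_ok <- nrow(raw_runs) >= 2

    mask <- screen_targets(sc$image, model)
    intervals <- detect_spot_intervals(mask, model)
    dd <- dediffract(sc$image, intervals, params, model)
    main_runs <- runs_of(dd$classes[cr, ] == PX_MAIN_SPOT, 0L, 2L)
    proc_ok <- FALSE
    if (nrow(main_runs) >= 2) {
      main_runs <- main_runs[order(main_runs[, "start"]), , drop = FALSE]
      two <- main_runs[c(1, nrow(main_runs)), , drop = FALSE]
      mk_ring <- function(run) {
        ring_model(cr, cc,
          inner_radius = max(0, run["start"] - cc),
          ring_width = run["end"] - run["start"] + 1,
          orientation = "right"
        )
      }
      r_in <- mk_ring(two[1, ]); r_out <- mk_ring(two[2, ])
      img_b <- beautify_rings(dd$cleaned, list(r_in, r_out), background_value = 0)
      b_runs <- runs_of(as.matrix(img_b)[cr, ] > raw_tau, 0L, 2L)
      proc_ok <- nrow(b_runs) >= 2 && are_rings_resolved(r_in, r_out)
    }
    c(raw = raw_ok, processed = proc_ok)
  }

  res <- vapply(separations, eval_sep, c(raw = NA, processed = NA))
  grid <- tibble::tibble(
    separation = separations,
    raw_resolved = as.logical(res["raw", ]),
    processed_resolved = as.logical(res["processed", ])
  )
  min_or_na <- function(ok) {
    hit <- grid$separation[!is.na(ok) & ok]
    if (length(hit) == 0) NA_real_ else min(hit)
  }
  list(
    grid = grid,
    raw_min = min_or_na(grid$raw_resolved),
    processed_min = min_or_na(grid$processed_resolved)
  )
}
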