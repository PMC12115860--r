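#' Semi-annular ring model
#'
#' One semi-annular spot: the half-annulus between radii `r` and `r + d`
#' around the optical-axis center, restricted to the half-plane left or
#' right of the vertical line through the center. The flat side of the
#' half-annulus lies on that line; the arc apex sits on the center row,
#' which is also where the vertical intensity falloff peaks. Both the inner
#' radius `r` and the ring width `d` are proportional to the defocus
#' distance `z` of the reflective surface that produced the spot; `r = 0`
#' with a small `d` represents a focused point spot.
#'
#' @param center_row,center_col Optical-axis center on the image (1-based
#'   pixels; fractional values allowed).
#' @param inner_radius Inner radius `r` in pixels, `>= 0`.
#' @param ring_width Ring width `d` in pixels, `> 0` (may be `NA` for an
#'   unreliable measurement).
#' @param orientation `"right"` or `"left"`: which half-plane holds the
#'   ring; encodes the sign of the defocus. `NA` for a focused point spot.
#' @param reliable Flag set by the measurement stage: `TRUE` when the ring
#'   was measured from an unbroken main-spot run.
#' @param corrected `TRUE` when the width was replaced by the value
#'   predicted from the defocus proportionality.
#' @param z Defocus distance in relative units, if known.
#' @return A `ring_model` object.
#' @export
ring_model <- function(center_row, center_col, inner_radius, ring_width,
                       orientation = "right", reliable = TRUE,
                       corrected = FALSE, z = NA_real_) {
  if (!is.na(orientation) && !orientation %in% c("left", "right")) {
    stop('`orientation` must be "left", "right" or NA', call. = FALSE)
  }
  if (!is.na(inner_radius) && inner_radius < 0) {
    stop("inner radius must be >= 0", call. = FALSE)
  }
  if (!is.na(ring_width) && ring_width <= 0) {
    stop("ring width must be > 0", call. = FALSE)
  }
  structure(
    list(
      center_row = as.numeric(center_row), center_col = as.numeric(center_col),
      inner_radius = as.numeric(inner_radius), ring_width = as.numeric(ring_width),
      orientation = if (is.na(orientation)) NA_character_ else as.character(orientation),
      reliable = isTRUE(reliable),
      corrected = isTRUE(corrected), z = as.numeric(z)
    ),
    class = "ring_model"
  )
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf(
    "<ring_model> center (%.1f, %.1f), r = %.1f px, d = %.1f px, %s%s%s%s\n",
    x$center_row, x$center_col, x$inner_radius, x$ring_width,
    if (is.na(x$orientation)) "point spot" else paste0("opens ", x$orientation),
    if (is.na(x$z)) "" else sprintf(", z = %.3g", x$z),
    if (x$reliable) "" else ", unreliable",
    if (x$corrected) ", corrected" else ""
  ))
  invisible(x)
}

#' Outer radius of a ring
#' @param ring A [ring_model()].
#' @return `r + d` in pixels.
#' @export
outer_radius <- function(ring) ring$inner_radius + ring$ring_width

#' The inner-edge apex of a ring
#'
#' The point of the inner edge on the center row, offset from the
#' optical-axis center by `r` toward the ring's half-plane. As the defocus
#' shrinks to zero this point converges on the focused-spot center, which
#' is what [infer_focus_center()] exploits.
#'
#' @param ring A [ring_model()].
#' @return Numeric `c(row, col)`.
#' @export
inner_apex <- function(ring) {
  s <- if (identical(ring$orientation, "left")) -1 else 1
  c(row = ring$center_row, col = ring$center_col + s * ring$inner_radius)
}

#' Surface stack: rings plus shared defocus scales
#'
#' An ordered set of rings with their relative defocus distances `z_i` and
#' the shared proportionality scales `kappa_r`, `kappa_d` such that
#' `r_i = kappa_r * z_i` and `d_i = kappa_d * z_i`. Only ratios of `z`
#' matter; absolute units require an external calibration constant.
#'
#' @param rings List of [ring_model()] objects, ordered by increasing `z`.
#' @param z Numeric vector of defocus distances, strictly increasing, one
#'   per ring (taken from the rings' own `z` fields if omitted).
#' @param kappa_r,kappa_d Fitted scales (px per z unit); usually filled by
#'   [fit_stack_scales()].
#' @return A `surface_stack` object.
#' @export
surface_stack <- function(rings, z = NULL, kappa_r = NA_real_, kappa_d = NA_real_) {
  stopifnot(is.list(rings), all(vapply(rings, inherits, logical(1), "ring_model")))
  if (is.null(z)) z <- vapply(rings, function(r) r$z, numeric(1))
  stopifnot(length(z) == length(rings))
  if (length(z) > 1 && any(diff(z) <= 0)) {
    stop("defocus distances z must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(rings)) rings[[i]]$z <- z[i]
  structure(
    list(rings = rings, z = as.numeric(z), kappa_r = kappa_r, kappa_d = kappa_d),
    class = "surface_stack"
  )
}

#' @export
print.surface_stack <- function(x, ...) {
  cat(sprintf(
    "<surface_stack> %d surface(s), kappa_r = %.3g, kappa_d = %.3g px per z unit\n",
    length(x$rings), x$kappa_r, x$kappa_d
  ))
  for (r in x$rings) print(r)
  invisible(x)
}

#' Tidy a surface stack into a ring report tibble
#'
#' @param x A [surface_stack()].
#' @param ... Unused.
#' @return A tibble with one row per ring: `ring_id`, `center_row`,
#'   `center_col`, `inner_radius_px`, `ring_width_px`, `orientation`,
#'   `z_relative`, `reliable`, `corrected`.
#' @export
tidy.surface_stack <- function(x, ...) {
  tibble::tibble(
    ring_id = seq_along(x$rings),
    center_row = vapply(x$rings, `[[`, numeric(1), "center_row"),
    center_col = vapply(x$rings, `[[`, numeric(1), "center_col"),
    inner_radius_px = vapply(x$rings, `[[`, numeric(1), "inner_radius"),
    ring_width_px = vapply(x$rings, `[[`, numeric(1), "ring_width"),
    orientation = vapply(x$rings, function(r) as.character(r$orientation %||% NA), character(1)),
    z_relative = x$z,
    reliable = vapply(x$rings, `[[`, logical(1), "reliable"),
    corrected = vapply(x$rings, `[[`, logical(1), "corrected")
  )
}

#' @rdname tidy.surface_stack
#' @return `glance()`: a one-row tibble with `n_surfaces`, `kappa_r`,
#'   `kappa_d`, `n_reliable`, `n_corrected`.
#' @export
glance.surface_stack <- function(x, ...) {
  tibble::tibble(
    n_surfaces = length(x$rings),
    kappa_r = x$kappa_r,
    kappa_d = x$kappa_d,
    n_reliable = sum(vapply(x$rings, `[[`, logical(1), "reliable")),
    n_corrected = sum(vapply(x$rings, `[[`, logical(1), "corrected"))
  )
}

#' Are two nested rings resolved?
#'
#' Two semi-annular spots from the same optical axis are just separated
#' when the inner radius of the outer ring reaches the outer radius of the
#' inner ring: `r2 = r1 + d1`. This boundary (the interlayer resolution)
#' counts as resolved.
#'
#' @param inner,outer Two [ring_model()]s sharing center (within
#'   `center_tol` pixels) and orientation; they are sorted by inner radius
#'   internally.
#' @param center_tol Center agreement tolerance in pixels (default 1).
#' @return `TRUE` iff `r2 >= r1 + d1`.
#' @export
are_rings_resolved <- function(inner, outer, center_tol = 1) {
  stopifnot(inherits(inner, "ring_model"), inherits(outer, "ring_model"))
  if (!identical(inner$orientation, outer$orientation)) {
    stop("rings with different orientations cannot be compared", call. = FALSE)
  }
  if (abs(inner$center_row - outer$center_row) > center_tol ||
      abs(inner$center_col - outer$center_col) > center_tol) {
    stop("rings do not share a center (within tolerance)", call. = FALSE)
  }
  if (inner$inner_radius > outer$inner_radius) {
    tmp <- inner; inner <- outer; outer <- tmp
  }
  outer$inner_radius >= inner$inner_radius + inner$ring_width
}

#' Fit the shared defocus scales of a surface stack
#'
#' The width law `d1 / d2 = z1 / z2` and radius law `r1 / r2 = z1 / z2`
#' imply shared scales `kappa_d = d_i / z_i` and `kappa_r = r_i / z_i`.
#' They are estimated as the median of the per-ring ratios over the rings
#' flagged reliable (median: robust to one badly measured ring, and equal
#' to the trusted ring's ratio when only one ring is reliable).
#'
#' @param rings List of [ring_model()]s.
#' @param z Defocus distances (relative units, `> 0`), one per ring; taken
#'   from the rings if omitted.
#' @return A [surface_stack()] with `kappa_r`, `kappa_d` filled in.
#' @export
fit_stack_scales <- function(rings, z = NULL) {
  if (inherits(rings, "surface_stack")) {
    z <- rings$z
    rings <- rings$rings
  }
  stack <- surface_stack(rings, z)
  rel <- vapply(stack$rings, `[[`, logical(1), "reliable") & stack$z > 0
  if (!any(rel)) {
    stop("cannot fit scales: no reliable ring with z > 0", call. = FALSE)
  }
  d_ratio <- vapply(stack$rings[rel], `[[`, numeric(1), "ring_width") / stack$z[rel]
  r_ratio <- vapply(stack$rings[rel], `[[`, numeric(1), "inner_radius") / stack$z[rel]
  stack$kappa_d <- stats::median(d_ratio)
  stack$kappa_r <- stats::median(r_ratio)
  stack
}

#' Correct ring widths against the defocus proportionality
#'
#' A ring whose measured width deviates from `kappa_d * z` by more than
#' `width_tol` pixels is inconsistent with the width law; its width is
#' replaced by the predicted value and the ring flagged corrected. A
#' typical cause is diffraction-degraded imaging: a ring measured at 25 px
#' where surfaces at defocus ratio 1:2 and a trusted 17 px first ring
#' dictate 34 px.
#'
#' @param stack A [surface_stack()] with fitted scales (see
#'   [fit_stack_scales()]; fitted on the fly if missing).
#' @param width_tol Tolerated deviation in pixels (default 3).
#' @return The corrected [surface_stack()]; idempotent.
#' @export
correct_ring_widths <- function(stack, width_tol = 3) {
  stopifnot(inherits(stack, "surface_stack"))
  if (is.na(stack$kappa_d)) stack <- fit_stack_scales(stack)
  for (i in seq_along(stack$rings)) {
    if (stack$z[i] <= 0) next
    predicted <- stack$kappa_d * stack$z[i]
    measured <- stack$rings[[i]]$ring_width
    if (is.na(measured) || abs(measured - predicted) > width_tol) {
      stack$rings[[i]]$ring_width <- predicted
      stack$rings[[i]]$corrected <- TRUE
    }
  }
  stack
}

#' Extrapolate the focused-spot center from two defocused rings
#'
#' The inner-edge reference points of the rings obey
#' `x_i = c + kappa * z_i` per coordinate, so two rings at distinct
#' defocus distances give the focused-surface spot center
#' `c = (z_b * x_a - z_a * x_b) / (z_b - z_a)` exactly.
#'
#' @param point_a,point_b Numeric reference points of equal length (for a
#'   measured ring, its [inner_apex()]), or [ring_model()]s with `z` set.
#' @param z_a,z_b Defocus distances; `z_a != z_b`.
#' @return Numeric vector `c`, same length as the points.
#' @examples
#' infer_focus_center(c(118, 180), c(182, 180), z_a = 1, z_b = 2) # (54, 180)
#' @export
infer_focus_center <- function(point_a, point_b, z_a = NULL, z_b = NULL) {
  if (inherits(point_a, "ring_model")) {
    z_a <- z_a %||% point_a$z
    point_a <- inner_apex(point_a)
  }
  if (inherits(point_b, "ring_model")) {
    z_b <- z_b %||% point_b$z
    point_b <- inner_apex(point_b)
  }
  stopifnot(length(point_a) == length(point_b), !is.null(z_a), !is.null(z_b))
  if (isTRUE(all.equal(z_a, z_b))) {
    stop("cannot extrapolate a center from equal defocus distances", call. = FALSE)
  }
  unname((z_b * point_a - z_a * point_b) / (z_b - z_a))
}

#' Harmonize a stack onto one shared optical-axis center
#'
#' All rings of a stack share the optical axis, but a fragmented interval
#' can misplace a ring's flat-side (center) estimate while its inner-edge
#' apex stays accurate. Given at least two reliable out-of-focus rings,
#' the shared center is re-derived from their apexes via
#' [infer_focus_center()], every ring's center is replaced by it, and the
#' inner radii are recomputed from the preserved apex positions.
#'
#' @param stack A [surface_stack()] with `z` assigned.
#' @return The harmonized [surface_stack()] (unchanged when fewer than two
#'   reliable out-of-focus rings are available).
#' @export
harmonize_stack_center <- function(stack) {
  stopifnot(inherits(stack, "surface_stack"))
  rel <- which(
    vapply(stack$rings, `[[`, logical(1), "reliable") &
      !is.na(vapply(stack$rings, `[[`, character(1), "orientation")) &
      stack$z > 0
  )
  if (length(rel) < 2) return(stack)
  a <- stack$rings[[rel[1]]]
  b <- stack$rings[[rel[length(rel)]]]
  ctr <- infer_focus_center(inner_apex(a), inner_apex(b), a$z, b$z)
  for (i in seq_along(stack$rings)) {
    ring <- stack$rings[[i]]
    if (is.na(ring$orientation)) next
    apex <- inner_apex(ring)
    ring$center_row <- ctr[1]
    ring$center_col <- ctr[2]
    ring$inner_radius <- as.numeric(abs(apex[2] - ctr[2]))
    stack$rings[[i]] <- ring
  }
  stack
}

#' Estimate the signed defocus distance of a ring
#'
#' The defocus magnitude is the mean of `r / kappa_r` and `d / kappa_d`
#' over whichever scales are available; the sign comes from the ring's
#' orientation under the configured convention.
#'
#' @param ring A [ring_model()].
#' @param kappa_r,kappa_d Scales in px per z unit (at least one).
#' @param positive_orientation Which orientation maps to positive defocus
#'   (default `"right"`; the physical assignment depends on the instrument).
#' @return Signed defocus estimate in the units of `1 / kappa`.
#' @export
defocus_from_ring <- function(ring, kappa_r = NULL, kappa_d = NULL,
                              positive_orientation = "right") {
  stopifnot(inherits(ring, "ring_model"))
  est <- c(
    if (!is.null(kappa_r) && !is.na(kappa_r)) ring$inner_radius / kappa_r,
    if (!is.null(kappa_d) && !is.na(kappa_d)) ring$ring_width / kappa_d
  )
  if (length(est) == 0L) {
    stop("cannot estimate defocus: no scale available", call. = FALSE)
  }
  sgn <- if (is.na(ring$orientation) || identical(ring$orientation, positive_orientation)) 1 else -1
  sgn * mean(est)
}

#' Pixel footprint of the diffraction-limited Airy spot
#'
#' The number of detector pixels the theoretical resolving distance covers
#' after magnification: `round(resolving_distance * magnification /
#' pixel_pitch)`, at least 1. A 0.68 um resolving distance through a 20x
#' objective on a 5.5 um pitch detector occupies 2 pixels.
#'
#' @param resolving_distance_um Resolving distance in micrometers.
#' @param magnification Optical magnification onto the detector.
#' @param pixel_pitch_um Detector pixel pitch in micrometers.
#' @return Whole pixels (integer, `>= 1`).
#' @export
airy_pixel_footprint <- function(resolving_distance_um, magnification, pixel_pitch_um) {
  stopifnot(resolving_distance_um > 0, magnification > 0, pixel_pitch_um > 0)
  max(1L, as.integer(round(resolving_distance_um * magnification / pixel_pitch_um)))
}

#' Reconstruct a missing ring (or the focused point spot)
#'
#' When a surface's spot is missing from the image (lost to aberration or
#' low brightness), its ring can be rebuilt from the neighbours: the shared
#' scales give `r = kappa_r * z` and `d = kappa_d * z`, and the center is
#' the consensus center of the reliable rings (their measured optical-axis
#' centers, or the [infer_focus_center()] extrapolation when a center is
#' not supplied and two reliable rings exist). For `z = 0` the
#' reconstruction is a focused point spot of diameter `focus_footprint_px`.
#'
#' @param stack A [surface_stack()] with at least 2 reliable rings, or 1
#'   reliable ring plus an explicit `center`.
#' @param z Defocus distance of the missing surface (relative units,
#'   `>= 0`).
#' @param center Optional `c(row, col)` optical-axis center.
#' @param focus_footprint_px Diameter of the focused point spot in pixels
#'   (default 2, the Airy footprint of the reference instrument).
#' @return A [ring_model()] (with `inner_radius = 0` and
#'   `ring_width = focus_footprint_px` when `z = 0`).
#' @export
reconstruct_missing_ring <- function(stack, z, center = NULL, focus_footprint_px = 2L) {
  stopifnot(inherits(stack, "surface_stack"), z >= 0)
  if (is.na(stack$kappa_r) || is.na(stack$kappa_d)) stack <- fit_stack_scales(stack)
  rel <- which(vapply(stack$rings, `[[`, logical(1), "reliable"))
  if (is.null(center)) {
    if (length(rel) >= 2) {
      a <- stack$rings[[rel[1]]]; b <- stack$rings[[rel[length(rel)]]]
      center <- infer_focus_center(inner_apex(a), inner_apex(b), a$z, b$z)
    } else if (length(rel) == 1) {
      r1 <- stack$rings[[rel]]
      center <- c(r1$center_row, r1$center_col)
    } else {
      stop("cannot reconstruct: no reliable ring and no center supplied", call. = FALSE)
    }
  }
  ori <- vapply(stack$rings[rel], `[[`, character(1), "orientation")
  tab <- table(ori[!is.na(ori)])
  orientation <- if (length(tab) > 0) names(sort(tab, decreasing = TRUE))[1] else "right"
  if (z == 0) {
    ring_model(center[1], center[2],
      inner_radius = 0, ring_width = focus_footprint_px,
      orientation = NA, reliable = FALSE, corrected = TRUE, z = 0
    )
  } else {
    ring_model(center[1], center[2],
      inner_radius = stack$kappa_r * z, ring_width = stack$kappa_d * z,
      orientation = orientation, reliable = FALSE, corrected = TRUE, z = z
    )
  }
}

#' Measure a ring from a cleaned image
#'
#' Works on the de-diffracted image inside one spot interval. The flat side
#' of the half-annulus is found from the vertical extent of bright pixels
#' at the interval's column edges (the flat side spans the full ring
#' height, the apex side does not); the optical-axis center is the
#' flat-side column at the interval's vertical midpoint. Along the center
#' row -- the spot's horizontal center, where the vertical falloff peaks --
#' the bright run farthest from the center gives the inner radius (run
#' start offset) and ring width (run length). Small spots (a few pixels
#' across) are reported as focused point spots with `r = 0`.
#'
#' @param img A cleaned [gray_image()].
#' @param interval One row of the tibble from [detect_spot_intervals()]
#'   (or any list with `row_min`, `row_max`, `col_min`, `col_max`).
#' @param bright_tau Gray level above which a pixel counts as bright
#'   (default 0.05); used for the extent and orientation estimates.
#' @param point_extent_px Bright regions no larger than this in both
#'   directions are treated as focused point spots (default 6).
#' @param params [classifier_params()] used to extract the main-spot runs
#'   of the center row.
#' @return A [ring_model()]; flagged unreliable when no main-spot run
#'   crosses the center row.
#' @export
measure_ring <- function(img, interval, bright_tau = 0.05, point_extent_px = 6L,
                         params = classifier_params()) {
  stopifnot(inherits(img, "gray_image"))
  rows <- interval$row_min:interval$row_max
  cols <- interval$col_min:interval$col_max
  sub <- as.matrix(img)[rows, cols, drop = FALSE]
  bright <- sub > bright_tau
  if (!any(bright)) {
    return(ring_model(mean(rows), mean(cols), NA, NA, NA, reliable = FALSE))
  }

  # tight bright extent inside the interval
  brows <- range(which(rowSums(bright) > 0))
  bcols <- range(which(colSums(bright) > 0))
  center_row <- rows[1] + (brows[1] + brows[2] - 2L) / 2

  # focused point spot: small, roughly isotropic blob
  if (diff(brows) + 1L <= point_extent_px && diff(bcols) + 1L <= point_extent_px) {
    return(ring_model(
      round(center_row), cols[1] + (bcols[1] + bcols[2] - 2L) / 2,
      inner_radius = 0, ring_width = ceiling((diff(bcols) + 1L) / 2),
      orientation = NA, reliable = TRUE, z = 0
    ))
  }

  # main-spot runs along the center row. The zero-gradient plateau of an
  # accepted run spans the ring interior; the sharp edges contribute one
  # pixel on each side, so the ring width is the plateau length plus two.
  mid_global <- round(center_row)
  row_vals <- as.matrix(img)[mid_global, ]
  lab <- classify_row(row_vals, params)
  dg <- central_difference_row(row_vals)$values
  plateau_full <- lab == PX_MAIN_SPOT & !is.na(dg) & abs(dg) <= params$eps_zero
  v <- plateau_full[cols]
  edge_px <- 1L
  reliable <- TRUE
  if (!any(v)) {
    # no accepted main-spot run (ring narrower than l_min, or broken):
    # fall back on the bright run, flagged unreliable
    v <- bright[mid_global - rows[1] + 1L, ]
    edge_px <- 0L
    reliable <- FALSE
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) {
    return(ring_model(center_row, mean(cols), NA, NA, NA, reliable = FALSE))
  }
  # the run this interval bounds: the widest (an interval's own ring is the
  # outermost, hence widest, main-spot structure it fully contains)
  pick <- runs[which.max(r$lengths[runs])]

  # the arc apex hugs the bright bounding box on the arc side; the flat
  # side sits one inner radius away -- that asymmetry gives the orientation
  left_gap <- starts[pick] - bcols[1]
  right_gap <- bcols[2] - ends[pick]
  orientation <- if (left_gap >= right_gap) "right" else "left"
  if (orientation == "right") {
    center_col <- cols[1] + bcols[1] - 1L
    inner <- starts[pick] - edge_px - bcols[1]
  } else {
    center_col <- cols[1] + bcols[2] - 1L
    inner <- bcols[2] - ends[pick] - edge_px
  }
  ring_model(
    center_row, center_col,
    inner_radius = max(0L, inner),
    ring_width = r$lengths[pick] + 2L * edge_px,
    orientation = orientation, reliable = reliable
  )
}

#' Measure one ring per spot interval
#'
#' A fragmented spot (hollow edge traces of a wide ring, say) can yield
#' several nested intervals that all measure the same physical ring; such
#' duplicates share a center and radially overlapping bands `[r, r + d)`,
#' and only the widest (most complete) measurement is kept.
#'
#' @param img A cleaned [gray_image()].
#' @param intervals Tibble from [detect_spot_intervals()].
#' @param center_tol Center agreement (px) under which radially overlapping
#'   measurements count as the same ring (default 5).
#' @param ... Passed to [measure_ring()].
#' @return A list of [ring_model()]s ordered by increasing inner radius.
#' @export
measure_rings <- function(img, intervals, center_tol = 5, ...) {
  rings <- purrr::map(seq_len(nrow(intervals)), function(i) {
    measure_ring(img, intervals[i, ], ...)
  })
  ok <- !vapply(rings, function(r) is.na(r$inner_radius), logical(1))
  rings <- rings[ok]
  if (length(rings) > 1) {
    # widest first; drop later rings that overlap a kept ring's radial band
    rings <- rings[order(-vapply(rings, `[[`, numeric(1), "ring_width"))]
    kept <- list()
    for (ring in rings) {
      dup <- any(vapply(kept, function(k) {
        same_center <- abs(k$center_row - ring$center_row) <= center_tol &&
          abs(k$center_col - ring$center_col) <= center_tol
        same_side <- identical(k$orientation, ring$orientation) ||
          is.na(k$orientation) || is.na(ring$orientation)
        overlap <- ring$inner_radius < k$inner_radius + k$ring_width &&
          k$inner_radius < ring$inner_radius + ring$ring_width
        same_center && same_side && overlap
      }, logical(1)))
      if (!dup) kept <- c(kept, list(ring))
    }
    rings <- kept
  }
  radii <- vapply(rings, `[[`, numeric(1), "inner_radius")
  rings[order(radii)]
}
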