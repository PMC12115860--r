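#' Pipeline configuration
#'
#' Collects every tunable threshold of the cleaning pipeline in one object
#' that can round-trip through JSON, so a run is fully reproducible from
#' its config file.
#'
#' @param tau_e,min_component_px,merge_radius See [background_model()].
#' @param eps_zero,tau_jump,l_min,max_gap See [classifier_params()].
#' @param n_iterations Screen/de-diffract passes (default 2): the first
#'   pass works inside the intervals screened from the raw frame, a second
#'   pass catches speckle that fell outside them (dim band fringes missed
#'   by the first screen).
#' @param tau_low Dim-pixel threshold of [beautify_ring()].
#' @param width_tol Width correction tolerance (px) of
#'   [correct_ring_widths()].
#' @param bright_tau Bright threshold of [measure_ring()].
#' @param background Background fill: `"median"` or a number in `[0, 1]`.
#' @param positive_orientation Orientation mapping to positive defocus.
#' @param focus_footprint_px Diameter (px) of a reconstructed focus spot.
#' @param z_calibration Optional physical calibration (defocus units per
#'   px of inner radius); `NA` reports defocus in relative units.
#' @return An `autofocus_config` list.
#' @export
autofocus_config <- function(tau_e = 0.08, min_component_px = 20L, merge_radius = 8L,
                             eps_zero = 0.01, tau_jump = 0.05, l_min = 8L, max_gap = 2L,
                             n_iterations = 2L,
                             tau_low = 0.1, width_tol = 3, bright_tau = 0.05,
                             background = "median", positive_orientation = "right",
                             focus_footprint_px = 2L, z_calibration = NA_real_) {
  cfg <- list(
    tau_e = tau_e, min_component_px = as.integer(min_component_px),
    merge_radius = as.integer(merge_radius),
    eps_zero = eps_zero, tau_jump = tau_jump, l_min = as.integer(l_min),
    max_gap = as.integer(max_gap), n_iterations = as.integer(n_iterations),
    tau_low = tau_low, width_tol = width_tol, bright_tau = bright_tau,
    background = background, positive_orientation = positive_orientation,
    focus_footprint_px = as.integer(focus_footprint_px),
    z_calibration = z_calibration
  )
  # validate through the stage constructors
  background_model(cfg$tau_e, cfg$min_component_px, cfg$merge_radius)
  classifier_params(cfg$eps_zero, cfg$tau_jump, cfg$l_min, cfg$max_gap)
  structure(cfg, class = "autofocus_config")
}

#' @rdname autofocus_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- vals[!vapply(vals, is.null, logical(1))] # JSON null: keep default
  do.call(autofocus_config, vals[names(vals) %in% names(formals(autofocus_config))])
}

#' @rdname autofocus_config
#' @param config An `autofocus_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Run the full de-diffraction pipeline on one frame
#'
#' Stage order: screen the background to find spot intervals; de-diffract
#' row by row inside them; re-screen the cleaned frame (speckle that glued
#' neighbouring spots together is gone, so the surface count can only grow
#' or stay); measure one ring per interval; fit the shared defocus scales
#' and correct inconsistent ring widths; optionally reconstruct a missing
#' focused surface; beautify each ring against its ideal annulus.
#'
#' @param input A [gray_image()], a [scene_spec()] (rendered first), or a
#'   path to a PNG/TIFF image.
#' @param config An [autofocus_config()].
#' @param expected_surfaces Optional known number of reflective surfaces;
#'   if one more than found, the missing surface is assumed to be the
#'   focused one (z = 0) and reconstructed from the measured rings.
#' @param z Optional defocus distances for the measured rings (innermost
#'   first); default assumes equally spaced surfaces: `z_i = i`.
#' @param output_dir Optional directory; when given, writes `cleaned.png`,
#'   `mask.png`, `refined.png`, `rings.csv` and `summary.json` there.
#' @return An `autofocus_result` list: `cleaned`, `refined`
#'   ([gray_image()]s), `classes`, `intervals`, `stack`
#'   ([surface_stack()]), `summary` (plain list, JSON-ready), `config`.
#' @export
run_pipeline <- function(input, config = autofocus_config(),
                         expected_surfaces = NULL, z = NULL,
                         output_dir = NULL) {
  img <- if (inherits(input, "gray_image")) {
    input
  } else if (inherits(input, "scene_spec")) {
    render_scene(input)$image
  } else if (is.character(input)) {
    read_gray_image(input)
  } else {
    stop("`input` must be a gray_image, a scene_spec or a file path", call. = FALSE)
  }
  model <- background_model(config$tau_e, config$min_component_px, config$merge_radius)
  params <- classifier_params(config$eps_zero, config$tau_jump, config$l_min, config$max_gap)

  mask <- screen_targets(img, model)
  intervals_raw <- detect_spot_intervals(mask, model)
  dd <- dediffract(img, intervals_raw, params, model)
  for (iter in seq_len(max(0L, config$n_iterations - 1L))) {
    iv_i <- detect_spot_intervals(screen_targets(dd$cleaned, model), model)
    dd_i <- dediffract(dd$cleaned, iv_i, params, model)
    cls <- pmax(dd$classes, dd_i$classes)
    cls[dd_i$classes == PX_DIFFRACTION] <- PX_DIFFRACTION # erased on this pass
    dd <- list(cleaned = dd_i$cleaned, classes = cls)
  }

  mask2 <- screen_targets(dd$cleaned, model)
  intervals <- detect_spot_intervals(mask2, model)

  n_found <- nrow(intervals)
  bg_value <- if (identical(config$background, "median")) {
    if (n_found > 0) {
      outside <- matrix(TRUE, nrow(img), ncol(img))
      for (i in seq_len(n_found)) {
        outside[intervals$row_min[i]:intervals$row_max[i],
                intervals$col_min[i]:intervals$col_max[i]] <- FALSE
      }
      stats::median(as.matrix(img)[outside])
    } else {
      stats::median(as.matrix(img))
    }
  } else {
    as.numeric(config$background)
  }

  refined <- dd$cleaned
  stack <- NULL
  corrections <- 0L
  reconstructed <- 0L
  resolvability <- tibble::tibble(
    inner_ring = integer(), outer_ring = integer(), resolved = logical()
  )

  if (n_found > 0) {
    rings <- measure_rings(dd$cleaned, intervals, bright_tau = config$bright_tau)
    # unreliable fallback measurements (debris blobs) only enter the stack
    # when nothing better was found
    if (any(vapply(rings, `[[`, logical(1), "reliable"))) {
      rings <- purrr::keep(rings, `[[`, "reliable")
    }
    zz <- z %||% seq_along(rings)
    stack <- harmonize_stack_center(surface_stack(rings, zz))
    stack <- fit_stack_scales(stack)
    stack <- correct_ring_widths(stack, config$width_tol)
    corrections <- sum(vapply(stack$rings, `[[`, logical(1), "corrected"))

    if (!is.null(expected_surfaces) && expected_surfaces == length(stack$rings) + 1L) {
      focus <- reconstruct_missing_ring(stack, z = 0,
        focus_footprint_px = config$focus_footprint_px
      )
      stack <- surface_stack(c(list(focus), stack$rings),
        z = c(0, stack$z), kappa_r = stack$kappa_r, kappa_d = stack$kappa_d
      )
      reconstructed <- 1L
    }

    usable <- purrr::keep(stack$rings, function(r) r$reliable || r$corrected)
    refined <- beautify_rings(refined, usable,
      tau_low = config$tau_low, background_value = bg_value
    )
    # within the detected intervals, anything outside every ideal annulus is
    # background -- this clears residue the ring-local pass cannot reach
    if (length(usable) > 0) {
      annuli <- purrr::map(usable, annulus_mask, dims = dim(refined))
      outside <- !Reduce(`|`, annuli)
      in_iv <- matrix(FALSE, nrow(refined), ncol(refined))
      all_iv <- dplyr::bind_rows(intervals, intervals_raw)
      for (i in seq_len(nrow(all_iv))) {
        in_iv[all_iv$row_min[i]:all_iv$row_max[i],
              all_iv$col_min[i]:all_iv$col_max[i]] <- TRUE
      }
      m <- as.matrix(refined)
      m[in_iv & outside] <- bg_value
      refined <- gray_image(pmin(pmax(m, 0), 1), provenance = attr(refined, "provenance"))
    }
    for (ring in stack$rings) {
      if (is.na(ring$orientation)) {
        # focused point spot: supplement an approximate circle at max gray
        disc <- annulus_mask(ring, dim(refined))
        m <- as.matrix(refined)
        m[disc] <- 1
        refined <- gray_image(m, provenance = attr(refined, "provenance"))
      }
    }

    out_of_focus <- which(stack$z > 0)
    if (length(out_of_focus) >= 2) {
      pairs <- cbind(out_of_focus[-length(out_of_focus)], out_of_focus[-1])
      resolvability <- tibble::tibble(
        inner_ring = pairs[, 1],
        outer_ring = pairs[, 2],
        resolved = vapply(seq_len(nrow(pairs)), function(i) {
          tryCatch(
            are_rings_resolved(stack$rings[[pairs[i, 1]]], stack$rings[[pairs[i, 2]]],
              center_tol = 2
            ),
            error = function(e) NA
          )
        }, logical(1))
      )
    }
  }

  counters <- list(
    pixels_flagged = sum(mask),
    pixels_erased = sum(dd$classes == PX_DIFFRACTION),
    pixels_main_spot = sum(dd$classes == PX_MAIN_SPOT),
    intervals_before = nrow(intervals_raw),
    intervals_after = n_found
  )
  summary <- list(
    surfaces = if (is.null(stack)) 0L else length(stack$rings),
    rings = if (is.null(stack)) list() else as.data.frame(tidy.surface_stack(stack)),
    kappa_r = if (is.null(stack)) NA_real_ else stack$kappa_r,
    kappa_d = if (is.null(stack)) NA_real_ else stack$kappa_d,
    corrections_applied = corrections,
    surfaces_reconstructed = reconstructed,
    resolvability = as.data.frame(resolvability),
    counters = counters,
    config = unclass(config)
  )
  if (is.null(stack) || nrow(intervals) == 0L) {
    warning("no surfaces found: empty report")
  }

  result <- structure(
    list(
      input = img, cleaned = dd$cleaned, refined = refined,
      classes = dd$classes, intervals = intervals, stack = stack,
      resolvability = resolvability, summary = summary, config = config
    ),
    class = "autofocus_result"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_gray_image(dd$cleaned, file.path(output_dir, "cleaned.png"))
    write_gray_image(refined, file.path(output_dir, "refined.png"))
    write_mask(dd$classes, file.path(output_dir, "mask.png"))
    if (!is.null(stack)) write_ring_report(stack, file.path(output_dir, "rings.csv"))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
  }
  result
}

#' @export
print.autofocus_result <- function(x, ...) {
  cat(sprintf(
    "<autofocus_result> %d surface(s); %d px erased as diffraction, %d px main spot\n",
    x$summary$surfaces, x$summary$counters$pixels_erased, x$summary$counters$pixels_main_spot
  ))
  if (!is.null(x$stack)) print(x$stack)
  invisible(x)
}

#' Tidy pipeline results
#'
#' `tidy()` returns the per-ring report; `glance()` a one-row summary.
#'
#' @param x An `autofocus_result` from [run_pipeline()].
#' @param ... Unused.
#' @export
tidy.autofocus_result <- function(x, ...) {
  if (is.null(x$stack)) {
    return(tidy.surface_stack(surface_stack(list())))
  }
  tidy.surface_stack(x$stack)
}

#' @rdname tidy.autofocus_result
#' @export
glance.autofocus_result <- function(x, ...) {
  tibble::tibble(
    n_surfaces = x$summary$surfaces,
    kappa_r = x$summary$kappa_r,
    kappa_d = x$summary$kappa_d,
    n_corrected = x$summary$corrections_applied,
    n_reconstructed = x$summary$surfaces_reconstructed,
    pixels_erased = x$summary$counters$pixels_erased,
    all_resolved = if (nrow(x$resolvability) == 0) NA else all(x$resolvability$resolved)
  )
}
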