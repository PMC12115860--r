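#' Gradient classifier parameters
#'
#' Tunable thresholds of the per-row run-length classifier, all in
#' normalized gray units per pixel.
#'
#' @param eps_zero Zero-gradient tolerance: a central difference with
#'   `|dg| <= eps_zero` counts as zero (default 0.01; the synthetic plateau
#'   ripple stays below this).
#' @param tau_jump Edge-jump threshold: `dg > tau_jump` is a positive jump,
#'   `dg < -tau_jump` a negative one (default 0.05; ring edges with contrast
#'   >= 0.2 over at most 2 px always jump). Must exceed `eps_zero` and may
#'   not exceed 0.5, the largest central difference possible on `[0, 1]`.
#' @param l_min Minimum zero-run length (pixels) for a run between opposite
#'   jumps to count as main-spot (default 8: accepted spot runs in real
#'   frames are 16+ pixels while diffraction runs stay below 6).
#' @param max_gap Transition pixels: up to this many consecutive
#'   intermediate gradients (neither zero nor jump) are tolerated between a
#'   jump and its zero run (default 2, about one edge width).
#' @return A `classifier_params` object.
#' @export
classifier_params <- function(eps_zero = 0.01, tau_jump = 0.05, l_min = 8L, max_gap = 2L) {
  stopifnot(
    eps_zero >= 0, eps_zero < tau_jump, tau_jump <= 0.5,
    l_min >= 1, max_gap >= 0
  )
  structure(
    list(
      eps_zero = eps_zero, tau_jump = tau_jump,
      l_min = as.integer(l_min), max_gap = as.integer(max_gap)
    ),
    class = "classifier_params"
  )
}

#' Central-difference gradient of one pixel row
#'
#' `dg[k] = (g[k + 1] - g[k - 1]) / 2` for interior columns; the two
#' endpoint columns carry no gradient value (`NA`). With optional
#' `params`, the row is annotated with jump positions and maximal zero
#' runs.
#'
#' @param g Numeric vector of gray values in `[0, 1]`, length at least 3.
#' @param params Optional [classifier_params()] used for the annotations.
#' @return A `gradient_row`: list with `values` (length of `g`, `NA` at the
#'   ends) and, when `params` is given, `jump_pos`, `jump_neg` (column
#'   indices) and `zero_runs` (two-column matrix of run start/end columns).
#' @examples
#' central_difference_row(c(0.2, 0.5, 0.8))$values
#' @export
central_difference_row <- function(g, params = NULL) {
  if (!is.numeric(g) || length(g) < 3L) {
    stop("a pixel row must hold at least 3 gray values", call. = FALSE)
  }
  n <- length(g)
  dg <- c(NA_real_, (g[3:n] - g[1:(n - 2L)]) / 2, NA_real_)
  out <- structure(list(values = dg, n = n), class = "gradient_row")
  if (!is.null(params)) {
    out$jump_pos <- which(!is.na(dg) & dg > params$tau_jump)
    out$jump_neg <- which(!is.na(dg) & dg < -params$tau_jump)
    z <- !is.na(dg) & abs(dg) <= params$eps_zero
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    zi <- which(r$values)
    out$zero_runs <- cbind(start = starts[zi], end = ends[zi])
  }
  out
}

#' @export
print.gradient_row <- function(x, ...) {
  cat(sprintf("<gradient_row> %d columns", x$n))
  if (!is.null(x$zero_runs)) {
    cat(sprintf(
      ", %d positive / %d negative jumps, %d zero runs",
      length(x$jump_pos), length(x$jump_neg), nrow(x$zero_runs)
    ))
  }
  cat("\n")
  invisible(x)
}

#' Classify one pixel row into background, main-spot and diffraction
#'
#' Scanning left to right, a maximal zero-gradient run that sits between a
#' positive jump (intensity rising: the outer edge of a spot) and a
#' negative jump (falling: the inner edge) is a main-spot segment if it is
#' at least `l_min` pixels long -- the run and its bounding jump columns are
#' labelled `main_spot`. Shorter runs between jumps, and jump columns not
#' attached to an accepted run, show the rapid gradient alternation of
#' diffraction speckle and are labelled `diffraction`. Everything else is
#' `background`.
#'
#' @param x A gray-value vector or a `gradient_row` from
#'   [central_difference_row()].
#' @param params A [classifier_params()].
#' @return Integer vector of pixel class codes (see [pixel-classes]), one
#'   per column.
#' @export
classify_row <- function(x, params = classifier_params()) {
  grad <- if (inherits(x, "gradient_row")) x else central_difference_row(x)
  dg <- grad$values
  n <- grad$n
  # per-column category: Z zero, P/N jumps, O intermediate (incl. endpoints)
  cat_ <- rep("O", n)
  cat_[!is.na(dg) & abs(dg) <= params$eps_zero] <- "Z"
  cat_[!is.na(dg) & dg > params$tau_jump] <- "P"
  cat_[!is.na(dg) & dg < -params$tau_jump] <- "N"

  r <- rle(cat_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  labels <- rep(PX_BACKGROUND, n)
  run_used <- rep(FALSE, nr) # jump runs attached to an accepted segment

  # neighbouring significant run, looking through short O runs
  neighbour <- function(i, dir) {
    j <- i + dir
    while (j >= 1L && j <= nr) {
      if (r$values[j] == "O") {
        if (r$lengths[j] > params$max_gap) return(NA_integer_)
        j <- j + dir
      } else {
        return(j)
      }
    }
    NA_integer_
  }

  for (i in seq_len(nr)) {
    if (r$values[i] != "Z") next
    left <- neighbour(i, -1L)
    right <- neighbour(i, 1L)
    between_jumps <- !is.na(left) && !is.na(right) &&
      r$values[left] == "P" && r$values[right] == "N"
    if (!between_jumps) next
    if (r$lengths[i] >= params$l_min) {
      # accepted main-spot segment: run + transition gaps + its edges (the
      # nearest jump columns, at most one edge width on either side)
      edge <- max(1L, params$max_gap)
      from <- max(starts[left], ends[left] - edge + 1L)
      to <- min(ends[right], starts[right] + edge - 1L)
      labels[from:to] <- PX_MAIN_SPOT
      run_used[left] <- TRUE
      run_used[right] <- TRUE
    } else {
      labels[starts[i]:ends[i]] <- PX_DIFFRACTION
    }
  }
  # jump runs not attached to any accepted segment are diffraction; the
  # unabsorbed overflow of an attached run stays background here (the
  # de-diffraction stage erases any non-spot pixel with an active gradient)
  for (i in seq_len(nr)) {
    if (r$values[i] %in% c("P", "N") && !run_used[i]) {
      cols <- starts[i]:ends[i]
      labels[cols][labels[cols] != PX_MAIN_SPOT] <- PX_DIFFRACTION
    }
  }
  as.integer(labels)
}

#' Remove diffraction speckle from an image
#'
#' Processes the rows covered by the detected spot intervals from top to
#' bottom. Within the interval columns of each row, pixels classified as
#' main-spot by [classify_row()] are preserved bit for bit. Pixels the
#' classifier did not accept as main-spot are treated as removable
#' interference when they are target-flagged or carry a non-zero gradient
#' (the chaotic texture of diffraction speckle): they are labelled
#' diffraction and replaced by the local background prediction `Y` of
#' [predict_background()]. Flat, unflagged pixels are genuine background
#' and stay. Rows and columns outside every interval are untouched and
#' labelled background.
#'
#' @param img A [gray_image()].
#' @param intervals Interval tibble from [detect_spot_intervals()]; an empty
#'   tibble returns the image unchanged.
#' @param params A [classifier_params()].
#' @param model A [background_model()] used for the background prediction
#'   and the target mask.
#' @return A list with `cleaned` (a [gray_image()]) and `classes` (integer
#'   matrix of pixel class codes).
#' @export
dediffract <- function(img, intervals, params = classifier_params(),
                       model = background_model()) {
  stopifnot(inherits(img, "gray_image"))
  f <- as.matrix(img)
  classes <- matrix(PX_BACKGROUND, nrow(f), ncol(f))
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(list(cleaned = img, classes = classes))
  }
  y <- predict_background(img, model)
  mask <- as.matrix(img) - y > model$tau_e
  # replacement values: the same Sj-window prediction, but averaging only
  # pixels that look like background -- Sj is a set of *background* points,
  # and inside a dense speckle band the unrestricted mean is not background.
  # Background-like means: not target-flagged, flat (near-zero horizontal
  # gradient) and near the global background gray level. Where no such
  # pixel falls in the window, the global background level is used.
  covered_all <- matrix(FALSE, nrow(f), ncol(f))
  for (i in seq_len(nrow(intervals))) {
    covered_all[intervals$row_min[i]:intervals$row_max[i],
                intervals$col_min[i]:intervals$col_max[i]] <- TRUE
  }
  bg_level <- if (all(covered_all)) stats::median(f) else stats::median(f[!covered_all])
  dgm <- cbind(NA, (f[, 3:ncol(f), drop = FALSE] - f[, 1:(ncol(f) - 2L), drop = FALSE]) / 2, NA)
  quiet <- !(mask | (!is.na(dgm) & abs(dgm) > params$eps_zero)) &
    f <= bg_level + model$tau_e
  y_bg <- background_restricted_mean(f, quiet, model)
  y[!is.na(y_bg)] <- y_bg[!is.na(y_bg)]
  y[is.na(y_bg)] <- bg_level
  cleaned <- f
  rows_covered <- sort(unique(unlist(
    purrr::map2(intervals$row_min, intervals$row_max, seq)
  )))
  for (m in rows_covered) {
    # union of interval column ranges covering this row
    hit <- intervals$row_min <= m & intervals$row_max >= m
    covered <- rep(FALSE, ncol(f))
    for (i in which(hit)) covered[intervals$col_min[i]:intervals$col_max[i]] <- TRUE
    lab <- classify_row(f[m, ], params)
    lab[!covered] <- PX_BACKGROUND
    # pixels between the accepted spot segments count as background: anything
    # not accepted as main-spot that is target-flagged or carries a non-zero
    # gradient (the chaotic texture of speckle) is diffraction
    dg <- central_difference_row(f[m, ])$values
    active <- mask[m, ] | (!is.na(dg) & abs(dg) > params$eps_zero)
    lab[covered & active & lab != PX_MAIN_SPOT] <- PX_DIFFRACTION
    erase <- lab == PX_DIFFRACTION
    cleaned[m, erase] <- y[m, erase]
    classes[m, ] <- pmax(classes[m, ], lab)
  }
  list(
    cleaned = gray_image(pmin(pmax(cleaned, 0), 1), provenance = attr(img, "provenance")),
    classes = classes
  )
}
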