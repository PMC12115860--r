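test_that("central differences follow the half-difference stencil", {
  expect_equal(central_difference_row(c(0.2, 0.5, 0.8))$values, c(NA, 0.3, NA))
  expect_equal(central_difference_row(rep(0.4, 10))$values, c(NA, rep(0, 8), NA))

  ramp <- seq(0, 0.9, by = 0.1)
  expect_equal(central_difference_row(ramp)$values, c(NA, rep(0.1, 8), NA))

  for (seed in 1:5) {
    g <- withr::with_seed(seed, runif(30))
    expect_equal(central_difference_row(g)$values, oracle_central_diff(g))
  }
  expect_error(central_difference_row(c(0.1, 0.2)), "at least 3")
})

test_that("gradients of unit-range rows never exceed one half in magnitude", {
  for (seed in 1:5) {
    g <- withr::with_seed(seed, runif(50))
    dg <- central_difference_row(g)$values
    expect_true(all(abs(dg) <= 0.5, na.rm = TRUE))
  }
})

test_that("annotated rows carry maximal, disjoint zero runs and jump positions", {
  params <- classifier_params()
  g <- c(0, 0, 0.4, 0.4, 0.4, 0.4, 0, 0, 0.3, 0)
  grad <- central_difference_row(g, params)
  runs <- grad$zero_runs
  expect_true(all(runs[, "end"] >= runs[, "start"]))
  if (nrow(runs) > 1) {
    expect_true(all(runs[-1, "start"] > runs[-nrow(runs), "end"] + 1))
  }
  dg <- grad$values
  expect_identical(grad$jump_pos, which(!is.na(dg) & dg > params$tau_jump))
  expect_identical(grad$jump_neg, which(!is.na(dg) & dg < -params$tau_jump))
})

test_that("a flat row is all background and a trapezoid pulse is one spot segment", {
  params <- classifier_params(eps_zero = 0.01, tau_jump = 0.05, l_min = 8)
  expect_true(all(classify_row(rep(0.2, 40), params) == PX_BACKGROUND))

  # 2 px ramps up to a 20 px plateau
  g <- c(rep(0, 10), 0.4, rep(0.8, 20), 0.4, rep(0, 10))
  lab <- classify_row(g, params)
  seg <- which(lab == PX_MAIN_SPOT)
  expect_equal(seg, 11:32) # plateau and its edges, nothing else
  expect_true(all(lab[-seg] == PX_BACKGROUND))
})

test_that("zero runs of 16 and 47 pass while a run of 5 is diffraction", {
  params <- classifier_params(l_min = 8)
  # plateaus of width w yield interior zero runs of length w - 2
  plateau <- function(w) c(rep(0.8, w))
  gap <- function(w) rep(0, w)
  g <- c(
    gap(10), plateau(18), gap(12), plateau(49), gap(8), plateau(7), gap(10)
  )
  lab <- classify_row(g, params)
  grad <- central_difference_row(g, params)
  lens <- grad$zero_runs[, "end"] - grad$zero_runs[, "start"] + 1
  expect_true(all(c(16, 47, 5) %in% lens)) # the three plateau interiors
  expect_true(all(lab[11:28] == PX_MAIN_SPOT)) # 18 px plateau: run of 16
  expect_true(all(lab[41:89] == PX_MAIN_SPOT)) # 49 px plateau: run of 47
  expect_true(all(lab[98:104] == PX_DIFFRACTION)) # 7 px plateau: run of 5
})

test_that("classification is translation-equivariant", {
  params <- classifier_params()
  g <- c(rep(0, 12), 0.4, rep(0.8, 15), 0.4, rep(0, 12))
  base <- classify_row(g, params)
  for (shift in c(3, 7)) {
    shifted <- c(rep(0, shift), g)[1:length(g)]
    expect_identical(classify_row(shifted, params)[(shift + 2):length(g)],
      base[2:(length(g) - shift)])
  }
})

test_that("raising l_min never converts diffraction to main-spot", {
  g <- withr::with_seed(4, {
    v <- rep(0, 120)
    v[20:40] <- 0.8 # long plateau
    v[60:66] <- 0.8 # short plateau
    v[80:100] <- runif(21, 0, 0.6) # chaos
    v
  })
  lab_lo <- classify_row(g, classifier_params(l_min = 6))
  lab_hi <- classify_row(g, classifier_params(l_min = 12))
  expect_false(any(lab_hi == PX_MAIN_SPOT & lab_lo == PX_DIFFRACTION))
  expect_true(all(which(lab_hi == PX_MAIN_SPOT) %in% which(lab_lo == PX_MAIN_SPOT)))
})

test_that("de-diffraction without intervals is the identity", {
  img <- random_gray(30, 30, seed = 2)
  iv <- detect_spot_intervals(matrix(FALSE, 30, 30), background_model())
  dd <- dediffract(img, iv)
  expect_identical(as.matrix(dd$cleaned), as.matrix(img))
  expect_true(all(dd$classes == PX_BACKGROUND))
})

test_that("speckle is erased and the ring preserved on a planted one-ring scene", {
  sc <- render_scene(moderate_one_ring_spec())
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  dd <- dediffract(sc$image, iv)
  f0 <- as.matrix(sc$image)
  f1 <- as.matrix(dd$cleaned)
  speckle <- sc$classes == PX_DIFFRACTION
  ring <- sc$classes == PX_MAIN_SPOT
  expect_gte(mean(f1[speckle] != f0[speckle]), 0.90)
  expect_gte(mean(f1[ring] == f0[ring]), 0.95)
  # main-spot pixels are bit-identical; everything else moved to the
  # background prediction or stayed
  expect_true(all(f1[dd$classes == PX_MAIN_SPOT] ==
    f0[dd$classes == PX_MAIN_SPOT]))
  expect_true(all(f1[dd$classes != PX_DIFFRACTION] ==
    f0[dd$classes != PX_DIFFRACTION]))
})

test_that("cleaned two-ring widths stay within one pixel of the planted widths", {
  spec <- scene_spec(seed = 7) # defaults: two rings, speckle between them
  sc <- render_scene(spec)
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  dd <- dediffract(sc$image, iv)
  iv2 <- detect_spot_intervals(screen_targets(dd$cleaned, model), model)
  rings <- measure_rings(dd$cleaned, iv2)
  expect_equal(length(rings), 2)
  expect_lte(abs(rings[[1]]$ring_width - 17), 1)
  expect_lte(abs(rings[[2]]$ring_width - 34), 1)
})

test_that("noise-free classification agrees with the truth map away from edges", {
  spec <- clean_scene_spec(2)
  sc <- render_scene(spec)
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  dd <- dediffract(sc$image, iv)
  truth <- sc$classes
  # interior pixels: 3x3 neighbourhood uniformly one truth class
  M <- nrow(truth); N <- ncol(truth)
  interior <- matrix(TRUE, M, N)
  for (dl in -1:1) {
    for (dk in -1:1) {
      sh <- truth[pmin(pmax(seq_len(M) + dl, 1), M), pmin(pmax(seq_len(N) + dk, 1), N)]
      interior <- interior & sh == truth
    }
  }
  agree <- mean((dd$classes == truth)[interior])
  expect_gte(agree, 0.99)
})
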