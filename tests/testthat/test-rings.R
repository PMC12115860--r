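test_that("resolvability is the r2 >= r1 + d1 boundary", {
  a <- ring_model(100, 10, 64, 17, "right")
  expect_true(are_rings_resolved(a, ring_model(100, 10, 81, 20, "right")))
  expect_false(are_rings_resolved(a, ring_model(100, 10, 80, 20, "right")))
  # argument order does not matter
  expect_true(are_rings_resolved(ring_model(100, 10, 81, 20, "right"), a))
  expect_error(are_rings_resolved(a, ring_model(100, 10, 81, 20, "left")), "orientation")
  expect_error(are_rings_resolved(a, ring_model(100, 30, 81, 20, "right")), "center")
})

test_that("resolvability agrees with rasterized annulus overlap", {
  dims <- c(240, 130)
  withr::with_seed(42, {
    for (i in 1:50) {
      r1 <- runif(1, 10, 50)
      d1 <- runif(1, 4, 20)
      r2 <- runif(1, r1, 90)
      d2 <- runif(1, 4, 20)
      a <- ring_model(120, 5, r1, d1, "right")
      b <- ring_model(120, 5, r2, d2, "right")
      overlap <- any(annulus_mask(a, dims) & annulus_mask(b, dims))
      expect_equal(are_rings_resolved(a, b), !overlap)
    }
  })
})

test_that("stack scales are the median per-ring ratios", {
  one <- fit_stack_scales(list(ring_model(0, 0, 30, 17, z = 1)))
  expect_equal(one$kappa_d, 17)

  three <- fit_stack_scales(
    list(
      ring_model(0, 0, 11, 10, z = 1),
      ring_model(0, 0, 20, 21, z = 2),
      ring_model(0, 0, 30, 29, z = 3)
    )
  )
  expect_equal(three$kappa_d, 10) # median of 10, 10.5, 9.667
  expect_equal(three$kappa_d * three$z, c(10, 20, 30))

  planted <- surface_stack(
    list(ring_model(0, 0, 32, 8.5, z = 1), ring_model(0, 0, 64, 17, z = 2))
  )
  fit <- fit_stack_scales(planted)
  expect_equal(fit$kappa_r, 32)
  expect_equal(fit$kappa_d, 8.5)

  expect_error(
    fit_stack_scales(list(ring_model(0, 0, 30, 17, z = 1, reliable = FALSE))),
    "reliable"
  )
})

test_that("an inconsistent width is replaced by the proportionality prediction", {
  stack <- surface_stack(
    list(
      ring_model(180, 12, 64, 17, "right", z = 1),
      ring_model(180, 12, 128, 25, "right", reliable = FALSE, z = 2)
    )
  )
  stack <- fit_stack_scales(stack)
  corrected <- correct_ring_widths(stack)
  expect_equal(corrected$rings[[2]]$ring_width, 34)
  expect_true(corrected$rings[[2]]$corrected)
  expect_false(corrected$rings[[1]]$corrected)

  # consistent stacks do not change; correction is idempotent
  ok <- correct_ring_widths(fit_stack_scales(surface_stack(
    list(ring_model(0, 0, 30, 10, z = 1), ring_model(0, 0, 60, 20, z = 2))
  )))
  expect_equal(vapply(ok$rings, `[[`, numeric(1), "ring_width"), c(10, 20))
  expect_false(any(vapply(ok$rings, `[[`, logical(1), "corrected")))
  twice <- correct_ring_widths(corrected)
  expect_equal(generics::tidy(twice), generics::tidy(corrected))
})

test_that("only the outlier of a three-ring stack is corrected", {
  stack <- fit_stack_scales(surface_stack(list(
    ring_model(0, 0, 30, 10, z = 1),
    ring_model(0, 0, 60, 27, z = 2), # 7 px off the law
    ring_model(0, 0, 90, 30, z = 3)
  )))
  out <- correct_ring_widths(stack)
  expect_equal(vapply(out$rings, `[[`, numeric(1), "ring_width"), c(10, 20, 30))
  expect_identical(vapply(out$rings, `[[`, logical(1), "corrected"), c(FALSE, TRUE, FALSE))
})

test_that("width/defocus closure holds after fitting and correction", {
  stack <- correct_ring_widths(fit_stack_scales(surface_stack(list(
    ring_model(0, 0, 30, 10, z = 1),
    ring_model(0, 0, 60, 24, z = 2),
    ring_model(0, 0, 90, 30, z = 3)
  ))))
  d <- vapply(stack$rings, `[[`, numeric(1), "ring_width")
  r <- vapply(stack$rings, `[[`, numeric(1), "inner_radius")
  z <- stack$z
  keep <- vapply(stack$rings, function(x) x$reliable || x$corrected, logical(1))
  for (i in which(keep)) {
    for (j in which(keep)) {
      expect_equal(d[i] * z[j], d[j] * z[i])
    }
  }
})

test_that("the focused-spot center extrapolates exactly from two rings", {
  expect_equal(infer_focus_center(c(118, 180), c(182, 180), z_a = 1, z_b = 2), c(54, 180))
  expect_equal(infer_focus_center(c(77, 40), c(77, 40), z_a = 1, z_b = 3), c(77, 40))
  expect_error(infer_focus_center(c(1, 1), c(2, 2), z_a = 2, z_b = 2), "equal defocus")

  withr::with_seed(11, {
    for (i in 1:20) {
      ctr <- runif(2, 0, 200)
      kappa <- runif(1, 5, 80)
      zz <- sort(runif(2, 0.2, 4))
      xa <- ctr + kappa * zz[1] * c(0, 1)
      xb <- ctr + kappa * zz[2] * c(0, 1)
      expect_equal(infer_focus_center(xa, xb, zz[1], zz[2]), ctr)
    }
  })
})

test_that("defocus follows from either scale and the orientation sign", {
  ring <- ring_model(0, 0, 30, 10, "right")
  expect_equal(defocus_from_ring(ring, kappa_r = 10), 3)
  expect_equal(defocus_from_ring(ring, kappa_r = 10, kappa_d = 10 / 3), 3)
  left <- ring_model(0, 0, 30, 10, "left")
  expect_equal(defocus_from_ring(left, kappa_r = 10), -3)
  expect_equal(defocus_from_ring(left, kappa_r = 10, positive_orientation = "left"), 3)
  expect_error(defocus_from_ring(ring), "no scale")
})

test_that("the Airy footprint rounds to whole pixels with a floor of one", {
  expect_identical(airy_pixel_footprint(0.68, 20, 5.5), 2L)
  expect_identical(airy_pixel_footprint(5.5, 1, 5.5), 1L)
  expect_identical(airy_pixel_footprint(1.0, 11, 5.5), 2L)
  expect_identical(airy_pixel_footprint(0.1, 1, 5.5), 1L)
  expect_error(airy_pixel_footprint(-1, 20, 5.5))
})

test_that("missing rings and the focus point rebuild from the stack", {
  stack <- fit_stack_scales(surface_stack(list(
    ring_model(180, 118, 64, 17, "right", z = 1),
    ring_model(180, 118, 128, 34, "right", z = 2)
  )))
  focus <- reconstruct_missing_ring(stack, z = 0)
  expect_equal(focus$inner_radius, 0)
  expect_equal(focus$ring_width, 2)
  expect_equal(c(focus$center_row, focus$center_col), c(180, 118))
  expect_equal(focus$z, 0)

  same <- reconstruct_missing_ring(stack, z = 2)
  expect_equal(same$inner_radius, 128)
  expect_equal(same$ring_width, 34)

  # leave-one-out on a rendered three-ring stack
  sc <- render_scene(clean_scene_spec(3))
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  rings <- measure_rings(sc$image, iv)
  partial <- fit_stack_scales(surface_stack(rings[c(1, 3)], z = c(1, 3)))
  rebuilt <- reconstruct_missing_ring(partial, z = 2)
  expect_lte(abs(rebuilt$inner_radius - rings[[2]]$inner_radius), 1)
  expect_lte(abs(rebuilt$ring_width - rings[[2]]$ring_width), 1)

  expect_error(
    reconstruct_missing_ring(surface_stack(list(
      ring_model(0, 0, 30, 10, z = 1, reliable = FALSE)
    )), z = 2),
    "reliable"
  )
})

test_that("rendered rings measure back to their planted geometry", {
  spec <- scene_spec(
    size = c(130, 70), center = c(65, 8),
    surfaces = data.frame(z = 1, orientation = "right", peak = 0.9),
    kappa_r = 40, kappa_d = 12,
    speckle_amplitude = 0, noise_sigma = 0, seed = 6
  )
  sc <- render_scene(spec)
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  ring <- measure_ring(sc$image, iv[1, ])
  expect_lte(abs(ring$inner_radius - 40), 1)
  expect_lte(abs(ring$ring_width - 12), 1)
  expect_identical(ring$orientation, "right")
  expect_true(ring$reliable)
  expect_lte(abs(ring$center_row - 65), 1)
  expect_lte(abs(ring$center_col - 8), 1)
})

test_that("left-opening rings and focused points measure correctly", {
  spec <- scene_spec(
    size = c(130, 70), center = c(65, 62),
    surfaces = data.frame(z = 1, orientation = "left", peak = 0.9),
    kappa_r = 40, kappa_d = 12,
    speckle_amplitude = 0, noise_sigma = 0, seed = 6
  )
  sc <- render_scene(spec)
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(sc$image, model), model)
  ring <- measure_ring(sc$image, iv[1, ])
  expect_identical(ring$orientation, "left")
  expect_lte(abs(ring$inner_radius - 40), 1)
  expect_lte(abs(ring$ring_width - 12), 1)

  point_spec <- scene_spec(
    size = c(40, 40), center = c(20, 20),
    surfaces = data.frame(z = 0, orientation = NA, peak = 0.9),
    focus_footprint_px = 2,
    speckle_amplitude = 0, noise_sigma = 0, seed = 6
  )
  sc2 <- render_scene(point_spec)
  model2 <- background_model(min_component_px = 3)
  iv2 <- detect_spot_intervals(screen_targets(sc2$image, model2), model2)
  pt <- measure_ring(sc2$image, iv2[1, ])
  expect_equal(pt$inner_radius, 0)
  expect_equal(pt$ring_width, 2)
  expect_true(is.na(pt$orientation))
})

test_that("stack centers harmonize from the apexes", {
  stack <- surface_stack(list(
    ring_model(180, 12, 64, 17, "right", z = 1),
    ring_model(180, 40, 100, 34, "right", z = 2) # misplaced flat side, apex 140
  ))
  fixed <- harmonize_stack_center(stack)
  expect_equal(fixed$rings[[2]]$center_col, 12)
  expect_equal(fixed$rings[[2]]$inner_radius, 128)
  expect_equal(fixed$rings[[1]]$inner_radius, 64)
})

test_that("duplicate fragment measurements collapse to one ring", {
  img <- render_scene(clean_scene_spec(2))$image
  model <- background_model()
  iv <- detect_spot_intervals(screen_targets(img, model), model)
  # duplicate the outer interval, clipped, to mimic a fragmented component
  iv2 <- rbind(iv, iv[1, ])
  iv2$col_max[3] <- iv2$col_max[3] - 10
  rings <- measure_rings(img, iv2)
  expect_equal(length(rings), 2)
})
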