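make_ideal_ring <- function(value = 0.8) {
  ring <- ring_model(40, 5, 10, 6, "right")
  m <- matrix(0, 80, 60)
  m[annulus_mask(ring, dim(m))] <- value
  list(ring = ring, img = gray_image(m))
}

test_that("beautification trims protrusions and lifts dim in-annulus pixels", {
  x <- make_ideal_ring()
  m <- as.matrix(x$img)
  m[40, 23] <- 0.9 # protrusion 2 px beyond the outer radius (rho = 18)
  m[40, 16] <- 0.02 # dim in-annulus (rho = 11); neighbour (39,16) is 0.8
  m[28, 5] <- 0.02 # dim on the upper arm; its neighbour toward mid-row ...
  m[29, 5] <- 0.03 # ... is also dim
  b <- beautify_ring(gray_image(m), x$ring, tau_low = 0.1, background_value = 0)
  bm <- as.matrix(b)
  expect_equal(bm[40, 23], 0) # assigned the background gray value
  expect_equal(bm[40, 16], 0.8) # adjacent longitudinal pixel
  expect_equal(bm[28, 5], 1) # both references dim: maximum brightness
  expect_equal(bm[29, 5], 0.8) # its own longitudinal reference is bright

  expect_error(
    beautify_ring(x$img, ring_model(40, 5, 10, NA, "right", reliable = FALSE)),
    "degenerate"
  )
})

test_that("after beautification the annulus is clean inside and empty outside", {
  x <- make_ideal_ring()
  m <- as.matrix(x$img)
  withr::with_seed(3, {
    noise_px <- cbind(sample(25:55, 15), sample(25:40, 15))
    m[noise_px] <- runif(15, 0.2, 0.9) # speckle-ish litter around the ring
  })
  b <- beautify_ring(gray_image(m), x$ring, tau_low = 0.1, background_value = 0.01)
  bm <- as.matrix(b)
  ann <- annulus_mask(x$ring, dim(bm))
  reg <- dediffract:::ring_region(x$ring, dim(bm))
  expect_true(all(bm[reg & !ann] == 0.01))
  expect_true(all(bm[ann] >= 0.1 | bm[ann] == 1))
  # idempotent
  b2 <- beautify_ring(b, x$ring, tau_low = 0.1, background_value = 0.01)
  expect_identical(as.matrix(b2), bm)
})

test_that("the standard line removes burrs and fills arc gaps", {
  x <- make_ideal_ring()
  m <- as.matrix(x$img)
  m[40, 22:24] <- 0.7 # 3 px burr on the outer edge
  gap_px <- which(annulus_mask(x$ring, dim(m)), arr.ind = TRUE)
  gap_px <- gap_px[gap_px[, 1] == 33, , drop = FALSE][1:2, ] # 2 px gap in the arc
  m[gap_px] <- 0
  tr <- trim_to_standard_line(gray_image(m), x$ring, tau_low = 0.1, background_value = 0)
  tm <- as.matrix(tr)
  expect_true(all(tm[40, 22:24] == 0))
  expect_true(all(tm[gap_px] >= 0.1)) # filled from neighbour means
  expect_lte(max(abs(tm[gap_px] - 0.8)), 1e-9) # neighbours are all 0.8

  # a clean ring is a fixed point, and refinement is idempotent
  ideal <- trim_to_standard_line(x$img, x$ring, tau_low = 0.1, background_value = 0)
  expect_identical(as.matrix(ideal)[annulus_mask(x$ring, dim(m))],
    as.matrix(x$img)[annulus_mask(x$ring, dim(m))])
  tr2 <- trim_to_standard_line(tr, x$ring, tau_low = 0.1, background_value = 0)
  expect_identical(as.matrix(tr2), tm)
})

test_that("a fully void annulus is reported, not silently filled", {
  ring <- ring_model(40, 5, 10, 6, "right")
  img <- gray_image(matrix(0, 80, 60))
  expect_warning(trim_to_standard_line(img, ring, background_value = 0), "void")
})

test_that("beautifying a stack protects sibling rings", {
  inner <- ring_model(90, 5, 30, 10, "right")
  outer <- ring_model(90, 5, 60, 20, "right")
  m <- matrix(0, 180, 100)
  m[annulus_mask(inner, dim(m))] <- 0.8
  m[annulus_mask(outer, dim(m))] <- 0.7
  img <- gray_image(m)
  b <- beautify_rings(img, list(inner, outer), background_value = 0)
  bm <- as.matrix(b)
  expect_true(all(bm[annulus_mask(inner, dim(bm))] == 0.8))
  expect_true(all(bm[annulus_mask(outer, dim(bm))] == 0.7))
})

test_that("a beautified degraded ring recovers the ideal width", {
  sc <- render_scene(strong_one_ring_spec())
  res <- run_pipeline(sc$image)
  mid <- 130
  raw_w <- diff(range(which(as.matrix(sc$image)[mid, ] > 0.08))) + 1
  beaut_w <- diff(range(which(as.matrix(res$refined)[mid, ] > 0.08))) + 1
  expect_lte(abs(beaut_w - 10), 1) # planted width
  expect_lte(beaut_w, 0.3 * raw_w) # about a quarter of the inflated width
})
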