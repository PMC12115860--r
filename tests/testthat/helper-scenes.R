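# Shared synthetic study conditions.
#
# Default scenes echo the reference geometry (64 px radius / 17 px width per
# defocus unit, surfaces at defocus ratio 1:2). The "strong diffraction"
# family uses an outer speckle band three ring widths wide, packed densely
# enough to adhere to the ring as one bright mass (the failure mode the
# cleaning stage exists to fix).

clean_scene_spec <- function(K, seed = 100 + K) {
  ext <- (64 + 17) * K
  scene_spec(
    size = c(2 * ext + 40, ext + 40), center = c(ext + 20, 12),
    surfaces = data.frame(z = seq_len(K), orientation = "right", peak = 0.85),
    speckle_amplitude = 0, noise_sigma = 0, seed = seed
  )
}

# one ring at the reference geometry with its default (moderate) speckle band
moderate_one_ring_spec <- function(seed = 11) {
  scene_spec(
    size = c(200, 120), center = c(100, 10),
    surfaces = data.frame(z = 1, orientation = "right", peak = 0.85),
    kappa_r = 64, kappa_d = 17, seed = seed
  )
}

# One out-of-focus ring with a dense speckle band three ring widths wide.
# Strong diffraction means speckle comparable in brightness to the spot all
# along the band, so the vertical falloff spans ring plus band.
strong_one_ring_spec <- function(seed = 19) {
  scene_spec(
    size = c(260, 150), center = c(130, 10),
    surfaces = data.frame(z = 1, orientation = "right", peak = 0.85),
    kappa_r = 30, kappa_d = 10, outer_band = 30, speckle_count = 1500,
    vertical_falloff = 0.75 * (30 + 10 + 30),
    seed = seed
  )
}

# two-ring template for the resolution probe, same strong band
strong_two_ring_spec <- function(seed = 17) {
  scene_spec(
    size = c(260, 150), center = c(130, 10),
    surfaces = data.frame(z = c(1, 2), orientation = "right", peak = 0.85),
    kappa_r = 30, kappa_d = 10, outer_band = 30, speckle_count = 1500,
    vertical_falloff = 0.75 * (30 + 10 + 30),
    seed = seed
  )
}

# three reflective surfaces, one at focus (dim, easily lost), with a band
# wide enough to glue the two out-of-focus rings into one screened interval
multilayer_focus_spec <- function(seed = 3) {
  scene_spec(
    size = c(400, 240), center = c(200, 12),
    surfaces = data.frame(
      z = c(0, 1, 2), orientation = c(NA, "right", "right"),
      peak = c(0.2, 0.85, 0.85)
    ),
    outer_band = 35, seed = seed
  )
}
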