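---
title: "De-diffraction of semi-annular autofocus spot images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-diffraction of semi-annular autofocus spot images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 5)
```

```{r setup}
library(dediffract)
```

## The measurement problem

A semi-annular laser autofocus microscope images each reflective surface of
a transparent sample as a half-ring on its detector. The geometry carries
the measurement: for a surface at defocus distance $z$, both the inner
radius $r$ and the ring width $d$ of its half-ring are proportional to $z$,

$$\frac{d_1}{d_2} = \frac{z_1}{z_2}, \qquad \frac{r_1}{r_2} = \frac{z_1}{z_2},$$

so $r = \kappa_r z$ and $d = \kappa_d z$ with shared scales $\kappa_r,
\kappa_d$ for one optical configuration. The sign of the defocus flips the
half-ring's orientation. Two surfaces are *just resolved* when the outer
radius of the inner ring meets the inner radius of the outer one,
$r_2 = r_1 + d_1$; the corresponding axial distance is the interlayer
resolution.

Diffraction from the half-annular aperture litters the image with speckle
that clings to the outer side of each ring. The speckle widens the apparent
ring, glues neighbouring rings together, and cannot be removed by intensity
thresholds (near focus it is as bright as the spot) or frequency-domain
filters (it shares the spot's spectrum). This package implements a cleaning
pipeline that exploits the one robust difference: along a pixel row, a
genuine half-ring crossing is a long run of near-zero horizontal gradient
bracketed by one strong positive and one strong negative jump, while
speckle flips its gradient sign every pixel or two.

## Geometry conventions

All gray values live on $[0,1]$ (8-bit levels divided by exactly 255).
Indices are 1-based `(row, col)` with row 1 at the top, the R convention
for matrices. A `ring_model` stores the optical-axis center, $r$, $d$, and
an orientation `"left"`/`"right"`: the half-ring occupies the half-plane on
that side of the vertical line through the center, its flat side on the
line, its arc apex on the center row. Intensity peaks on the center row
and decays as a Gaussian in the vertical offset, so the upper and lower
arm ends are the dim parts. With this layout the width of the ring can be
read directly off the row through the spot's vertical midpoint, and the
inner-edge apex sits at `center_col + r`, which makes the center
extrapolation below exact. The same geometry works rotated by 90 degrees;
only the scan direction of the classifier is tied to rows.

## Stage 1: background screening (spot intervals)

The local background at a pixel is predicted as

$$Y(m,n) = \sum_{(l,k) \in S_j} W\, f(m-l,\, n-k), \qquad W = \tfrac{1}{40},$$

where $S_j$ is the 7×7 window minus the 3×3 core: 40 offsets, the unique
symmetric arrangement with that count. At the border the set is clipped
and $W$ rescaled so the weights still sum to one. A pixel is a *target*
when the residual $E = f - Y$ exceeds `tau_e` (default 0.08 normalized
units, below the dimmest ring contrast the generator produces, above its
noise). No main-spot/diffraction distinction is made here.

Because the predictor averages a local window, it flags structures
*narrower* than the window throughout but only the edges of wider ones;
that is all interval detection needs. The 8-connected components of the
target mask (components under `min_component_px = 20` dropped as noise)
are merged when within `2 * merge_radius = 16` px of each other — this
absorbs speckle debris and the hollow edge traces of a wide ring while
keeping well-separated nested rings apart — and each surviving group's
bounding box, padded by `merge_radius`, becomes one spot interval. Nested
surfaces yield nested intervals; the interval count is the screened
surface count. A literal "merge on bounding-box overlap" rule cannot work
here: nested rings are concentric, so every inner box lies inside the
outer one and all surfaces would collapse into a single interval.

## Stage 2: gradient run-length classification

Within each interval, rows are processed top-down. For a row $g$ the
central difference is $\Delta g_k = (g_{k+1} - g_{k-1})/2$ (endpoints carry
no value; $|\Delta g| \le 1/2$ on unit-range data). Columns are
categorized by two thresholds: *zero* when $|\Delta g| \le$ `eps_zero`
(default 0.01), a *jump* when $|\Delta g| >$ `tau_jump` (default 0.05),
transitional otherwise (up to `max_gap = 2` transitional columns are
tolerated between a jump and its plateau — one sharp edge spreads over two
central-difference columns).

Scanning left to right, a maximal zero run bracketed by a positive jump
(rising outer flank) and then a negative jump (falling flank) is accepted
as a main-spot segment when it is at least `l_min = 8` px long; the run
and one edge width on either side are labelled `main_spot`. Shorter
bracketed runs and unpaired jumps carry the rapid sign alternation of
speckle and are labelled `diffraction`. The `l_min` default sits inside
the interval bracketed by observed behaviour on real frames — runs of 16
and 47 px are spot, a run of 5 px is not — and both thresholds are
exposed in the configuration.

Erasure then replaces every non-accepted pixel that is either
target-flagged or carries a non-zero gradient with a background value;
accepted main-spot pixels are preserved bit for bit, and flat unflagged
pixels (true background) are untouched. The replacement value is the same
$S_j$-window prediction restricted to background-like pixels (unflagged,
flat, and near the global background level): $S_j$ is by definition a set
of background points, and inside a dense speckle band the unrestricted
mean would be speckle, not background. Where the window holds no such
pixel the global background median is used. The prediction is computed
once from the input frame, so rows are independent and the result is
order-invariant; the *pipeline* iterates the whole screen/de-diffract pass
(`n_iterations = 2` by default) because the second pass catches speckle
that fell outside the first screen's intervals.

## Stage 3: ring measurement and geometric correction

On the cleaned frame, each interval is re-measured: the accepted zero-run
plateau on the spot's center row spans the ring interior, and the two
sharp edges add one pixel per side, so $d$ = plateau length + 2 and $r$ is
the plateau's offset from the flat side. The orientation comes from the
asymmetry of the run inside its bright bounding box (flush against the
arc side, $r$ away from the flat side). Fragmented components can measure
the same physical ring twice; measurements with radially overlapping
bands at one center are collapsed to the widest. Measurements without an
accepted plateau fall back to a bright run and are flagged unreliable.

With relative defocus assigned (equally spaced surfaces, $z_i = i$, unless
supplied), the shared scales are fitted as medians of the per-ring ratios
$d_i / z_i$ and $r_i / z_i$ over reliable rings — equal to the trusted
ring's ratio when only one ring is reliable, robust to one bad ring
otherwise. A ring whose width deviates from $\kappa_d z_i$ by more than
`width_tol = 3` px is replaced by the prediction and flagged corrected
(a conservative tolerance: the degradation this targets mismeasures by
ten pixels and more). Because all rings share the optical axis while a
fragmented interval can misplace one flat-side estimate, the stack center
is re-derived from two reliable rings' inner-edge apexes,

$$c = \frac{z_b x_a - z_a x_b}{z_b - z_a},$$

applied per coordinate — the same extrapolation that, fed the printed
apex centers (118, 180) and (182, 180) at defocus ratio 1:2, returns the
focused-surface center (54, 180). A missing surface is rebuilt from the
fitted scales; a missing *focused* surface ($z = 0$) becomes a point spot
whose diameter is the Airy footprint
`round(resolving_distance * magnification / pitch)` — 2 px for the
reference instrument (0.68 µm, 20×, 5.5 µm).

## Stage 4: beautification

A degraded ring is snapped to its ideal annulus: within the ring's
neighbourhood, pixels outside the annulus take the background gray (the
median outside all annuli unless configured); in-annulus pixels dimmer
than `tau_low = 0.1` take the gray of their longitudinal neighbour (same
column, one row toward the bright center row; the brighter neighbour on
the center row itself), and 1 — maximum brightness — when that reference
is also dim, so the repaired pixel cannot be mistaken for background.
`trim_to_standard_line()` is the variant that fills in-annulus voids with
the mean of their 8-connected non-void in-annulus neighbours, sweeping
alternately top-down and bottom-up (to avoid directional bias) until
stable. Both operations are idempotent. When several rings are nested,
`beautify_rings()` protects each annulus from its siblings' background
assignment; the pipeline additionally clears everything inside the
detected intervals that no ideal annulus claims.

## The synthetic scene generator

`scene_spec()` / `render_scene()` produce the study frames with per-pixel
ground truth. Defaults echo the reference instrument's worked geometry:
$\kappa_r = 64$, $\kappa_d = 17$ px per defocus unit, two surfaces at
defocus ratio 1:2 (hence widths 17 and 34 px and an inter-apex offset of
64 px), peak intensity 0.85, vertical falloff sigma of three quarters of
the largest outer radius (arm ends dim but still screenable), background
noise sigma 0.004 (about one 8-bit level), and 8-bit quantization applied
last so `normalize_image()` round-trips. Diffraction is phenomenological,
not wave optics: grains of 4×2 px with independent uniform intensities
(0.5–1 times the amplitude, 0.55 by default) packed into a band hugging
the ring's outer edge at 1.2 grains' worth of pixels per band pixel,
overwriting each other rather than accumulating so that density never
smooths the texture into a plateau. Speckle is not dimmed vertically —
on the real instrument its brightness is comparable to the main spot
throughout. Only grain pixels brighter than 0.05 are recorded as planted
diffraction in the truth map; dimmer ones are indistinguishable from
background by construction.

The "strong diffraction" fixture family used by the resolution tests sets
the band three ring widths wide at double packing density, which
reproduces the failure modes the pipeline exists to fix: the band bridges
the gap between rings (undercounted intervals before cleaning) and
inflates the apparent ring width several-fold.

What passing these tests shows — and what it does not: the generator
reproduces the *geometry* (exact proportionality, rasterized half-annuli),
the *intensity profile* qualitatively (vertical falloff, uniform plateau),
and the *gradient statistics* of speckle (short chaotic runs against long
flat ones). It does not model physical point-spread functions, coherent
interference fringes, detector blooming, or non-Gaussian camera noise, so
thresholds tuned here (`tau_e`, `eps_zero`, `tau_jump`) should be
re-examined against real frames, for which every one of them is exposed in
`autofocus_config()`.

```{r scene, eval = FALSE}
sc <- render_scene(scene_spec(seed = 7))
res <- run_pipeline(sc$image)
tidy(res)
autoplot(res)
```

## Resolution probe

`resolution_probe()` renders a two-surface template over a grid of axial
separations and reports the smallest separation at which the rings are
resolved before and after processing. On the raw frame "resolved" is an
operational image test: two distinct bright runs on the center row, with
pinholes of up to 4 px bridged (chaotic bands are porous) and runs under
3 px ignored. After cleaning, the rings measured from the main-spot runs
must satisfy $r_2 \ge r_1 + d_1$. On the strong-diffraction template the
processed minimum is about a third of the raw one (the test suite asserts
at most one half), and the beautified ring occupies under 0.3 of the
diffraction-inflated raw width — the mechanism by which cleaning restores
the interlayer resolution the speckle destroyed. Problem sizes are kept
modest (260×150 px frames, 15 grid points) so the whole probe runs in a
few seconds.

## Numerical choices and edge cases

* Two gradient formulations are in circulation for this scheme — the
  half-difference $\Delta g_k$ and a $[1\ 0\ {-1}]$ convolution stencil,
  which differ by sign and a factor of two. The half-difference is
  normative here; the stencil is treated as its illustration. All
  thresholds are stated on the half-difference scale.
* `classify_row()` on a row with no jumps returns all-background; an
  interval-less `dediffract()` call is the identity.
* Rings are rasterized as $\rho \in [r, r+d)$ (half-open), which makes
  "just resolved" ($r_2 = r_1 + d_1$) correspond exactly to disjoint
  pixel sets, and a rendered width of exactly $d$ pixels along the center
  row.
* Orientation of a focused point spot is undefined (`NA`); it is excluded
  from scale fitting and protected, not beautified.
* The orientation-to-sign convention of `defocus_from_ring()` is
  configurable (`positive_orientation`), since the physical assignment
  depends on which side of focus the instrument places "up"; defocus is
  reported in relative units unless a calibration constant is supplied.
* Measurement-stage ties: when several main-spot runs lie in one interval
  (nested rings), the widest is taken — an interval's own ring is the
  outermost, hence widest, structure it fully contains.

## Known limitations

* The row classifier erases the extreme arm-tip rows of a ring, whose
  chord runs are shorter than `l_min`; this costs a fraction of a percent
  of ring pixels and does not move the measured geometry.
* Interval detection under-counts when speckle genuinely glues rings
  together on the raw frame — by design this is recovered by re-screening
  after cleaning, which can only increase the count.
* The equal-spacing default for relative defocus matches stacked samples
  with uniform layer separation; uneven stacks need explicit `z`.
* Absolute defocus requires an external calibration; the package works in
  relative units throughout.
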