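# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the full default phantom (study conditions: 160 x 160 x 200, 0.1 mm)
full_phantom <- function() cached("full_phantom", function() {
  build_phantom(phantom_spec())
})

# noiseless renders of the full phantom with the filtered-protocol basis
full_renders <- function() cached("full_renders", function() {
  ph <- full_phantom()
  b <- basis_filtered()
  list(low = render_ct(ph, b, "low", noise_sigma = 0),
       high = render_ct(ph, b, "high", noise_sigma = 0))
})

# a short-z phantom for cheaper geometric tests (same xy layout, 12 mm tall;
# tall enough that the vessel tubes stay far above the bead size window)
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(160, 160, 120), bead_z_range = c(2, 10), ...)
}

small_phantom <- function() cached("small_phantom", function() {
  build_phantom(small_phantom_spec())
})

# center of the small phantom, used as misalignment rotation center
small_center <- c(7.95, 7.95, 5.95)

# ROIs of the small phantom (same in-plane positions, shallower z)
small_rois <- function(which = "eval") {
  rois <- phantom_rois(which)
  lapply(rois, function(r) roi_spec(c(r$center_mm[1:2], 6), r$edge_mm, r$label))
}

# a two-voxel "phantom" with hand-set fractions, for closed-form render tests
tiny_phantom <- function(fr_soft, fr_bone, fr_vessel) {
  d <- c(length(fr_soft), 1L, 1L)
  zero <- array(0, dim = d)
  fractions <- list(
    soft_tissue = array(fr_soft, dim = d), bone = array(fr_bone, dim = d),
    vessel = array(fr_vessel, dim = d), ptfe = zero, water = zero,
    air_vial = zero, calibrator = zero,
    air = array(10000 - fr_soft - fr_bone - fr_vessel, dim = d))
  structure(list(fractions = fractions,
                 labels = array(1L, dim = d),
                 bead_centroids = matrix(numeric(0), ncol = 3),
                 spec = list(spacing = 0.1, noise_sigma = 0, seed = 1L)),
            class = "dect_phantom")
}

# a bare spectrum object with chosen fluence, for closed-form beam tests
manual_spectrum <- function(energies, fluence, kvp = max(energies) + 1) {
  structure(list(kvp = kvp, energies = energies, fluence = fluence,
                 provenance = list()), class = "xray_spectrum")
}
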