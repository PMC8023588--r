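# Shared fixtures: small phantom geometries keep the unit tests fast; the
# full-size default geometry is exercised where a contract depends on it.

small_phantom_config <- function(n_frames = 12L, seed = 1L,
                                 voi_label = "calcification",
                                 guidewire_width = 5L, ...) {
  phantom_config(n_alines = 96L, n_radial = 120L, n_frames = n_frames,
                 voi_label = voi_label,
                 lumen_radius_mean = 18, lumen_radius_amplitude = 6,
                 guidewire_width = guidewire_width,
                 lesion_params = list(depth_px = 8, thickness_px = 28,
                                      arc_extent_deg = 130),
                 seed = seed, ...)
}

small_preprocess_config <- function() preprocess_config(crop_depth = 64L)

small_preprocessed_voi <- function(n_frames = 12L, seed = 1L, ...) {
  preprocess_voi(generate_voi(small_phantom_config(n_frames, seed, ...)),
                 small_preprocess_config())
}

# Archetype construction used for planted-cluster-structure tests: three
# clearly distinct lesion morphologies, the third confined to a short
# terminal block that stride-10 equal spacing never reaches.
cluster_archetypes <- function() {
  a <- list(
    list(arc_center_deg = 60, depth_px = 8, thickness_px = 16,
         arc_extent_deg = 40),
    list(arc_center_deg = 180, depth_px = 10, thickness_px = 30,
         arc_extent_deg = 200),
    list(arc_center_deg = 300, depth_px = 18, thickness_px = 55,
         arc_extent_deg = 330))
  attr(a, "weights") <- c(22, 12, 6)
  a
}

archetype_blocks <- function(n = 40L) rep(1:3, times = c(22L, 12L, 6L))

archetype_voi_config <- function(seed) {
  phantom_config(n_alines = 96L, n_radial = 120L, n_frames = 40L,
                 speckle_scale = 0.45,
                 lumen_radius_mean = 18, lumen_radius_amplitude = 6,
                 guidewire_width = 5L,
                 lesion_params = list(depth_px = 8, thickness_px = 28,
                                      z_drift = 0.015),
                 seed = seed)
}
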