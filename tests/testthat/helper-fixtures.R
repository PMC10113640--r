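# Shared lightweight fixtures for fast unit tests.

tiny_design <- function(weeks = 1) {
  study_design(session_weeks = weeks)
}

# Small, flat histology phantom: constant density, fixed hole and kill zone.
tiny_phantom <- function(density = 900, killzone = 120, hole = c(40, 20),
                         elongation = 0.079, noise_sd = 0.04) {
  histo_phantom(
    image_shape = c(360, 360), pixel_size_um = 1,
    density_profile = function(d) rep(density, length(d)),
    hole_half_axes = function(d) hole,
    killzone_radius = function(d) rep(killzone, length(d)),
    elongation_gradient = elongation, noise_sd = noise_sd
  )
}

# Classifier trained on one rendered slice's ground truth.
train_on_slice <- function(slice, blur_sigma = 1, seed = 1) {
  pre <- preprocess_slice(slice$image, blur_sigma = blur_sigma)
  train_pixel_classifier(list(pre), list(nucleus_mask(slice)), seed = seed)
}

# Rasterised disk mask (binary matrix), radius in pixels.
disk_mask <- function(r_px, pad = 4) {
  n <- 2 * (r_px + pad) + 1
  ctr <- r_px + pad + 1
  xx <- outer(rep(1, n), seq_len(n)) - ctr
  yy <- outer(seq_len(n), rep(1, n)) - ctr
  (xx^2 + yy^2) <= r_px^2
}
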