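# Shared fixture builders. Everything is generated in code at test time.

# Rasterise a filled disk (pixel-centre membership), value inside, 0 outside.
draw_disk <- function(h, w, cy, cx, r, value = 100) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(0, h, w)
  m[(rows - cy)^2 + (cols - cx)^2 <= r^2] <- value
  m
}

# Rasterise a filled axis-rotated ellipse (semi-axes a, b in px).
draw_ellipse <- function(h, w, cy, cx, a, b, theta = 0, value = 100) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dx <- cols - cx; dy <- rows - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  m <- matrix(0, h, w)
  m[u^2 + v^2 <= 1] <- value
  m
}

# The liver-like study composition used throughout validation.
study_fractions <- function() {
  c(NPC_2n = 0.4, HEP_2c = 0.3, HEP_4c = 0.2, HEP_8c = 0.07, HEP_16c = 0.03)
}

# Standard validation cohort: 2,000 nuclei, 10% bilobular, 2% Gaussian
# noise, 0.5 um/px.
make_standard_cohort <- function(seed = 2024, n_nuclei = 2000,
                                 bilobular_fraction = 0.1,
                                 noise = noise_model()) {
  spec <- acquisition_spec(pixel_size_um = 0.5,
                           height_px = 1500, width_px = 1500)
  comp <- population_composition(study_fractions(), n_nuclei = n_nuclei,
                                 bilobular_fraction = bilobular_fraction)
  generate_field(spec, comp, noise, seed = seed)
}

# Small noiseless field for exact oracle checks.
make_noiseless_field <- function(seed = 7, n_nuclei = 50,
                                 channels = c("hoechst", "hnf4a"),
                                 marker_prevalence = NULL,
                                 side_px = 700) {
  spec <- acquisition_spec(pixel_size_um = 0.5, height_px = side_px,
                           width_px = side_px, channels = channels)
  comp <- population_composition(study_fractions(), n_nuclei = n_nuclei)
  generate_field(spec, comp, noise_model(0, gaussian_sigma = 0),
                 seed = seed, marker_prevalence = marker_prevalence)
}

# Brute-force per-label pixel statistics (independent of extract_features).
brute_label_stats <- function(labels, channel) {
  ids <- sort(unique(labels[labels > 0]))
  do.call(rbind, lapply(ids, function(i) {
    v <- channel[labels == i]
    data.frame(nucleus_id = i, npx = length(v), sum = sum(v),
               mean = mean(v))
  }))
}
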