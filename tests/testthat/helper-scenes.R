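# Scene configurations used across the suite.

# Noise-free detector: detections coincide with ground truth.
zero_noise_config <- function(seed, n_objects = 5L, duration = 30) {
  scene_config(duration = duration, n_objects = n_objects,
               miss_prob = 0, fp_rate = 0, loc_noise_sd = 0, seed = seed)
}

# The moderate-noise detector regime: 10% dropouts, 2 px localization
# noise, 0.01 spurious boxes per frame (the scene_config defaults).
noisy_config <- function(seed, n_objects = 5L, duration = 30) {
  scene_config(duration = duration, n_objects = n_objects, seed = seed)
}

# A hand-scripted confirmed-track row in the format tracker_step() emits.
track_row <- function(id, x, y, w, h, observed = TRUE) {
  data.frame(track_id = id, x = x, y = y, w = w, h = h, conf = 0.9,
             observed = observed, hits = 3L, time_since_update = 0L)
}
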