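## Shared fixtures: small, fast instances of the generator's stated world.

## single arm-free Gaussian cell on a dark field (closed-form oracles)
single_gauss_field <- function(sigma_px, field = 96L, noise = 0,
                               territory_um = 25, seed = 1) {
  cfg <- gen_config(field_size = field, pixel_size = 1, n_cells = 1L,
                    soma_sigma = sigma_px, territory_radius = territory_um,
                    n_arms = 0L, arm_amp = 0, background = 0,
                    struct_noise_sd = noise)
  ctr <- matrix(c(field / 2, field / 2), 1)
  list(field = make_astrocyte_field(cfg, seed = seed, centers = ctr),
       config = cfg, center = c(field / 2, field / 2))
}

## small noiseless movie world for event-detection oracles
oracle_movie <- function(seed = 7, duration = 20, onset = 20) {
  cfg <- gen_config(noise_sd = 0, struct_noise_sd = 0, basal_rate = 0,
                    movie_duration = max(60, onset + duration + 10))
  field <- make_astrocyte_field(cfg, seed = seed)
  pr <- stimulus_protocol(onset, duration, 2, 2)
  sim <- simulate_calcium_movie(field, pr, cfg, seed = seed)
  list(config = cfg, field = field, protocol = pr, sim = sim)
}

## a bare trace object
bare_trace <- function(f, dt = 0.5, roi = "t", comp = "microdomain") {
  gliawave:::new_trace(roi, comp, f, dt)
}

## ECoG tone helper: pure sinusoid recording
tone_recording <- function(freq, amp = 1, fs = 10000, dur = 6, extra = NULL) {
  tt <- (seq_len(fs * dur) - 1) / fs
  x <- amp * sin(2 * pi * freq * tt)
  if (!is.null(extra)) x <- x + extra(tt)
  ecog_recording(x, sampling_rate = fs)
}
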