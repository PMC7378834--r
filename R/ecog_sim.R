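## pink (1/f) noise by FFT spectral shaping, flattened below f_floor
pink_noise <- function(n, fs, rms, f_floor = 0.5, f_ceiling = NULL) {
  nfft <- stats::nextn(n, 2)
  f <- c(0, seq_len(nfft / 2), seq.int(nfft / 2 - 1, 1)) * fs / nfft
  shape <- 1 / sqrt(pmax(f, f_floor))
  shape[1] <- 0
  if (!is.null(f_ceiling)) shape[f > f_ceiling] <- 0
  z <- stats::rnorm(nfft) + 1i * stats::rnorm(nfft)
  x <- Re(stats::fft(stats::fft(z) * shape, inverse = TRUE))[seq_len(n)]
  x * rms / stats::sd(x)
}

#' Simulate an ECoG recording with a controlled gamma envelope
#'
#' The synthetic field potential is the sum of (i) pink (1/f) background noise
#' scaled to `pink_rms`, (ii) Poisson-timed up-state transients (half-sine
#' bumps with the reference amplitude 0.17 +/- 0.05 mV and duration
#' 0.93 +/- 0.10 s), and (iii) a deterministic gamma comb: tones placed
#' exactly on the FFT bin grid of the analysis spectrogram
#' (`gamma_bins` x sampling_rate / `analysis_window`, spanning 30--50 Hz),
#' amplitude-modulated so the measured 30--50 Hz band power tracks
#' `gamma_envelope` in dB. Because on-bin tones plus their one-bin Hamming
#' leakage drive every gamma-band bin, all band bins scale together with the
#' envelope and the band's mean dB follows it analytically.
#'
#' @param protocol a [stimulus_protocol()]
#' @param config a [gen_config()]
#' @param gamma_envelope optional list with `times` and `db` (relative gamma,
#'   dB) sampled on the feedback clock, e.g. from [simulate_feedback()]; the
#'   default is a `ecog_peak_gamma_db` plateau during the stimulus
#' @param seed integer seed
#' @param duration recording length, seconds (default: cover the envelope or
#'   protocol plus 20 s)
#' @return list with `recording` ([ecog_recording()]) and `truth` (up-state
#'   table, envelope sampler, tone frequencies)
#' @export
simulate_ecog <- function(protocol, config = gen_config(),
                          gamma_envelope = NULL, seed = 1, duration = NULL) {
  fs <- config$sampling_rate
  if (inherits(gamma_envelope, "feedback_sim")) {
    gamma_envelope <- list(times = gamma_envelope$times, db = gamma_envelope$gamma)
  }
  duration <- duration %||%
    (if (!is.null(gamma_envelope)) max(gamma_envelope$times)
     else protocol$onset + protocol$duration + 20)
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  set.seed(child_seed(seed, "ecog"))
  x <- pink_noise(n, fs, config$pink_rms, f_ceiling = 500)

  ## up-states: thinned Poisson, no overlap
  ups <- data.frame(onset = numeric(0), duration = numeric(0),
                    amplitude = numeric(0))
  if (config$upstate_rate > 0) {
    n_up <- stats::rpois(1, config$upstate_rate * duration)
    if (n_up > 0) {
      t_up <- sort(stats::runif(n_up, 1, max(1, duration - 3)))
      keep <- numeric(0)
      for (ti in t_up) {
        if (!length(keep) || ti - keep[length(keep)] >= 3) keep <- c(keep, ti)
      }
      for (ti in keep) {
        du <- min(2, max(0.3, stats::rnorm(1, config$upstate_duration,
                                           config$upstate_duration_sd)))
        am <- max(0.1, stats::rnorm(1, config$upstate_amplitude,
                                     config$upstate_amplitude_sd))
        sel <- tt >= ti & tt < ti + du
        x[sel] <- x[sel] + am * sin(pi * (tt[sel] - ti) / du)
        ups <- rbind(ups, data.frame(onset = ti, duration = du, amplitude = am))
      }
    }
  }

  ## relative gamma envelope in dB, sampled on the ECoG clock
  env_db <- if (is.null(gamma_envelope)) {
    config$ecog_peak_gamma_db *
      as.numeric(tt >= protocol$onset & tt < protocol$onset + protocol$duration)
  } else {
    stats::approx(gamma_envelope$times, gamma_envelope$db, xout = tt,
                  rule = 2)$y
  }
  amp <- config$gamma_tone_amp * 10^(env_db / 20)
  tone_freqs <- config$gamma_bins * fs / config$analysis_window
  phases <- stats::runif(length(tone_freqs), 0, 2 * pi)
  for (j in seq_along(tone_freqs)) {
    x <- x + amp * cos(2 * pi * tone_freqs[j] * tt + phases[j])
  }
  list(recording = ecog_recording(x, sampling_rate = fs, t0 = 0),
       truth = list(upstates = ups, envelope_db = env_db[seq(1, n, by = 100)],
                    envelope_times = tt[seq(1, n, by = 100)],
                    tone_freqs = tone_freqs))
}
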