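#' Spectral analysis configuration
#'
#' The field-potential processing chain: an FIR lowpass below 100 Hz, a
#' Hamming-window spectrogram of length 4096 samples converted to decibels,
#' Welch smoothing of the temporal frequency dynamics, and band averages over
#' low (0-1), delta (0-4), theta (4-7), alpha (8-12), beta (13-30) and gamma
#' (30-50 Hz). Band intervals are half-open `[f_lo, f_hi)`; low and delta
#' overlap as in the reference band table.
#'
#' @param lowpass_cutoff FIR lowpass cutoff, Hz
#' @param window_length spectrogram window, samples
#' @param window_kind taper (only "hamming" implemented)
#' @param overlap_fraction window overlap in `[0, 0.95)`
#' @param welch_segments periodograms averaged per output time point
#' @param bands named list of `c(f_lo, f_hi)` pairs, Hz
#' @param peak_search_window seconds after onset searched for the gamma peak
#' @param steady_state_start seconds after onset where the steady state begins
#' @param upstate_threshold_sd envelope threshold in SDs above the mean
#' @param upstate_duration_range accepted up-state durations, seconds
#' @param upstate_env_cutoff envelope smoothing cutoff, Hz
#' @param upstate_min_amplitude minimum up-state amplitude, mV (reference
#'   up-states are 0.17 +/- 0.05 mV; the floor rejects slow background
#'   excursions of the pink 1/f noise)
#' @param db_floor power floor before dB conversion (guards log of zero)
#' @return list of class `SpectralConfig`
#' @export
spectral_config <- function(lowpass_cutoff = 100,
                            window_length = 4096L,
                            window_kind = "hamming",
                            overlap_fraction = 0.75,
                            welch_segments = 4L,
                            bands = list(low = c(0, 1), delta = c(0, 4),
                                         theta = c(4, 7), alpha = c(8, 12),
                                         beta = c(13, 30), gamma = c(30, 50)),
                            peak_search_window = 10,
                            steady_state_start = 50,
                            upstate_threshold_sd = 2,
                            upstate_duration_range = c(0.3, 2.0),
                            upstate_env_cutoff = 10,
                            upstate_min_amplitude = 0.1,
                            db_floor = 1e-20) {
  if (overlap_fraction < 0 || overlap_fraction >= 0.95) {
    stopf("overlap_fraction must lie in [0, 0.95)")
  }
  if (window_kind != "hamming") stopf("only the hamming taper is implemented")
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    if (!(lo >= 0 && lo < hi && hi <= lowpass_cutoff)) {
      stopf("band %s must satisfy 0 <= f_lo < f_hi <= lowpass_cutoff", b)
    }
  }
  structure(as.list(environment()), class = "SpectralConfig")
}

## windowed-sinc lowpass kernel with a Hamming taper (odd length, unit DC)
fir_lowpass_kernel <- function(cutoff, fs, ntaps = NULL) {
  ntaps <- ntaps %||% {
    ## Hamming transition width ~ 3.3 fs / N; keep the 0.8-1.2 x cutoff
    ## transition band inside spec (ripple < 0.1 dB below, > 40 dB above)
    n <- ceiling(3.3 * fs / (0.4 * cutoff) * 1.2)
    n + (1 - n %% 2)
  }
  m <- (ntaps - 1) / 2
  t <- seq(-m, m)
  h <- 2 * cutoff / fs * sinc(2 * cutoff * t / fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (t + m) / (ntaps - 1))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR lowpass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR applied by FFT convolution with
#' group-delay compensation: zero phase, output length equals input length,
#' passband ripple below 0.1 dB under 0.8 x cutoff and at least 40 dB of
#' attenuation above 1.2 x cutoff.
#'
#' @param rec an [ecog_recording()] (or numeric vector with `fs` given)
#' @param config a [spectral_config()] (or `cutoff` override)
#' @param fs sampling rate when `rec` is a bare vector
#' @return filtered recording of the same class/length
#' @export
lowpass_fir <- function(rec, config = spectral_config(), fs = NULL) {
  x <- if (inherits(rec, "EcogRecording")) rec$samples else rec
  fs <- if (inherits(rec, "EcogRecording")) rec$sampling_rate else fs
  stopifnot(is_scalar_num(fs))
  if (fs <= 2 * config$lowpass_cutoff) {
    stopf("sampling rate %g Hz too low for a %g Hz lowpass", fs,
          config$lowpass_cutoff)
  }
  k <- fir_lowpass_kernel(config$lowpass_cutoff, fs)
  if (length(x) < 3 * length(k)) {
    stopf("signal shorter than 3 x filter order (%d samples)", 3 * length(k))
  }
  y <- fft_filter(x, k)
  if (inherits(rec, "EcogRecording")) {
    out <- rec; out$samples <- y; out
  } else y
}

#' Spectrogram in decibels
#'
#' Sliding Hamming-windowed one-sided periodograms (length
#' `window_length`, hop `window_length x (1 - overlap_fraction)`), power
#' spectral density referenced to 1 mV^2/Hz and converted to
#' `10 log10(psd)` dB; zero power is guarded by `db_floor`. Frequencies are
#' restricted to the lowpass analysis range. Time stamps are window centers
#' on the recording's protocol clock.
#'
#' @param rec an [ecog_recording()]
#' @param config a [spectral_config()]
#' @return object of class `spectrogram`: list with `times` (s), `freqs`
#'   (Hz), `db` (freq x time matrix)
#' @export
spectrogram_db <- function(rec, config = spectral_config()) {
  stopifnot(inherits(rec, "EcogRecording"))
  x <- rec$samples
  N <- config$window_length
  if (length(x) < N) stopf("recording shorter than one %d-sample window", N)
  fs <- rec$sampling_rate
  hop <- max(1L, as.integer(round(N * (1 - config$overlap_fraction))))
  starts <- seq.int(1L, length(x) - N + 1L, by = hop)
  n <- seq_len(N) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * n / (N - 1))
  seg <- vapply(starts, function(s) x[s:(s + N - 1L)] * w, numeric(N))
  sp <- stats::mvfft(seg)
  keep <- seq_len(floor(N / 2) + 1L)
  freqs <- (keep - 1) * fs / N
  scale <- 2 / (fs * sum(w^2))
  psd <- Mod(sp[keep, , drop = FALSE])^2 * scale
  psd[1, ] <- psd[1, ] / 2                      # DC not doubled
  if (N %% 2 == 0) psd[length(keep), ] <- psd[length(keep), ] / 2
  sel <- freqs <= config$lowpass_cutoff
  db <- 10 * log10(pmax(psd[sel, , drop = FALSE], config$db_floor))
  structure(list(times = rec$t0 + (starts - 1 + (N - 1) / 2) / fs,
                 freqs = freqs[sel], db = db, fs = fs, config = config),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d freqs (%.2f-%.1f Hz, df=%.3f) x %d windows\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], length(x$times)))
  invisible(x)
}

#' Welch smoothing of a spectrogram along time
#'
#' Each output time point is the average (in linear power) of
#' `welch_segments` neighbouring windowed periodograms, reducing per-bin
#' variance by roughly the segment count; a centred window that shrinks at
#' the edges preserves the time axis.
#'
#' @param spec a [spectrogram_db()] result
#' @param config a [spectral_config()]
#' @return smoothed `spectrogram`
#' @export
smooth_welch <- function(spec, config = spectral_config()) {
  k <- as.integer(config$welch_segments)
  if (k <= 1L) return(spec)
  if (ncol(spec$db) < k) stopf("fewer spectrogram columns than welch_segments")
  p <- 10^(spec$db / 10)
  m <- ncol(p)
  half_lo <- floor((k - 1) / 2); half_hi <- k - 1 - half_lo
  sm <- vapply(seq_len(m), function(j) {
    cols <- max(1L, j - half_lo):min(m, j + half_hi)
    rowMeans(p[, cols, drop = FALSE])
  }, numeric(nrow(p)))
  spec$db <- 10 * log10(pmax(sm, spec$config$db_floor))
  spec
}

#' Band power over time
#'
#' Mean of the dB values over the frequency bins in `[f_lo, f_hi)`, per time
#' point.
#'
#' @param spec a [spectrogram_db()] result
#' @param band band name from the config, or a numeric `c(f_lo, f_hi)`
#' @param config a [spectral_config()]
#' @return object of class `BandPowerSeries`: list with `band`, `times`,
#'   `power_db` (and `relative_db` after [relative_power()])
#' @export
band_power <- function(spec, band = "gamma", config = spectral_config()) {
  rng <- if (is.character(band)) {
    config$bands[[band]] %||% stopf("unknown band: %s", band)
  } else band
  sel <- spec$freqs >= rng[1] & spec$freqs < rng[2]
  if (!any(sel)) stopf("band [%g, %g) Hz contains no frequency bins", rng[1], rng[2])
  structure(list(band = if (is.character(band)) band else sprintf("%g-%g Hz", rng[1], rng[2]),
                 range = rng, times = spec$times,
                 power_db = colMeans(spec$db[sel, , drop = FALSE])),
            class = "BandPowerSeries")
}

#' @export
print.BandPowerSeries <- function(x, ...) {
  cat(sprintf("BandPowerSeries %s: %d points, %.1f to %.1f dB%s\n", x$band,
              length(x$times), min(x$power_db), max(x$power_db),
              if (!is.null(x$relative_db)) " (relative set)" else ""))
  invisible(x)
}

#' Relative band power versus a pre-stimulus baseline
#'
#' `relative_db(t) = power_db(t) - mean(power_db over the baseline window)`;
#' dB differences are reference-free.
#'
#' @param series a [band_power()] result
#' @param baseline_window `c(t0, t1)` seconds; must cover at least 5 windows
#' @param protocol optional [stimulus_protocol()]; an error is raised if the
#'   baseline overlaps the stimulus
#' @return the series with `relative_db` and `baseline_db` added
#' @export
relative_power <- function(series, baseline_window, protocol = NULL) {
  if (!is.null(protocol) && baseline_window[2] > protocol$onset) {
    stopf("baseline window [%g, %g] overlaps the stimulus (onset %g s)",
          baseline_window[1], baseline_window[2], protocol$onset)
  }
  sel <- series$times >= baseline_window[1] & series$times <= baseline_window[2]
  if (!any(sel)) stopf("empty baseline window")
  if (sum(sel) < 5) stopf("baseline window spans fewer than 5 spectrogram windows")
  series$baseline_db <- mean(series$power_db[sel])
  series$relative_db <- series$power_db - series$baseline_db
  series
}

as_relative_series <- function(x) {
  if (inherits(x, "BandPowerSeries")) {
    if (is.null(x$relative_db)) stopf("series has no relative_db; run relative_power()")
    list(times = x$times, db = x$relative_db)
  } else if (inherits(x, "feedback_sim")) {
    list(times = x$times, db = x$gamma)
  } else {
    stopifnot(!is.null(x$times), !is.null(x$db))
    x
  }
}

#' Gamma peak, steady state and their ratio
#'
#' Peak = maximum relative gamma within `peak_search_window` after onset;
#' steady state = mean relative gamma from `steady_state_start` after onset
#' to stimulus offset; ratio = 100 x steady/peak (the astrocyte-dampening
#' index). For stimuli shorter than `steady_state_start` the steady state is
#' undefined and flagged `NA`.
#'
#' @param series a relative [band_power()] series (or a `feedback_sim`)
#' @param protocol a [stimulus_protocol()]
#' @param config a [spectral_config()]
#' @return list of class `GammaMetrics`: `peak_db`, `steady_state_db`,
#'   `ratio` (%)
#' @export
gamma_metrics <- function(series, protocol, config = spectral_config()) {
  s <- as_relative_series(series)
  pk_sel <- s$times >= protocol$onset &
    s$times <= protocol$onset + config$peak_search_window
  if (!any(pk_sel)) stopf("no samples in the peak search window")
  peak <- max(s$db[pk_sel])
  ss <- NA_real_; ratio <- NA_real_
  if (protocol$duration > config$steady_state_start) {
    ss_sel <- s$times >= protocol$onset + config$steady_state_start &
      s$times <= protocol$onset + protocol$duration
    ss <- mean(s$db[ss_sel])
    if (peak > 0) ratio <- 100 * ss / peak
  }
  structure(list(peak_db = peak, steady_state_db = ss, ratio = ratio,
                 steady_state_defined = protocol$duration > config$steady_state_start),
            class = "GammaMetrics")
}

#' @export
print.GammaMetrics <- function(x, ...) {
  cat(sprintf("GammaMetrics: peak %.2f dB, steady state %.2f dB, ratio %.1f%%\n",
              x$peak_db, x$steady_state_db, x$ratio))
  invisible(x)
}

#' Detect up-states in a lowpass-filtered recording
#'
#' Up-states are slow large-amplitude deflections: the signal is restricted
#' to frequencies below `upstate_env_cutoff` Hz (which also removes gamma
#' oscillations from the envelope), rectified and smoothed into an envelope.
#' Detection uses hysteresis thresholding: an up-state is triggered where the
#' envelope exceeds mean + `upstate_threshold_sd` x SD and extends outward to
#' the crossings of mean + 0.5 x SD; an excursion must last within
#' `upstate_duration_range` and reach `upstate_min_amplitude`. Amplitude is the maximum absolute deviation of
#' the low-frequency signal within the excursion. Apply to baseline
#' (pre-stimulus) epochs: a sustained stimulus response inflates the
#' threshold.
#'
#' @param rec a lowpass-filtered [ecog_recording()]
#' @param config a [spectral_config()]
#' @return data.frame with columns `onset`, `duration`, `amplitude`
#' @export
detect_upstates <- function(rec, config = spectral_config()) {
  stopifnot(inherits(rec, "EcogRecording"))
  fs <- rec$sampling_rate
  k <- fir_lowpass_kernel(config$upstate_env_cutoff, fs,
                          ntaps = 2L * as.integer(fs / config$upstate_env_cutoff) + 1L)
  y <- fft_filter(rec$samples - stats::median(rec$samples), k)
  env <- fft_filter(abs(y), k)
  mu <- mean(env); s <- stats::sd(env)
  thr_hi <- mu + config$upstate_threshold_sd * s
  thr_lo <- mu + 0.5 * s
  above_lo <- env > thr_lo
  if (!any(env > thr_hi)) {
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      amplitude = numeric(0)))
  }
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(onset = numeric(0), duration = numeric(0),
                    amplitude = numeric(0))
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    if (max(env[seg]) <= thr_hi) next  # never reaches the trigger level
    dur <- r$lengths[i] / fs
    if (dur < config$upstate_duration_range[1] ||
        dur > config$upstate_duration_range[2]) next
    amp <- max(abs(y[seg]))
    if (amp < config$upstate_min_amplitude) next
    out <- rbind(out, data.frame(onset = rec$t0 + (starts[i] - 1) / fs,
                                 duration = dur, amplitude = amp))
  }
  out
}

#' Band response across stimulus conditions
#'
#' For each recording/protocol pair the steady-state relative power of the
#' band (mean over the second half of the stimulus, or from
#' `steady_state_start` for long stimuli), packaged as a [response_curve()]
#' for sigmoid fitting with a free floor.
#'
#' @param recordings list of [ecog_recording()]
#' @param protocols list of matching [stimulus_protocol()]
#' @param x stimulus parameter value per condition (strictly increasing)
#' @param kind stimulus parameter kind
#' @param band band name
#' @param baseline_window baseline `c(t0, t1)` for [relative_power()]
#' @param config a [spectral_config()]
#' @return a [response_curve()]
#' @export
band_response_curve <- function(recordings, protocols, x,
                                kind = c("duration", "frequency", "intensity"),
                                band = "gamma", baseline_window = NULL,
                                config = spectral_config()) {
  kind <- match.arg(kind)
  stopifnot(length(recordings) == length(protocols),
            length(recordings) == length(x))
  if (length(x) < 4) stopf("need at least 4 stimulus levels for curve fitting")
  y <- vapply(seq_along(recordings), function(i) {
    pr <- protocols[[i]]
    bw <- baseline_window %||% c(0, pr$onset)
    sp <- smooth_welch(spectrogram_db(lowpass_fir(recordings[[i]], config),
                                      config), config)
    bp <- relative_power(band_power(sp, band, config), bw)
    ss_start <- min(pr$onset + config$steady_state_start,
                    pr$onset + pr$duration / 2)
    sel <- bp$times >= ss_start & bp$times <= pr$onset + pr$duration
    mean(bp$relative_db[sel])
  }, numeric(1))
  response_curve(x, y, kind = kind)
}
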