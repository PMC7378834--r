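test_that("FIR lowpass meets its passband, stopband and phase contracts", {
  fs <- 2000
  sc <- spectral_config()
  tt <- (seq_len(4 * fs) - 1) / fs
  amp_out <- function(f_in) {
    y <- lowpass_fir(sin(2 * pi * f_in * tt), sc, fs = fs)
    ## avoid edges when measuring amplitude
    max(abs(y[fs:(3 * fs)]))
  }
  expect_equal(amp_out(40), 1, tolerance = 0.01)     # passband
  expect_lt(amp_out(300), 10^(-40 / 20))             # >= 40 dB attenuation

  ## zero phase: a low-frequency bump keeps its peak position
  bump <- exp(-(tt - 2)^2 / (2 * 0.05^2))
  y <- lowpass_fir(bump, sc, fs = fs)
  expect_lte(abs(which.max(y) - which.max(bump)), 1)

  ## output length equals input length; short input is rejected
  expect_length(y, length(bump))
  expect_error(lowpass_fir(rnorm(100), sc, fs = fs), "filter order")
  expect_error(lowpass_fir(rnorm(1000), sc, fs = 150), "too low")
})

test_that("spectrogram places tones on the right bins and scales in dB", {
  rec <- tone_recording(40, amp = 0.5)
  sc <- spectral_config()
  sp <- spectrogram_db(rec, sc)
  ## frequency resolution fs/4096 ~ 2.44 Hz; argmax at the bin nearest 40 Hz
  peak_bin <- sp$freqs[which.max(rowMeans(sp$db))]
  expect_equal(peak_bin, sp$freqs[which.min(abs(sp$freqs - 40))])
  expect_lt(abs(peak_bin - 40), sp$freqs[2] - sp$freqs[1])

  ## amplitude x10 adds exactly 20 dB everywhere
  set.seed(81)
  noise <- rnorm(60000, 0, 0.01)
  r1 <- ecog_recording(0.5 * sin(2 * pi * 40 * (0:59999) / 10000) + noise)
  r10 <- ecog_recording(10 * r1$samples)
  d1 <- spectrogram_db(r1, sc)$db
  d10 <- spectrogram_db(r10, sc)$db
  expect_equal(max(abs(d10 - d1 - 20)), 0, tolerance = 1e-9)

  ## zero signal is floored, not -Inf
  dz <- spectrogram_db(ecog_recording(rep(0, 8192)), sc)$db
  expect_true(all(is.finite(dz)))
  expect_equal(max(dz), 10 * log10(sc$db_floor))

  expect_error(spectrogram_db(ecog_recording(rnorm(1000)), sc), "window")
})

test_that("Welch smoothing averages periodograms and reduces variance", {
  sc <- spectral_config()
  rec <- tone_recording(40, amp = 0.3, dur = 8)
  sp <- spectrogram_db(rec, sc)

  ## one segment is the identity
  expect_equal(smooth_welch(sp, spectral_config(welch_segments = 1))$db, sp$db)

  ## constant-power input is unchanged
  spc <- sp; spc$db <- matrix(3, 5, 12); spc$config <- sc
  expect_equal(smooth_welch(spc, sc)$db, spc$db, tolerance = 1e-9)

  ## white noise, non-overlapping windows: variance drops ~ x segments
  set.seed(82)
  sc0 <- spectral_config(overlap_fraction = 0, welch_segments = 4)
  spn <- spectrogram_db(ecog_recording(rnorm(300 * 4096)), sc0)
  spw <- smooth_welch(spn, sc0)
  lin <- 10^(spn$db / 10); linw <- 10^(spw$db / 10)
  ratio <- median(apply(lin, 1, var) / apply(linw, 1, var))
  expect_equal(ratio, 4, tolerance = 0.3 * 4)
})

test_that("band power separates bands and respects dB arithmetic", {
  sc <- spectral_config()
  rec <- tone_recording(40, amp = 0.5, extra = function(tt) rnorm(length(tt), 0, 1e-4))
  sp <- spectrogram_db(rec, sc)
  g <- band_power(sp, "gamma", sc)
  th <- band_power(sp, "theta", sc)
  expect_gte(mean(g$power_db) - mean(th$power_db), 20)

  ## a DC-dominated signal maximizes the low band
  rec_dc <- ecog_recording(0.5 + rnorm(60000, 0, 1e-4))
  sp_dc <- spectrogram_db(rec_dc, sc)
  means <- vapply(names(sc$bands), function(b) {
    mean(band_power(sp_dc, b, sc)$power_db)
  }, numeric(1))
  expect_equal(names(which.max(means)), "low")

  ## superposition: each band tracks its own tone
  two <- function(a5, a40) {
    tt <- (0:59999) / 10000
    ecog_recording(a5 * sin(2 * pi * 5 * tt) + a40 * sin(2 * pi * 40 * tt) +
                     rnorm(60000, 0, 0.15))
  }
  spA <- spectrogram_db(two(0.1, 0.2), sc)
  spB <- spectrogram_db(two(1.0, 0.2), sc) # 5 Hz tone x10
  d_theta <- mean(band_power(spB, "theta", sc)$power_db) -
    mean(band_power(spA, "theta", sc)$power_db)
  d_gamma <- mean(band_power(spB, "gamma", sc)$power_db) -
    mean(band_power(spA, "gamma", sc)$power_db)
  expect_equal(d_theta, 20, tolerance = 1)
  ## residual change is Hamming sidelobe leakage from the x10 tone
  expect_lt(abs(d_gamma), 1.5)

  ## a single in-band tone keeps >= 80% of 0-100 Hz power in its band
  psd <- 10^(spectrogram_db(tone_recording(40, amp = 0.5), sc)$db / 10)
  tot <- rowMeans(psd)
  sel <- sp$freqs >= 30 & sp$freqs < 50
  expect_gte(sum(tot[sel]) / sum(tot), 0.8)

  expect_error(band_power(sp, c(200, 300), sc), "no frequency bins")

  ## identical input, identical spectrogram (no stochastic steps)
  expect_identical(spectrogram_db(rec, sc)$db, sp$db)
})

test_that("relative power subtracts the baseline and validates windows", {
  sc <- spectral_config()
  set.seed(83)
  tt <- (0:199999) / 10000
  ## stationary signal: relative power ~ 0 throughout (Welch-smoothed)
  rec <- ecog_recording(rnorm(length(tt), 0, 0.05))
  g <- relative_power(band_power(smooth_welch(spectrogram_db(rec, sc), sc),
                                 "gamma", sc), c(0, 10))
  ## no systematic drift; residual wiggle is chi-squared estimation noise
  post <- g$relative_db[g$times > 10]
  expect_lt(abs(mean(post)), 0.5)
  expect_lt(mean(abs(post)), 2)

  ## gamma amplitude stepped x10 at onset: relative gamma ~ +20 dB
  amp <- ifelse(tt >= 10, 2, 0.2)
  rec2 <- ecog_recording(amp * sin(2 * pi * 40 * tt) + rnorm(length(tt), 0, 0.01))
  g2 <- relative_power(band_power(spectrogram_db(rec2, sc), "gamma", sc), c(0, 9.5))
  expect_equal(mean(g2$relative_db[g2$times > 11]), 20, tolerance = 0.5)

  pr <- stimulus_protocol(10, 5)
  expect_error(relative_power(band_power(spectrogram_db(rec2, sc), "gamma", sc),
                              c(0, 12), pr), "overlaps")
  expect_error(relative_power(band_power(spectrogram_db(rec2, sc), "gamma", sc),
                              c(100, 101)), "baseline")
})

test_that("gamma metrics compute peak, steady state and their ratio", {
  sc <- spectral_config()
  ## constructed envelope: 15 dB for 10 s then 9 dB until 60 s
  times <- seq(0.5, 80, by = 0.5)
  db <- numeric(length(times))
  db[times > 20 & times <= 30] <- 15
  db[times > 30 & times <= 80] <- 9
  pr <- stimulus_protocol(20, 60)
  gm <- gamma_metrics(list(times = times, db = db), pr, sc)
  expect_equal(gm$peak_db, 15)
  expect_equal(gm$steady_state_db, 9)
  expect_equal(gm$ratio, 60)

  ## flat envelope: ratio 100%
  gm_flat <- gamma_metrics(list(times = times,
                                db = ifelse(times > 20 & times <= 80, 12, 0)),
                           pr, sc)
  expect_equal(gm_flat$ratio, 100)

  ## short stimulus: steady state undefined and flagged
  gm_short <- gamma_metrics(list(times = times, db = db),
                            stimulus_protocol(20, 20), sc)
  expect_true(is.na(gm_short$steady_state_db))
  expect_false(gm_short$steady_state_defined)

  ## feedback simulation: gain > 0 lowers the ratio vs gain = 0
  pr60 <- stimulus_protocol(20, 60, 5, 2)
  r_fb <- gamma_metrics(simulate_feedback(pr60, gen_config(), seed = 4), pr60)$ratio
  r_0 <- gamma_metrics(simulate_feedback(pr60, gen_config(feedback_gain = 0),
                                         seed = 4), pr60)$ratio
  expect_lt(r_fb, r_0)
})

test_that("up-state detection recovers injected transients and rejects noise", {
  sc <- spectral_config()
  fs <- 10000
  n <- 60 * fs
  tt <- (seq_len(n) - 1) / fs
  set.seed(84)
  x <- rnorm(n, 0, 0.02)
  for (ti in c(10, 30, 50)) {
    s <- tt >= ti & tt < ti + 0.9
    x[s] <- x[s] + 0.2 * sin(pi * (tt[s] - ti) / 0.9)
  }
  ups <- detect_upstates(ecog_recording(x, fs), sc)
  expect_equal(nrow(ups), 3)
  expect_equal(ups$amplitude, rep(0.2, 3), tolerance = 0.1)
  expect_lt(max(abs(ups$duration - 0.9)), 0.2)
  expect_equal(ups$onset, c(10, 30, 50), tolerance = 0.3)

  ## pure noise: at most 1 false detection per 60 s
  for (seed in 85:87) {
    set.seed(seed)
    fp <- detect_upstates(ecog_recording(rnorm(n, 0, 0.02), fs), sc)
    expect_lte(nrow(fp), 1)
  }

  ## zero signal: empty list
  expect_equal(nrow(detect_upstates(ecog_recording(rep(0, n), fs), sc)), 0)
})

test_that("band response curves recover the generating dose-response", {
  truth <- c(r_max = 12, r_50 = 6, r_slope = 0.4, r_min = 2)
  durs <- c(1, 2, 5, 10, 20, 40)
  recs <- list(); prots <- list()
  for (i in seq_along(durs)) {
    pr <- stimulus_protocol(15, durs[i], 5, 2)
    cfg <- gen_config(ecog_peak_gamma_db = evaluate_sigmoid(truth, durs[i]))
    ec <- simulate_ecog(pr, cfg, seed = 200 + i, duration = 15 + durs[i] + 5)
    recs[[i]] <- ec$recording; prots[[i]] <- pr
  }
  curve <- band_response_curve(recs, prots, durs, "duration", "gamma", c(0, 15))
  ## measured steady-state dB tracks the generating curve
  expect_lt(max(abs(curve$y - evaluate_sigmoid(truth, durs))), 1.5)
  fit <- fit_sigmoid(curve, with_offset = TRUE)
  expect_equal(coef(fit)[["r_50"]], 6, tolerance = 1.5)
  expect_equal(coef(fit)[["r_slope"]], 0.4, tolerance = 0.15)
  expect_equal(coef(fit)[["r_max"]] + coef(fit)[["r_min"]], 14, tolerance = 1)

  ## flat curves: slope at its bound or non-converged
  flat_fit <- fit_sigmoid(response_curve(durs, rep(5, 6) + rnorm(6, 0, 0.01)),
                          with_offset = TRUE)
  expect_true(!flat_fit$converged || coef(flat_fit)[["r_slope"]] < 0.1 ||
                coef(flat_fit)[["r_max"]] < 0.5)
})

test_that("the delta band shows no stimulus dependence under the generator", {
  ## the generator modulates only the gamma comb; steady-state delta across
  ## the duration battery is stimulus-independent (1-way ANOVA)
  durs <- c(1, 5, 10, 20)
  vals <- data.frame()
  for (animal in 1:4) {
    for (d in durs) {
      pr <- stimulus_protocol(15, d, 5, 2)
      ec <- simulate_ecog(pr, gen_config(), seed = 500 + 10 * animal + d,
                          duration = 15 + d + 5)
      sc <- spectral_config()
      sp <- smooth_welch(spectrogram_db(lowpass_fir(ec$recording, sc), sc), sc)
      bp <- relative_power(band_power(sp, "delta", sc), c(0, 15), pr)
      sel <- bp$times >= 15 + d / 2 & bp$times <= 15 + d
      vals <- rbind(vals, data.frame(duration = factor(d),
                                     delta = mean(bp$relative_db[sel])))
    }
  }
  p <- summary(aov(delta ~ duration, vals))[[1]]$`Pr(>F)`[1]
  expect_gt(p, 0.05)
})

test_that("dB shift equivariance holds through the band pipeline", {
  sc <- spectral_config()
  set.seed(88)
  rec <- ecog_recording(rnorm(60000, 0, 0.05))
  rec2 <- ecog_recording(rec$samples * 3)
  for (b in c("delta", "gamma")) {
    s1 <- band_power(spectrogram_db(rec, sc), b, sc)
    s2 <- band_power(spectrogram_db(rec2, sc), b, sc)
    expect_equal(s2$power_db - s1$power_db,
                 rep(20 * log10(3), length(s1$power_db)), tolerance = 1e-9)
  }
})
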