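#' Synthetic-data generator configuration
#'
#' Defaults define the generator's stated world, calibrated once from the
#' printed results of the reference experiments: arborization stimulus-response
#' sigmoids (duration (82.8 %, 7.5 s, 0.4 s^-1), frequency (91.8 %, 1.7 Hz,
#' 1.9 Hz^-1), intensity (91.7 %, 1.7 mA, 2.0 mA^-1)), a several-second delayed
#' calcium response (mean 4 s), basal event rate 1 event/min, 14.7 dB peak
#' relative gamma, up-states of 0.17 mV and 0.93 s, and a feedback gain/drive
#' pair whose closed-form steady-state/peak ratios are 62.2 % (wildtype) and
#' 79.5 % (ip3r2_ko).
#'
#' @param field_size image side, pixels
#' @param pixel_size micrometres per pixel
#' @param n_cells number of astrocytes
#' @param soma_sigma radial Gaussian scale of the soma profile, micrometres
#' @param soma_amp peak soma structural intensity above background, a.u.
#' @param territory_radius territory radius, micrometres
#' @param n_arms number of radial processes per cell
#' @param arm_amp peak process structural intensity above background, a.u.
#' @param arm_width Gaussian cross-section scale of a process, micrometres
#' @param background structural background level, a.u.
#' @param struct_noise_sd structural channel pixel noise SD, a.u.
#' @param frame_interval movie frame interval, seconds
#' @param movie_duration movie length, seconds
#' @param response_sigmoids list of three `c(r_max, r_50, r_slope)` triplets
#'   (duration, frequency, intensity; r_max in %)
#' @param event_delay_mean mean stimulus-to-response delay, seconds
#' @param transient_rise,transient_decay calcium transient kernel time
#'   constants, seconds
#' @param event_amp_range range of event amplitudes, delta-F/F units
#' @param basal_rate spontaneous event rate per ROI, events/min
#' @param min_event_gap minimum spacing enforced between injected events on
#'   one ROI, seconds (keeps injected events resolvable)
#' @param noise_sd activity channel pixel noise SD, a.u.
#' @param activity_baseline_offset,activity_baseline_frac activity baseline
#'   image = offset + frac x (noiseless structure)
#' @param sampling_rate ECoG sampling rate, Hz
#' @param pink_rms RMS of the pink-noise ECoG background, mV
#' @param upstate_rate up-state rate, Hz
#' @param upstate_amplitude,upstate_amplitude_sd up-state amplitude, mV
#' @param upstate_duration,upstate_duration_sd up-state duration, seconds
#' @param ecog_peak_gamma_db stimulus-evoked relative gamma plateau, dB
#' @param gamma_tone_amp baseline amplitude of each gamma comb tone, mV
#' @param gamma_bins FFT bin indices (of `analysis_window` at `sampling_rate`)
#'   carrying the gamma comb
#' @param analysis_window spectrogram window the comb is aligned to, samples
#' @param feedback_gain dimensionless astrocyte feedback gain k (0 <= k < 1
#'   applies to the gamma suppression term; the default 0.61 yields the
#'   wildtype steady-state/peak ratio 1/(1+k) = 62.2 %)
#' @param feedback_delay astrocyte activation delay, seconds
#' @param calcium_decay population calcium decay constant tau_c, seconds
#' @param feedback_dt integration step, seconds (must be <= 0.1)
#' @param gamma_noise_sd,calcium_noise_sd additive noise SDs of the two series
#' @param ko_drive relative calcium drive in ip3r2_ko mode (0.42 yields the
#'   printed 79.5 % ratio via 1/(1 + k x drive))
#' @param ko_response_scale event probability scaling in ip3r2_ko mode
#' @param cno_basal_boost basal event rate multiplier in dreadd_cno mode
#' @param cno_baseline_calcium added baseline population calcium in dreadd_cno
#'   mode (relative units)
#' @param mode one of "wildtype", "ip3r2_ko", "dreadd_cno", "control"
#' @return list of class `GeneratorConfig`
#' @export
gen_config <- function(field_size = 192L,
                       pixel_size = 0.6,
                       n_cells = 3L,
                       soma_sigma = 4,
                       soma_amp = 100,
                       territory_radius = 20,
                       n_arms = 6L,
                       arm_amp = 60,
                       arm_width = 1.5,
                       background = 10,
                       struct_noise_sd = 3,
                       frame_interval = 0.5,
                       movie_duration = 60,
                       response_sigmoids = list(duration = c(82.8, 7.5, 0.4),
                                                frequency = c(91.8, 1.7, 1.9),
                                                intensity = c(91.7, 1.7, 2.0)),
                       event_delay_mean = 4,
                       transient_rise = 1.5,
                       transient_decay = 4,
                       event_amp_range = c(0.4, 1.2),
                       basal_rate = 1.0,
                       min_event_gap = 12,
                       noise_sd = 2,
                       activity_baseline_offset = 20,
                       activity_baseline_frac = 0.4,
                       sampling_rate = 10000,
                       pink_rms = 0.04,
                       upstate_rate = 0.1,
                       upstate_amplitude = 0.17,
                       upstate_amplitude_sd = 0.05,
                       upstate_duration = 0.93,
                       upstate_duration_sd = 0.10,
                       ecog_peak_gamma_db = 14.7,
                       gamma_tone_amp = 0.05,
                       gamma_bins = c(13L, 15L, 17L, 19L),
                       analysis_window = 4096L,
                       feedback_gain = 0.61,
                       feedback_delay = 4,
                       calcium_decay = 6,
                       feedback_dt = 0.1,
                       gamma_noise_sd = 0.3,
                       calcium_noise_sd = 0.005,
                       ko_drive = 0.42,
                       ko_response_scale = 0.15,
                       cno_basal_boost = 3.5,
                       cno_baseline_calcium = 0.5,
                       mode = c("wildtype", "ip3r2_ko", "dreadd_cno", "control")) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  for (f in c("pixel_size", "soma_sigma", "territory_radius", "frame_interval",
              "movie_duration", "transient_rise", "transient_decay",
              "calcium_decay", "feedback_dt", "sampling_rate")) {
    if (!is_scalar_num(cfg[[f]]) || cfg[[f]] <= 0) stopf("%s must be > 0", f)
  }
  if (cfg$feedback_gain < 0 || cfg$feedback_gain >= 1) {
    stopf("feedback_gain must lie in [0, 1)")
  }
  for (tri in cfg$response_sigmoids) {
    if (length(tri) != 3L || tri[3] < 0) stopf("each response sigmoid is c(r_max, r_50, r_slope >= 0)")
  }
  structure(cfg, class = "GeneratorConfig")
}

#' Combined response probability of a protocol under the generator sigmoids
#'
#' Product of the per-dimension sigmoid factors, each normalized by its own
#' maximum (the reference experiments vary one parameter at a time, leaving
#' the joint dependence unspecified; the normalized product preserves each
#' marginal shape). In `ip3r2_ko` mode the probability is scaled by
#' `ko_response_scale` toward the reported near-abolition.
#'
#' @param protocol a [stimulus_protocol()]
#' @param config a [gen_config()]
#' @return probability in `[0, 1]`
#' @export
response_probability <- function(protocol, config = gen_config()) {
  f1 <- function(tri, x) {
    evaluate_sigmoid(list(r_max = tri[1], r_50 = tri[2], r_slope = tri[3],
                          r_min = 0), x) / tri[1]
  }
  p <- f1(config$response_sigmoids$duration, protocol$duration) *
    f1(config$response_sigmoids$frequency, protocol$pulse_frequency) *
    f1(config$response_sigmoids$intensity, protocol$intensity)
  if (config$mode == "ip3r2_ko") p <- p * config$ko_response_scale
  min(max(p, 0), 1)
}

place_centers <- function(config, seed) {
  set.seed(child_seed(seed, "centers"))
  r_t <- config$territory_radius / config$pixel_size
  min_sep <- 2 * r_t * 0.8
  lo <- r_t + 1; hi <- config$field_size - r_t
  if (hi <= lo) stopf("field too small for territory radius")
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < config$n_cells) {
    tries <- tries + 1L
    if (tries > 400L * config$n_cells) {
      stopf("field too small to place %d cells with separation %.1f px",
            config$n_cells, min_sep)
    }
    p <- stats::runif(2, lo, hi)
    if (!nrow(pts) || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep) {
      pts <- rbind(pts, p)
    }
  }
  pts # columns: x, y
}

#' Generate a synthetic astrocyte structural field
#'
#' Each cell is a radially decaying Gaussian soma plus `n_arms` radial
#' processes (Gaussian cross-section, exponentially decaying amplitude,
#' ramping on just outside the soma), truncated at the territory radius, over
#' a uniform background with Gaussian pixel noise. Ground truth records the
#' centers, soma scales and per-cell process masks.
#'
#' @param config a [gen_config()]
#' @param seed integer seed
#' @param centers optional n x 2 matrix of centers (x, y in px) overriding
#'   random placement
#' @return list with `image` (noisy), `clean` (noiseless) and `truth`
#' @export
make_astrocyte_field <- function(config = gen_config(), seed = 1,
                                 centers = NULL) {
  n <- config$field_size
  px <- config$pixel_size
  if (is.null(centers)) centers <- place_centers(config, seed)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) > 1) {
    dmin <- min(stats::dist(centers))
    if (dmin < 2 * config$territory_radius / px * 0.8) {
      stopf("cell centers closer than the minimum separation")
    }
  }
  sigma_px <- config$soma_sigma / px
  r_t <- config$territory_radius / px
  w_px <- config$arm_width / px
  clean <- matrix(config$background, n, n)
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), n), n, n)
  truth_cells <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                            soma_sigma_px = numeric(0), soma_radius_px = numeric(0),
                            territory_radius_px = numeric(0))
  arm_angles <- list(); arb_masks <- list()
  soma_edge <- sigma_px * sqrt(2 * log(2))
  set.seed(child_seed(seed, "field"))
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    dx <- xg - cx; dy <- yg - cy
    r <- sqrt(dx^2 + dy^2)
    inside <- r <= r_t
    cell <- config$soma_amp * exp(-r^2 / (2 * sigma_px^2))
    arm_mask <- matrix(FALSE, n, n)
    if (config$n_arms > 0 && config$arm_amp > 0) {
      angles <- stats::runif(1) * 2 * pi / config$n_arms +
        2 * pi * (seq_len(config$n_arms) - 1) / config$n_arms
      theta <- atan2(dy, dx)
      ramp <- 1 / (1 + exp(-(r - 1.25 * soma_edge) / (1 / px)))
      amp_r <- config$arm_amp * exp(-r / (config$territory_radius / px)) * ramp
      best_d2 <- matrix(Inf, n, n)
      for (a in angles) {
        ## perpendicular distance to the ray at angle a (forward half-plane)
        dth <- atan2(sin(theta - a), cos(theta - a))
        d_perp <- abs(r * sin(dth))
        d_perp[abs(dth) > pi / 2] <- Inf
        best_d2 <- pmin(best_d2, d_perp^2)
      }
      ## super-Gaussian (quartic) cross-section: near-flat core, fast falloff,
      ## so the process footprint is sharply defined
      arm_c <- amp_r * exp(-(best_d2 / w_px^2)^2)
      arm_c[!inside] <- 0
      cell <- cell + arm_c
      ## ground truth: resolvable process structure (above twice the pixel
      ## noise, or 5 % of the peak process intensity when noiseless)
      gt_thr <- max(2 * config$struct_noise_sd, 0.05 * config$arm_amp)
      arm_mask <- arm_c > gt_thr & r > soma_edge & inside
      arm_angles[[i]] <- angles
    } else {
      arm_angles[[i]] <- numeric(0)
    }
    cell[!inside] <- 0
    clean <- clean + cell
    truth_cells <- rbind(truth_cells,
                         data.frame(cell_id = i, x = cx, y = cy,
                                    soma_sigma_px = sigma_px,
                                    soma_radius_px = soma_edge,
                                    territory_radius_px = r_t))
    arb_masks[[i]] <- which(arm_mask)
  }
  img <- clean
  if (config$struct_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, config$struct_noise_sd), n, n)
  }
  list(image = img, clean = clean,
       truth = list(cells = truth_cells, arm_angles = arm_angles,
                    arb_masks = arb_masks, dim = c(n, n)),
       config = config)
}

## ground-truth compartments of one field, as AstrocyteTerritory objects
## (soma disk, process mask and center-anchored microdomain grid); used to
## inject activity and as oracle ROIs in noiseless pipeline tests
#' Territories derived from generator ground truth
#'
#' Builds `AstrocyteTerritory` objects directly from the generator's geometry
#' (no segmentation): soma disk at the true half-maximum radius, the true
#' process mask, and the center-anchored microdomain grid over it.
#'
#' @param field result of [make_astrocyte_field()]
#' @param seg a [seg_config()] providing the microdomain grid parameters
#' @return a `territory_set`
#' @export
truth_territories <- function(field, seg = seg_config()) {
  cfg <- field$config
  cells <- field$truth$cells
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ctr <- c(cells$x[i], cells$y[i])
    soma_idx <- disk_mask_idx(field$truth$dim, ctr, cells$soma_radius_px[i])
    arb <- matrix(FALSE, field$truth$dim[1], field$truth$dim[2])
    arb[field$truth$arb_masks[[i]]] <- TRUE
    arb[soma_idx] <- FALSE
    md <- grid_microdomains(arb, ctr, cfg$pixel_size, seg)
    out[[i]] <- structure(
      list(cell_id = i, center = ctr,
           soma_radius_px = cells$soma_radius_px[i],
           soma_mask = soma_idx, arborization_mask = which(arb),
           microdomains = md, background = cfg$background,
           dim = field$truth$dim,
           qc = list(edge_clipped = FALSE, vasculature_overlap = FALSE,
                     empty_arborization = !any(arb))),
      class = "AstrocyteTerritory")
  }
  structure(out, class = "territory_set")
}

## calcium transient kernel, peak-normalized
transient_kernel <- function(t, rise, decay) {
  k <- (1 - exp(-t / rise)) * exp(-t / decay)
  k[t < 0] <- 0
  tpk <- rise * log(1 + decay / rise)
  k / ((1 - exp(-tpk / rise)) * exp(-tpk / decay))
}

## draw event times with a dead-time (thinned Poisson)
draw_spontaneous <- function(rate_per_min, duration, gap) {
  n <- stats::rpois(1, rate_per_min / 60 * duration)
  if (n == 0) return(numeric(0))
  t <- sort(stats::runif(n, 0, duration))
  keep <- numeric(0)
  for (ti in t) if (!length(keep) || ti - keep[length(keep)] >= gap) keep <- c(keep, ti)
  keep
}

#' Simulate a two-channel calcium movie over a synthetic field
#'
#' For every compartment (soma and each ground-truth microdomain) a responder
#' status is drawn with the product-combined sigmoid probability of the
#' protocol (see [response_probability()]); responders receive one
#' stimulus-locked transient with onset delayed by a truncated-normal lag
#' (mean `event_delay_mean`, SD a quarter of it) and kernel
#' `(1 - exp(-t/rise)) exp(-t/decay)`. Spontaneous events are added at
#' `basal_rate` with a dead-time. The activity channel is a
#' structure-derived baseline plus the injected transients plus Gaussian
#' noise; every injected event is logged in the ground truth.
#'
#' @param field result of [make_astrocyte_field()]
#' @param protocol a [stimulus_protocol()] (onset + duration must fit in the
#'   movie)
#' @param config a [gen_config()]
#' @param seed integer seed
#' @return list with `movie` ([imaging_movie()]), `territories` (ground-truth
#'   ROIs), `events` (data.frame), `truth` (per-condition probability etc.)
#' @export
simulate_calcium_movie <- function(field, protocol, config = gen_config(),
                                   seed = 1) {
  if (protocol$onset + protocol$duration > config$movie_duration) {
    stopf("protocol (onset %g + duration %g s) exceeds movie duration %g s",
          protocol$onset, protocol$duration, config$movie_duration)
  }
  set.seed(child_seed(seed, "movie"))
  dt <- config$frame_interval
  nt <- as.integer(round(config$movie_duration / dt))
  tt <- (seq_len(nt) - 1) * dt
  h <- field$truth$dim[1]; w <- field$truth$dim[2]
  terr <- truth_territories(field)
  baseline_img <- config$activity_baseline_offset +
    config$activity_baseline_frac * field$clean
  act <- matrix(rep(as.vector(baseline_img), nt), h * w, nt)
  p_resp <- response_probability(protocol, config)
  basal <- config$basal_rate *
    (if (config$mode == "dreadd_cno") config$cno_basal_boost
     else if (config$mode == "ip3r2_ko") config$ko_response_scale * 2
     else 1)
  tpk <- config$transient_rise * log(1 + config$transient_decay / config$transient_rise)
  events <- list()
  add_event <- function(mask_idx, t_on, amp) {
    f0 <- mean(baseline_img[mask_idx])
    kv <- transient_kernel(tt - t_on, config$transient_rise, config$transient_decay)
    on_frames <- which(kv > 1e-6)
    if (!length(on_frames) || !length(mask_idx)) return(NULL)
    act[mask_idx, on_frames] <<- act[mask_idx, on_frames] +
      amp * f0 * rep(kv[on_frames], each = length(mask_idx))
    invisible(NULL)
  }
  roi_iter <- list()
  for (t in terr) {
    roi_iter[[length(roi_iter) + 1L]] <-
      list(cell = t$cell_id, compartment = "soma",
           roi = sprintf("c%d_soma", t$cell_id), mask = t$soma_mask)
    for (j in seq_along(t$microdomains)) {
      roi_iter[[length(roi_iter) + 1L]] <-
        list(cell = t$cell_id, compartment = "microdomain",
             roi = sprintf("c%d_md%d", t$cell_id, j),
             mask = t$microdomains[[j]]$pixels)
    }
  }
  for (ri in roi_iter) {
    responder <- stats::runif(1) < p_resp
    ev_times <- numeric(0); ev_amps <- numeric(0); ev_kind <- character(0)
    if (responder && protocol$duration > 0) {
      delay <- -1
      while (delay < 0) delay <- stats::rnorm(1, config$event_delay_mean,
                                              config$event_delay_mean / 4)
      t_on <- protocol$onset + delay
      if (t_on < config$movie_duration - tpk) {
        ev_times <- t_on
        ev_amps <- stats::runif(1, config$event_amp_range[1], config$event_amp_range[2])
        ev_kind <- "evoked"
      }
    }
    sp <- draw_spontaneous(basal, config$movie_duration, config$min_event_gap)
    sp <- sp[vapply(sp, function(s) !length(ev_times) ||
                      all(abs(s - ev_times) >= config$min_event_gap), logical(1))]
    sp <- sp[sp < config$movie_duration - tpk]
    if (length(sp)) {
      ev_times <- c(ev_times, sp)
      ev_amps <- c(ev_amps, stats::runif(length(sp), config$event_amp_range[1],
                                         config$event_amp_range[2]))
      ev_kind <- c(ev_kind, rep("spontaneous", length(sp)))
    }
    for (k in seq_along(ev_times)) {
      add_event(ri$mask, ev_times[k], ev_amps[k])
      events[[length(events) + 1L]] <-
        data.frame(cell_id = ri$cell, compartment = ri$compartment,
                   roi_id = ri$roi, onset = ev_times[k],
                   peak_time = ev_times[k] + tpk, amplitude = ev_amps[k],
                   kind = ev_kind[k], responder = responder)
    }
    if (!length(ev_times)) {
      events[[length(events) + 1L]] <-
        data.frame(cell_id = ri$cell, compartment = ri$compartment,
                   roi_id = ri$roi, onset = NA_real_, peak_time = NA_real_,
                   amplitude = NA_real_, kind = "none", responder = responder)
    }
  }
  if (config$noise_sd > 0) {
    act <- act + matrix(stats::rnorm(length(act), 0, config$noise_sd),
                        nrow(act), ncol(act))
  }
  struct_stack <- array(rep(as.vector(field$image), nt), c(h, w, nt))
  ev_df <- do.call(rbind, events)
  movie <- imaging_movie(struct_stack, array(act, c(h, w, nt)),
                         frame_interval = dt, pixel_size = config$pixel_size,
                         metadata = list(mode = config$mode, seed = seed))
  list(movie = movie, territories = terr,
       events = ev_df[!is.na(ev_df$onset), , drop = FALSE],
       truth = list(response_probability = p_resp,
                    responders = unique(ev_df[c("cell_id", "compartment",
                                                "roi_id", "responder")]),
                    kernel_peak_lag = tpk,
                    baseline_img = baseline_img))
}
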