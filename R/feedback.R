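#' Simulate the astrocyte-gamma negative-feedback loop
#'
#' Phenomenological discrete-time model of the delayed astrocyte dampening of
#' stimulus-evoked gamma. With S(t) = 1 during stimulation and 0 otherwise:
#'
#'   C(t+dt) = C(t) + dt * (alpha * S(t - delta) * G(t) - C(t) / tau_c)
#'   G(t)    = g_peak * S(t) * (1 - k * C(t) / C_ref) + noise
#'
#' where G is relative gamma power (dB), C population calcium (relative
#' units), k the feedback gain, delta the astrocyte activation delay and
#' tau_c the calcium decay constant. alpha is fixed at 1/(tau_c * g_peak) so
#' that without feedback C saturates at C_ref = 1; the closed-form
#' steady-state/peak gamma ratio is then 1/(1 + k x drive). With k = 0 gamma
#' is a noisy step. Modes: `ip3r2_ko` scales the calcium drive by `ko_drive`;
#' `dreadd_cno` adds `cno_baseline_calcium` of tonic calcium.
#'
#' @param protocol a [stimulus_protocol()]
#' @param config a [gen_config()]
#' @param seed integer seed
#' @param t_end simulation end, seconds (default: onset + duration + 40 s of
#'   recovery)
#' @return object of class `feedback_sim`: list with `times`, `gamma` (dB),
#'   `calcium` (a.u.), `stimulus` (0/1) and the model constants
#' @export
simulate_feedback <- function(protocol, config = gen_config(), seed = 1,
                              t_end = NULL) {
  dt <- config$feedback_dt
  if (dt > 0.1) stopf("feedback_dt must be <= 0.1 s (stability contract)")
  t_end <- t_end %||% (protocol$onset + protocol$duration + 40)
  set.seed(child_seed(seed, "feedback"))
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  k <- config$feedback_gain
  g_peak <- config$ecog_peak_gamma_db
  tau <- config$calcium_decay
  delta <- config$feedback_delay
  drive <- switch(config$mode, ip3r2_ko = config$ko_drive, 1)
  c0 <- if (config$mode == "dreadd_cno") config$cno_baseline_calcium else 0
  alpha <- drive / (tau * g_peak)
  s <- as.numeric(times >= protocol$onset & times < protocol$onset + protocol$duration)
  s_del <- as.numeric((times - delta) >= protocol$onset &
                        (times - delta) < protocol$onset + protocol$duration)
  C <- numeric(n); G <- numeric(n)
  gn <- stats::rnorm(n, 0, config$gamma_noise_sd)
  cn <- stats::rnorm(n, 0, config$calcium_noise_sd)
  for (i in seq_len(n)) {
    G[i] <- g_peak * s[i] * (1 - k * (C[i] + c0)) + gn[i]
    if (i < n) {
      C[i + 1] <- max(0, C[i] + dt * (alpha * s_del[i] * G[i] - C[i] / tau) + cn[i] * sqrt(dt))
    }
  }
  structure(list(times = times, gamma = G, calcium = C, stimulus = s,
                 protocol = protocol, mode = config$mode,
                 constants = list(k = k, delta = delta, tau_c = tau,
                                  g_peak = g_peak, drive = drive,
                                  ratio_closed_form = 1 / (1 + k * drive))),
            class = "feedback_sim")
}

#' @export
print.feedback_sim <- function(x, ...) {
  cat(sprintf(
    "feedback_sim (%s): %d steps, k = %g, delta = %g s, closed-form ss/peak = %.1f%%\n",
    x$mode, length(x$times), x$constants$k, x$constants$delta,
    100 * x$constants$ratio_closed_form))
  invisible(x)
}
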