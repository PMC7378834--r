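#' Align a calcium and a gamma series on a common clock
#'
#' Both series are linearly interpolated onto a uniform grid (default 0.5 s)
#' over their overlapping time support, which must span at least 20 s.
#'
#' @param calcium_times,calcium population calcium series and clock (s)
#' @param gamma_times,gamma relative gamma series and clock (s)
#' @param step grid step, seconds
#' @return object of class `AlignedStreams`: list with `times`, `calcium`,
#'   `gamma`
#' @export
align_streams <- function(calcium_times, calcium, gamma_times, gamma,
                          step = 0.5) {
  lo <- max(min(calcium_times), min(gamma_times))
  hi <- min(max(calcium_times), max(gamma_times))
  if (hi - lo < 20) stopf("overlapping time support %.1f s is below 20 s", hi - lo)
  grid <- seq(lo, hi, by = step)
  structure(list(times = grid,
                 calcium = stats::approx(calcium_times, calcium, grid)$y,
                 gamma = stats::approx(gamma_times, gamma, grid)$y),
            class = "AlignedStreams")
}

#' Pearson correlation with a Student t-test
#'
#' Pearson r with `t = r sqrt((n-2)/(1-r^2))` against the null of no
#' correlation; two-sided p from the t distribution with n-2 df.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance)
#' @return list with `r`, `r_squared`, `t`, `df`, `p`
#' @export
pearson_with_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance in input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, r_squared = r^2, t = t, df = n - 2, p = p)
}

#' Lag of maximal cross-correlation
#'
#' Signed lag (positive: calcium follows gamma) of the maximal normalized
#' cross-correlation between the mean-removed streams, searched within
#' `max_lag` seconds.
#'
#' @param streams an [align_streams()] result
#' @param max_lag search half-width, seconds
#' @return lag in seconds
#' @export
cross_correlation_lag <- function(streams, max_lag = 30) {
  g <- streams$gamma - mean(streams$gamma)
  c_ <- streams$calcium - mean(streams$calcium)
  if (stats::sd(g) == 0 || stats::sd(c_) == 0) stopf("flat input stream")
  dt <- streams$times[2] - streams$times[1]
  kmax <- min(length(g) - 3L, as.integer(floor(max_lag / dt)))
  lags <- -kmax:kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) { a <- g[1:(length(g) - k)]; b <- c_[(1 + k):length(c_)] }
    else { a <- g[(1 - k):length(g)]; b <- c_[1:(length(c_) + k)] }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  lags[which.max(cc)] * dt
}

#' Signed hysteresis loop area in the (calcium, gamma) plane
#'
#' Shoelace (polygon) area of the trajectory over the window, closed by a
#' straight segment between its endpoints. The sign is positive for the
#' gamma-rises-first orientation (gamma up at low calcium, return at high
#' calcium). The endpoint closure gap is reported as an attribute.
#'
#' @param streams an [align_streams()] result (or any list with `times`,
#'   `calcium`, `gamma`)
#' @param window optional `c(t0, t1)` restriction, seconds
#' @return signed area (calcium units x dB); attributes `closure_gap` and
#'   `n_points`
#' @export
hysteresis_area <- function(streams, window = NULL) {
  sel <- if (is.null(window)) rep(TRUE, length(streams$times))
         else streams$times >= window[1] & streams$times <= window[2]
  x <- streams$calcium[sel]; y <- streams$gamma[sel]
  n <- length(x)
  if (n < 3) stopf("need at least 3 trajectory points")
  xs <- c(x, x[1]); ys <- c(y, y[1]) # close the polygon with a chord
  shoelace <- 0.5 * sum(xs[-(n + 1)] * ys[-1] - xs[-1] * ys[-(n + 1)])
  area <- -shoelace # clockwise (gamma-rises-first) counted positive
  if (abs(area) < 1e-12 * (diff(range(x)) * diff(range(y)) + 1e-300)) {
    warning("degenerate (collinear) trajectory: area 0")
  }
  structure(area,
            closure_gap = sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2),
            n_points = n)
}

#' Surrogate-null floor for the hysteresis loop area
#'
#' Circular time shifts of the calcium stream (minimum shift `min_shift`
#' seconds) destroy the stream alignment while preserving both marginals and
#' autocorrelations; the floor is the `probs` quantile of the absolute
#' surrogate areas.
#'
#' @param streams an [align_streams()] result
#' @param n_surrogates number of shifts
#' @param min_shift smallest permitted shift, seconds
#' @param probs floor quantile
#' @param seed integer seed
#' @param window optional window forwarded to [hysteresis_area()]
#' @return the floor; attribute `areas` carries the surrogate distribution
#' @export
hysteresis_null_floor <- function(streams, n_surrogates = 200, min_shift = 10,
                                  probs = 0.95, seed = 1, window = NULL) {
  set.seed(child_seed(seed, "hysteresis_null"))
  n <- length(streams$times)
  dt <- streams$times[2] - streams$times[1]
  kmin <- max(1L, as.integer(ceiling(min_shift / dt)))
  if (kmin >= n - 1L) stopf("min_shift too large for the stream length")
  shifts <- sample(seq.int(kmin, n - kmin), n_surrogates, replace = TRUE)
  areas <- vapply(shifts, function(k) {
    surr <- streams
    surr$calcium <- c(streams$calcium[(k + 1):n], streams$calcium[1:k])
    as.numeric(suppressWarnings(hysteresis_area(surr, window)))
  }, numeric(1))
  structure(stats::quantile(abs(areas), probs, names = FALSE), areas = areas)
}

#' Full coupling analysis of one aligned stream pair
#'
#' Pearson correlation with t-test, cross-correlation lag and hysteresis
#' loop area with its surrogate floor.
#'
#' @param streams an [align_streams()] result
#' @param window optional hysteresis window
#' @param seed seed for the surrogate null
#' @return list of class `CouplingResult`
#' @export
coupling_result <- function(streams, window = NULL, seed = 1) {
  ct <- pearson_with_t(streams$gamma, streams$calcium)
  area <- hysteresis_area(streams, window)
  floor_ <- hysteresis_null_floor(streams, seed = seed, window = window)
  structure(list(pearson_r = ct$r, r_squared = ct$r_squared, p_value = ct$p,
                 lag_s = cross_correlation_lag(streams),
                 hysteresis_area = as.numeric(area),
                 hysteresis_closure_gap = attr(area, "closure_gap"),
                 hysteresis_null_floor = as.numeric(floor_)),
            class = "CouplingResult")
}

#' @export
print.CouplingResult <- function(x, ...) {
  cat(sprintf(paste0("CouplingResult: r = %.3f (R2 = %.3f, p = %.3g), ",
                     "lag = %.1f s,\n  loop area = %.3g ",
                     "(surrogate floor %.3g, closure gap %.3g)\n"),
              x$pearson_r, x$r_squared, x$p_value, x$lag_s,
              x$hysteresis_area, x$hysteresis_null_floor,
              x$hysteresis_closure_gap))
  invisible(x)
}

#' Compare gamma metrics between two condition groups
#'
#' Group means +/- SEM of peak, steady-state and ratio, with two-sided
#' two-sample Welch t-tests (delegated to [stats::t.test()]). Singleton
#' groups have undefined SEM and are flagged.
#'
#' @param group_a,group_b lists of [gamma_metrics()] results (or data.frames
#'   with columns `peak_db`, `steady_state_db`, `ratio`)
#' @param labels group labels for the output table
#' @return data.frame with one row per metric
#' @export
condition_compare <- function(group_a, group_b, labels = c("A", "B")) {
  as_df <- function(g) {
    if (is.data.frame(g)) return(g)
    do.call(rbind, lapply(g, function(m) {
      data.frame(peak_db = m$peak_db, steady_state_db = m$steady_state_db,
                 ratio = m$ratio)
    }))
  }
  a <- as_df(group_a); b <- as_df(group_b)
  if (nrow(a) < 2 || nrow(b) < 2) {
    warning("singleton group: SEM undefined and no t-test performed")
  }
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  out <- lapply(c("peak_db", "steady_state_db", "ratio"), function(m) {
    va <- a[[m]][is.finite(a[[m]])]; vb <- b[[m]][is.finite(b[[m]])]
    tt <- if (length(va) > 1 && length(vb) > 1 &&
              (stats::sd(va) > 0 || stats::sd(vb) > 0)) {
      stats::t.test(va, vb)
    } else NULL
    data.frame(metric = m,
               mean_a = mean(va), sem_a = sem(va),
               mean_b = mean(vb), sem_b = sem(vb),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- do.call(rbind, out)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", labels[1]), paste0("sem_", labels[1]),
                                 paste0("mean_", labels[2]), paste0("sem_", labels[2]))
  out
}
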