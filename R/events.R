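#' Event detection configuration
#'
#' The 3-SD rule: an event is a maximal contiguous excursion of delta-F/F
#' above baseline mean + `k_sd` x baseline SD, with excursions closer than
#' `min_separation` merged. `dff_floor` is the documented detection floor
#' used when the baseline SD is (numerically) zero on noiseless data.
#'
#' @param k_sd threshold multiplier (default 3)
#' @param baseline_window `c(t0, t1)` seconds before stimulus onset used as
#'   baseline; `NULL` defaults to everything before the protocol onset (or
#'   the first 20 s without a protocol). Must span at least 5 s.
#' @param min_separation merge gap, seconds
#' @param response_grace responder window extension past stimulus offset,
#'   seconds (astrocyte responses are delayed by seconds)
#' @param dff_floor minimum threshold height above the baseline mean, in
#'   delta-F/F units
#' @param min_frames minimum event extent in frames; single-frame threshold
#'   crossings are noise (calcium transients last seconds) and are not
#'   counted as events, though they still enter the supra-threshold frame
#'   statistic reported by [detect_events()]
#' @return list of class `EventDetectionConfig`
#' @export
event_config <- function(k_sd = 3, baseline_window = NULL, min_separation = 1,
                         response_grace = 10, dff_floor = 0.02,
                         min_frames = 2L) {
  if (k_sd <= 0) stopf("k_sd must be > 0")
  if (!is.null(baseline_window) &&
      diff(baseline_window) < 5) stopf("baseline window must span at least 5 s")
  structure(as.list(environment()), class = "EventDetectionConfig")
}

new_trace <- function(roi_id, compartment, f, frame_interval, cell_id = NA) {
  stopifnot(all(is.finite(f)))
  structure(list(roi_id = roi_id, cell_id = cell_id, compartment = compartment,
                 f = as.numeric(f), dff = NULL,
                 frame_interval = frame_interval),
            class = "CalciumTrace")
}

#' @export
print.CalciumTrace <- function(x, ...) {
  cat(sprintf("CalciumTrace %s (%s): %d frames @ %g s%s\n", x$roi_id,
              x$compartment, length(x$f), x$frame_interval,
              if (!is.null(x$dff)) ", dff computed" else ""))
  invisible(x)
}

trace_times <- function(trace) (seq_along(trace$f) - 1) * trace$frame_interval

#' Extract per-ROI fluorescence traces from a movie
#'
#' One trace per soma, per whole arborization and per microdomain of every
#' territory: `f(t)` is the mean activity-channel intensity over the ROI's
#' pixels. Empty ROIs are skipped with a warning.
#'
#' @param movie an [imaging_movie()]
#' @param territories a `territory_set` (from [segment_territories()] or
#'   [truth_territories()])
#' @return list of `CalciumTrace` objects (class `calcium_traces`)
#' @export
extract_traces <- function(movie, territories) {
  d <- dim(movie$activity)
  act <- matrix(movie$activity, d[1] * d[2], d[3])
  out <- list()
  grab <- function(idx, roi_id, compartment, cell_id) {
    if (!length(idx)) {
      warning(sprintf("empty ROI %s skipped", roi_id))
      return(NULL)
    }
    if (max(idx) > nrow(act)) stopf("ROI %s exceeds movie frame bounds", roi_id)
    f <- if (length(idx) == 1L) act[idx, ] else colMeans(act[idx, , drop = FALSE])
    out[[length(out) + 1L]] <<- new_trace(roi_id, compartment, f,
                                          movie$frame_interval, cell_id)
    invisible(NULL)
  }
  for (t in territories) {
    grab(t$soma_mask, sprintf("c%d_soma", t$cell_id), "soma", t$cell_id)
    grab(t$arborization_mask, sprintf("c%d_arb", t$cell_id), "arborization",
         t$cell_id)
    for (j in seq_along(t$microdomains)) {
      grab(t$microdomains[[j]]$pixels, sprintf("c%d_md%d", t$cell_id, j),
           "microdomain", t$cell_id)
    }
  }
  structure(out, class = "calcium_traces")
}

#' @export
print.calcium_traces <- function(x, ...) {
  comp <- table(vapply(x, function(t) t$compartment, character(1)))
  cat(sprintf("calcium_traces: %d traces (%s)\n", length(x),
              paste(sprintf("%d %s", comp, names(comp)), collapse = ", ")))
  invisible(x)
}

#' Compute delta-F/F for a trace
#'
#' `dff(t) = (f(t) - F0) / F0` with `F0` the mean fluorescence over the
#' baseline window, which must be positive.
#'
#' @param trace a `CalciumTrace`
#' @param baseline_window `c(t0, t1)` seconds
#' @return the trace with `dff` (and `f0`) filled in
#' @export
compute_dff <- function(trace, baseline_window) {
  tt <- trace_times(trace)
  sel <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(sel)) stopf("empty baseline window")
  f0 <- mean(trace$f[sel])
  if (f0 <= 0) stopf("baseline F0 = %g is not positive", f0)
  trace$f0 <- f0
  trace$dff <- (trace$f - f0) / f0
  trace$baseline_window <- baseline_window
  trace
}

default_baseline <- function(trace, protocol, config) {
  config$baseline_window %||% {
    end <- if (!is.null(protocol)) protocol$onset
           else min(20, length(trace$f) * trace$frame_interval)
    c(0, end)
  }
}

#' Detect calcium events on a trace (3-SD rule)
#'
#' The threshold is baseline mean + `k_sd` x baseline SD of delta-F/F (with
#' the documented `dff_floor` when the baseline SD vanishes on noiseless
#' data). An event is a maximal contiguous supra-threshold excursion
#' (strict `>`); excursions separated by less than `min_separation` merge.
#' Onset is the first crossing, amplitude the maximal delta-F/F in the
#' excursion minus the baseline mean. Excursions shorter than `min_frames`
#' are discarded as noise; the raw count of supra-threshold frames (before
#' any gating) is attached as attribute `n_supra_frames`.
#'
#' @param trace a `CalciumTrace` (delta-F/F computed on demand)
#' @param config an [event_config()]
#' @param protocol optional [stimulus_protocol()] fixing the default
#'   baseline window (everything before onset)
#' @return data.frame of class `calcium_events` with columns `roi_id`,
#'   `compartment`, `onset`, `peak_time`, `offset`, `amplitude`, `n_frames`;
#'   attributes `threshold`, `baseline_mean`, `baseline_sd`
#' @export
detect_events <- function(trace, config = event_config(), protocol = NULL) {
  bw <- default_baseline(trace, protocol, config)
  if (diff(bw) < 5) stopf("baseline window must span at least 5 s")
  if (is.null(trace$dff) || !identical(trace$baseline_window, bw)) {
    trace <- compute_dff(trace, bw)
  }
  tt <- trace_times(trace)
  bsel <- tt >= bw[1] & tt < bw[2]
  bmean <- mean(trace$dff[bsel])
  bsd <- stats::sd(trace$dff[bsel])
  thr <- bmean + max(config$k_sd * bsd, config$dff_floor)
  above <- trace$dff > thr
  empty <- data.frame(roi_id = character(0), compartment = character(0),
                      onset = numeric(0), peak_time = numeric(0),
                      offset = numeric(0), amplitude = numeric(0),
                      n_frames = integer(0))
  mk <- function(df) structure(df, class = c("calcium_events", "data.frame"),
                               threshold = thr, baseline_mean = bmean,
                               baseline_sd = bsd, n_supra_frames = sum(above))
  if (!any(above)) return(mk(empty))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  ## merge runs separated by less than min_separation
  gap_frames <- config$min_separation / trace$frame_interval
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, 1] - merged[nrow(merged), 2] - 1 < gap_frames) {
      merged[nrow(merged), 2] <- runs[i, 2]
    } else merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= config$min_frames
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(mk(empty))
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    seg <- merged[i, 1]:merged[i, 2]
    pk <- seg[which.max(trace$dff[seg])]
    data.frame(roi_id = trace$roi_id, compartment = trace$compartment,
               onset = tt[merged[i, 1]], peak_time = tt[pk],
               offset = tt[merged[i, 2]],
               amplitude = max(trace$dff[seg]) - bmean,
               n_frames = length(seg))
  }))
  mk(out)
}

#' Classify a trace as stimulus responder
#'
#' Responder iff at least one event peaks between stimulus onset and offset
#' plus the grace window (admitting the seconds-delayed astrocyte response).
#'
#' @param events a [detect_events()] result
#' @param protocol a [stimulus_protocol()]
#' @param config an [event_config()]
#' @return logical
#' @export
classify_responder <- function(events, protocol, config = event_config()) {
  if (!nrow(events)) return(FALSE)
  any(events$peak_time >= protocol$onset &
        events$peak_time <= protocol$onset + protocol$duration +
          config$response_grace)
}

#' Population response percentages
#'
#' Percentage of QC-passing ROIs of each compartment class (somas, whole
#' arborizations, microdomains) classified as responders.
#'
#' @param territories a `territory_set` (QC-flagged cells are excluded)
#' @param traces an [extract_traces()] result
#' @param protocol a [stimulus_protocol()]
#' @param config an [event_config()]
#' @return list with `soma`, `arborization`, `microdomain` (percent) and `n`
#'   (ROIs counted per class)
#' @export
population_response <- function(territories, traces, protocol,
                                config = event_config()) {
  ok_cells <- vapply(territories, function(t) if (qc_pass(t)) t$cell_id else NA_integer_,
                     integer(1))
  ok_cells <- ok_cells[!is.na(ok_cells)]
  if (!length(ok_cells)) stopf("no QC-passing territories")
  res <- list(soma = logical(0), arborization = logical(0),
              microdomain = logical(0))
  for (tr in traces) {
    if (!(tr$cell_id %in% ok_cells)) next
    resp <- classify_responder(detect_events(tr, config, protocol), protocol,
                               config)
    res[[tr$compartment]] <- c(res[[tr$compartment]], resp)
  }
  list(soma = 100 * mean(res$soma), arborization = 100 * mean(res$arborization),
       microdomain = 100 * mean(res$microdomain),
       n = vapply(res, length, integer(1)))
}

#' Event rate in a window
#'
#' @param events a [detect_events()] result
#' @param window `c(t0, t1)` seconds
#' @return events per minute (peaks counted within the window)
#' @export
event_rate <- function(events, window) {
  len <- diff(window)
  if (len <= 0) stopf("window length must be > 0")
  sum(events$peak_time >= window[1] & events$peak_time < window[2]) * 60 / len
}

#' Across-trial response reliability
#'
#' For a responder matrix (ROIs x repeated identical trains), the histogram
#' of "responded to m of n trains" over m = 0..n.
#'
#' @param responder_matrix logical matrix, one row per ROI, one column per
#'   train (n >= 2)
#' @return named integer vector of counts for m = 0..n; attribute
#'   `per_roi` carries each ROI's response count
#' @export
reliability <- function(responder_matrix) {
  if (is.data.frame(responder_matrix)) responder_matrix <- as.matrix(responder_matrix)
  if (!is.matrix(responder_matrix) || ncol(responder_matrix) < 2) {
    stopf("need a ROIs x trains matrix with at least 2 trains")
  }
  if (any(is.na(responder_matrix))) stopf("ragged responder matrix (NA entries)")
  n <- ncol(responder_matrix)
  m <- rowSums(responder_matrix)
  counts <- vapply(0:n, function(k) sum(m == k), integer(1))
  names(counts) <- as.character(0:n)
  structure(counts, per_roi = m)
}
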