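#' Two-channel imaging movie
#'
#' Container for a structural (SR101-like) and an activity (GCaMP6f-like)
#' channel acquired in parallel: arrays of dimension height x width x frames,
#' a frame interval in seconds and a pixel size in micrometres per pixel.
#'
#' @param structural numeric array (h x w x n frames), structural channel
#' @param activity numeric array of identical dimension, activity channel
#' @param frame_interval frame interval, seconds (0.05--2 s)
#' @param pixel_size pixel size, micrometres per pixel
#' @param metadata optional named list carried along unchanged
#' @return an object of class `ImagingMovie`
#' @export
imaging_movie <- function(structural, activity, frame_interval, pixel_size,
                          metadata = list()) {
  if (is.matrix(structural)) structural <- array(structural, c(dim(structural), 1L))
  if (is.matrix(activity)) activity <- array(activity, c(dim(activity), 1L))
  stopifnot(length(dim(structural)) == 3L, length(dim(activity)) == 3L)
  if (!identical(dim(structural), dim(activity))) {
    stopf("structural and activity stacks must share shape and frame count")
  }
  if (!is_scalar_num(frame_interval) || frame_interval < 0.05 || frame_interval > 2) {
    stopf("frame_interval must lie in [0.05, 2] s")
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) {
    stopf("pixel_size must be > 0")
  }
  structure(list(structural = structural, activity = activity,
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 metadata = metadata),
            class = "ImagingMovie")
}

#' @export
print.ImagingMovie <- function(x, ...) {
  d <- dim(x$structural)
  cat(sprintf("ImagingMovie: %d x %d px, %d frames, dt = %g s (%.1f s), %g um/px\n",
              d[1], d[2], d[3], x$frame_interval, movie_duration(x), x$pixel_size))
  invisible(x)
}

#' Movie duration in seconds
#' @param movie an [imaging_movie()]
#' @export
movie_duration <- function(movie) {
  dim(movie$structural)[3] * movie$frame_interval
}

#' Frame mid-times of a movie, seconds
#' @param movie an [imaging_movie()]
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$structural)[3]) - 1) * movie$frame_interval
}

#' Extracellular field-potential recording
#'
#' @param samples numeric vector of samples in millivolts
#' @param sampling_rate sampling rate, Hz (must exceed 200 Hz so that the
#'   30--50 Hz analysis band is resolvable; the reference rig samples at 10 kHz)
#' @param t0 recording start time on the protocol clock, seconds
#' @return an object of class `EcogRecording`
#' @export
ecog_recording <- function(samples, sampling_rate = 10000, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  if (!is_scalar_num(sampling_rate) || sampling_rate <= 200) {
    stopf("sampling_rate must exceed 200 Hz (2 x highest analysis frequency)")
  }
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 t0 = t0),
            class = "EcogRecording")
}

#' @export
print.EcogRecording <- function(x, ...) {
  cat(sprintf("EcogRecording: %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Sample times of a recording, seconds (protocol clock)
#' @param rec an [ecog_recording()]
#' @export
ecog_times <- function(rec) {
  rec$t0 + (seq_along(rec$samples) - 1) / rec$sampling_rate
}

#' Electrical stimulation protocol
#'
#' One square-pulse train. The reference battery combines durations
#' {1, 5, 10, 20, 60} s, pulse frequencies {0.5, 1, 2, 5, 10} Hz and
#' intensities {1, 2, 3} mA at 0.5 ms pulse width; arbitrary positive values
#' are accepted.
#'
#' @param onset train onset, seconds
#' @param duration train duration, seconds
#' @param pulse_frequency pulse rate, Hz
#' @param intensity pulse intensity, mA
#' @param pulse_width single-pulse width, seconds
#' @return an object of class `StimulusProtocol`
#' @export
stimulus_protocol <- function(onset, duration, pulse_frequency = 2,
                              intensity = 2, pulse_width = 5e-4) {
  for (v in list(onset, duration, pulse_frequency, intensity, pulse_width)) {
    if (!is_scalar_num(v) || v < 0) stopf("protocol fields must be non-negative scalars")
  }
  structure(list(onset = onset, duration = duration,
                 pulse_frequency = pulse_frequency, intensity = intensity,
                 pulse_width = pulse_width),
            class = "StimulusProtocol")
}

#' @export
print.StimulusProtocol <- function(x, ...) {
  cat(sprintf("StimulusProtocol: onset %g s, %g s @ %g Hz, %g mA (pulse %g ms)\n",
              x$onset, x$duration, x$pulse_frequency, x$intensity,
              1000 * x$pulse_width))
  invisible(x)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")

#' Write an imaging movie to disk
#'
#' One multi-page TIFF with interleaved channels (structural page first, then
#' activity, alternating) plus a JSON sidecar carrying `frame_interval`,
#' `pixel_size`, the channel order and any metadata.
#'
#' @param movie an [imaging_movie()]
#' @param path output TIFF path; the sidecar is written next to it
#' @return `path`, invisibly
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ImagingMovie"))
  n <- dim(movie$structural)[3]
  pages <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    pages[[2L * i - 1L]] <- movie$structural[, , i]
    pages[[2L * i]] <- movie$activity[, , i]
  }
  write_tiff(pages, path)
  write_json_file(list(format = "gliawave-movie",
                       channels = c("structural", "activity"),
                       n_frames = n,
                       frame_interval = movie$frame_interval,
                       pixel_size = movie$pixel_size,
                       metadata = movie$metadata),
                  sidecar_path(path))
  invisible(path)
}

#' Read an imaging movie from disk
#'
#' Expects the layout written by [write_movie()]: a multi-page TIFF with an
#' even number of pages (structural/activity interleaved) and a JSON sidecar
#' with `frame_interval` and `pixel_size`.
#'
#' @param path TIFF path (sidecar looked up next to it)
#' @return an [imaging_movie()]
#' @export
read_movie <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stopf("missing JSON sidecar: %s", sc_path)
  sc <- read_json_file(sc_path)
  if (is.null(sc$frame_interval)) stopf("sidecar lacks frame_interval: %s", sc_path)
  if (is.null(sc$pixel_size)) stopf("sidecar lacks pixel_size: %s", sc_path)
  pages <- read_tiff(path)
  if (length(pages) %% 2L != 0L) {
    stopf("channel count mismatch: %d TIFF pages cannot interleave 2 channels",
          length(pages))
  }
  n <- length(pages) / 2L
  if (!is.null(sc$n_frames) && sc$n_frames != n) {
    stopf("channel count mismatch: sidecar declares %d frame pairs, file has %d",
          sc$n_frames, n)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  s <- array(0, c(h, w, n)); a <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    s[, , i] <- pages[[2L * i - 1L]]
    a[, , i] <- pages[[2L * i]]
  }
  imaging_movie(s, a, sc$frame_interval, sc$pixel_size,
                metadata = as.list(sc$metadata %||% list()))
}

#' Write an ECoG recording to disk
#'
#' Samples as a one-column CSV (`mV` header) plus a JSON sidecar with
#' `sampling_rate`, `t0` and `units`.
#'
#' @param rec an [ecog_recording()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ecog <- function(rec, path) {
  stopifnot(inherits(rec, "EcogRecording"))
  utils::write.csv(data.frame(mV = rec$samples), path, row.names = FALSE)
  write_json_file(list(format = "gliawave-ecog", units = "mV",
                       sampling_rate = rec$sampling_rate, t0 = rec$t0,
                       n_samples = length(rec$samples)),
                  sidecar_path(path))
  invisible(path)
}

#' Read an ECoG recording from disk
#'
#' Accepts a one-column CSV or a raw little-endian float64 binary file plus a
#' JSON sidecar (`sampling_rate`, `t0`, `units`). Samples are converted to mV
#' (accepted units: mV, V, uV).
#'
#' @param path sample file path (`.csv` or binary)
#' @return an [ecog_recording()]
#' @export
read_ecog <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stopf("missing JSON sidecar: %s", sc_path)
  sc <- read_json_file(sc_path)
  if (is.null(sc$sampling_rate)) stopf("sidecar lacks sampling_rate: %s", sc_path)
  if (sc$sampling_rate <= 200) {
    stopf("sampling_rate %g Hz cannot resolve the 30-50 Hz analysis band",
          sc$sampling_rate)
  }
  units <- sc$units %||% "mV"
  scale <- switch(units, mV = 1, V = 1000, uV = 1e-3,
                  stopf("unknown ECoG units: %s", units))
  x <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path)[[1]]
  } else {
    readBin(path, "numeric", n = file.info(path)$size / 8L, size = 8L,
            endian = "little")
  }
  if (!length(x)) stopf("empty ECoG sample file: %s", path)
  ecog_recording(x * scale, sampling_rate = sc$sampling_rate, t0 = sc$t0 %||% 0)
}

#' Read a pipeline configuration document (JSON)
#'
#' @param path JSON configuration file
#' @return a named list
#' @export
read_config <- function(path) {
  cfg <- read_json_file(path)
  if (!is.list(cfg)) stopf("configuration must be a JSON object: %s", path)
  cfg
}
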