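# Zero-phase filtering and per-modality signal formats.
#
# All filters are Butterworth designs applied forward-backward (filtfilt),
# so event timing is preserved for window labelling. Inputs are extended by
# odd reflection about the endpoints before filtering and the extension is
# discarded afterwards; without this, drifting records show large end
# transients.

default_preproc_config <- function() {
  list(imu_highpass_hz = 0.3,
       piezo_highpass_hz = 0.1,
       piezo_band_low_hz = c(0.5, 5),
       piezo_band_high_hz = c(5, 30),
       rip_highpass_hz = 0.05,
       filter_order = 4)
}

filtfilt_padded <- function(filt, x) {
  n <- length(x)
  npad <- max(1L, min(n - 1L, 240L))
  pre  <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(npad + 1L):(npad + n)]
}

check_filter_args <- function(stream, cutoff_hz, order) {
  nyq <- stream$nominal_rate / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff %s Hz outside (0, Nyquist = %g Hz)",
                 paste(cutoff_hz, collapse = "-"), nyq), call. = FALSE)
  }
  if (n_samples(stream) <= 3 * order) {
    stop(sprintf("stream too short to filter: %d samples <= 3 * order %d",
                 n_samples(stream), order), call. = FALSE)
  }
}

apply_per_channel <- function(stream, f) {
  out <- stream
  out$channels <- lapply(stream$channels, f)
  out
}

#' Zero-phase high-pass filter
#'
#' De-means each channel and applies a zero-phase (forward-backward)
#' Butterworth high-pass. Used to remove gyroscope drift, accelerometer
#' gravity + drift, piezo baseline wander, and RIP belt drift.
#'
#' @param stream A [sensor_stream()].
#' @param cutoff_hz Cutoff frequency in Hz, in (0, Nyquist).
#' @param order Butterworth order (default 4).
#' @return A stream with the same timestamps and filtered channels.
#' @export
highpass <- function(stream, cutoff_hz, order = 4) {
  check_filter_args(stream, cutoff_hz, order)
  filt <- signal::butter(order, cutoff_hz / (stream$nominal_rate / 2),
                         type = "high")
  apply_per_channel(stream, function(x) filtfilt_padded(filt, x - mean(x)))
}

#' Zero-phase band-pass filter
#'
#' @param stream A [sensor_stream()].
#' @param band_hz Length-2 vector of band edges in Hz, inside (0, Nyquist).
#' @param order Butterworth order per edge (default 4).
#' @return A stream with filtered channels.
#' @export
bandpass <- function(stream, band_hz, order = 4) {
  stopifnot(length(band_hz) == 2, band_hz[1] < band_hz[2])
  check_filter_args(stream, band_hz, order)
  filt <- signal::butter(order, band_hz / (stream$nominal_rate / 2),
                         type = "pass")
  apply_per_channel(stream, function(x) filtfilt_padded(filt, x - mean(x)))
}

#' Standardize a stream's channels
#'
#' Applies `(x - mean) / sd` per channel, compensating for sensor positioning
#' and gain differences between subjects. The statistics come from
#' `reference_stats` (typically the training span when used inside the
#' classification pipeline, to avoid test-set leakage); by default they are
#' computed over the whole stream. Channels with zero SD map to all zeros.
#'
#' @param stream A [sensor_stream()].
#' @param reference_stats Optional list as returned by [stream_stats()].
#' @return A standardized stream.
#' @export
standardize <- function(stream, reference_stats = NULL) {
  if (is.null(reference_stats)) reference_stats <- stream_stats(stream)
  out <- stream
  for (ch in names(stream$channels)) {
    m <- reference_stats$mean[[ch]]
    s <- reference_stats$sd[[ch]]
    x <- stream$channels[[ch]]
    out$channels[[ch]] <- if (!is.finite(s) || s == 0) {
      rep(0, length(x))
    } else {
      (x - m) / s
    }
  }
  out
}

#' Per-channel mean and SD of a stream over a fitting span
#'
#' @param stream A [sensor_stream()].
#' @param span Optional `c(t0, t1)` restricting the samples used.
#' @return List with named numeric vectors `mean` and `sd`.
#' @export
stream_stats <- function(stream, span = NULL) {
  idx <- if (is.null(span)) {
    seq_along(stream$timestamps)
  } else {
    which(stream$timestamps >= span[1] & stream$timestamps < span[2])
  }
  list(mean = vapply(stream$channels, function(x) mean(x[idx]), numeric(1)),
       sd = vapply(stream$channels,
                   function(x) stats::sd(x[idx]), numeric(1)))
}

#' IMU format bundle: raw and high-passed variants
#'
#' The inertial data are kept in two formats: the raw stream and a
#' high-passed version (removing drift on the gyroscope; drift and gravity
#' on the accelerometer).
#'
#' @param stream An IMU [sensor_stream()].
#' @param config Preprocessing configuration list.
#' @return List of class `format_bundle` with variants `raw`, `highpass`.
#' @export
make_imu_formats <- function(stream, config = default_preproc_config()) {
  stopifnot(stream$modality == "imu")
  structure(list(modality = "imu",
                 variants = list(
                   raw = stream,
                   highpass = highpass(stream, config$imu_highpass_hz,
                                       config$filter_order))),
            class = "format_bundle")
}

#' Piezo format bundle: four standardized variants
#'
#' Converts the jaw piezo stream into four formats: the original, a
#' high-pass de-meaned version, and two band-pass versions (defaults
#' 0.5-5 Hz, covering chewing fundamentals, and 5-30 Hz for higher-frequency
#' content). All variants are standardized per channel.
#'
#' @param stream A piezo [sensor_stream()].
#' @param config Preprocessing configuration list.
#' @param reference_span Optional `c(t0, t1)` span for standardization stats.
#' @return List of class `format_bundle` with variants `raw`, `highpass`,
#'   `bandpass_low`, `bandpass_high`.
#' @export
make_piezo_formats <- function(stream, config = default_preproc_config(),
                               reference_span = NULL) {
  stopifnot(stream$modality == "piezo")
  std <- function(s) standardize(s, stream_stats(s, reference_span))
  structure(list(modality = "piezo",
                 variants = list(
                   raw = std(stream),
                   highpass = std(highpass(stream, config$piezo_highpass_hz,
                                           config$filter_order)),
                   bandpass_low = std(bandpass(stream,
                                               config$piezo_band_low_hz,
                                               config$filter_order)),
                   bandpass_high = std(bandpass(stream,
                                                config$piezo_band_high_hz,
                                                config$filter_order)))),
            class = "format_bundle")
}

#' Scale RIP belts to a lung-volume estimate
#'
#' Estimates lung volume as abdomen + ribs, removes drift with a zero-phase
#' high-pass configured slightly above zero Hz (default 0.05 Hz), then maps
#' the result affinely so that the breath-calibration interval's minimum
#' (forced exhale) becomes 0 and its maximum (maximal inhale) becomes 1.
#' The result is invariant to common belt gain.
#'
#' @param stream A RIP [sensor_stream()].
#' @param calibration_interval `c(t0, t1)` of the calibration action.
#' @param config Preprocessing configuration list.
#' @return List of class `format_bundle` with a single variant
#'   `volume_scaled_demeaned` (single channel `volume`) plus a `calibration`
#'   element recording the pre-scaling min/max volume levels.
#' @export
scale_rip_to_lung_volume <- function(stream, calibration_interval,
                                     config = default_preproc_config()) {
  stopifnot(stream$modality == "rip")
  if (length(calibration_interval) != 2 ||
      calibration_interval[1] >= calibration_interval[2]) {
    stop("calibration interval must be c(t0, t1) with t0 < t1",
         call. = FALSE)
  }
  vol_raw <- stream$channels$abdomen + stream$channels$ribs
  filt <- signal::butter(config$filter_order,
                         config$rip_highpass_hz / (stream$nominal_rate / 2),
                         type = "high")
  vol <- filtfilt_padded(filt, vol_raw - mean(vol_raw))
  sel <- stream$timestamps >= calibration_interval[1] &
    stream$timestamps <= calibration_interval[2]
  if (!any(sel)) {
    stop("calibration interval contains no RIP samples", call. = FALSE)
  }
  lo <- min(vol[sel]); hi <- max(vol[sel])
  if (hi - lo < 1e-12) {
    stop("flat calibration interval: cannot scale to lung volume",
         call. = FALSE)
  }
  scaled <- (vol - lo) / (hi - lo)
  out <- stream
  out$channels <- list(volume = scaled)
  class(out) <- "sensor_stream"
  structure(list(modality = "rip",
                 variants = list(volume_scaled_demeaned = out),
                 calibration = list(min_level = lo, max_level = hi,
                                    interval = calibration_interval)),
            class = "format_bundle")
}

#' @export
print.format_bundle <- function(x, ...) {
  cat(sprintf("<format_bundle %s: variants %s>\n", x$modality,
              paste(names(x$variants), collapse = ", ")))
  invisible(x)
}
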