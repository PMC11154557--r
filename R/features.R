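# Per-window feature registries.
#
# Sizes are contractual: 27 wrist-IMU features (10 gyroscope + 17
# accelerometer) on 1 s windows, 29 piezo features on 3 s windows, 36 RIP
# features per breathing cycle (26 on the raw-shape cycle + 10 on its
# normalized form). Degenerate inputs (constant, all-zero, 2-sample) follow
# documented rules instead of producing NaN/Inf: correlations and spectral
# entropy of silence are 0, missing-neighbour ratios are 1.

REGISTRY_ID <- "bitewatch-registry-1"

rms <- function(x) sqrt(mean(x^2))
signal_energy <- function(x) sum(x^2)
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) 0L else sum(diff(s) != 0)
}
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
safe_skew <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  e1071::skewness(x, type = 2)
}
safe_kurt <- function(x) {
  if (length(x) < 4 || stats::sd(x) == 0) return(0)
  e1071::kurtosis(x, type = 2)
}
count_peaks_above <- function(x, thresh) {
  n <- length(x)
  if (n < 3) return(0L)
  mid <- x[2:(n - 1)]
  sum(mid > x[1:(n - 2)] & mid >= x[3:n] & mid > thresh)
}
local_extrema_count <- function(x) {
  n <- length(x)
  if (n < 3) return(0L)
  mid <- x[2:(n - 1)]
  sum((mid > x[1:(n - 2)] & mid >= x[3:n]) |
        (mid < x[1:(n - 2)] & mid <= x[3:n]))
}
trapz_area <- function(t, y) {
  if (length(t) < 2) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# one-sided power spectrum (DC removed) of a window
window_spectrum <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  k <- seq(2, max(2, floor(n / 2) + 1))
  list(freq = (k - 1) * rate / n, power = sp[k])
}
dominant_frequency <- function(x, rate) {
  if (length(x) < 4 || stats::sd(x) == 0) return(0)
  sp <- window_spectrum(x, rate)
  sp$freq[which.max(sp$power)]
}
band_power <- function(sp, band) {
  sum(sp$power[sp$freq >= band[1] & sp$freq < band[2]])
}
spectral_entropy <- function(x, rate) {
  if (length(x) < 4 || stats::sd(x) == 0) return(0)
  sp <- window_spectrum(x, rate)
  p <- sp$power / sum(sp$power)
  p <- p[p > 0]
  if (length(p) < 2) return(0)
  -sum(p * log(p)) / log(length(sp$power))
}

slice <- function(stream, w, ch) stream$channels[[ch]][w$i_start:w$i_end]

#' IMU feature registry names (27)
#' @return Character vector of feature names in registry order.
#' @export
imu_feature_names <- function() {
  c(paste0("gyro_hp_mean_", c("x", "y", "z")),
    paste0("gyro_hp_sd_", c("x", "y", "z")),
    "gyro_hp_mag_max", "gyro_hp_mag_min", "gyro_hp_mag_rms",
    "gyro_hp_zc_underarm",
    "acc_raw_mag_mean", "acc_raw_mag_sd", "acc_raw_mag_max",
    "acc_raw_mag_min",
    paste0("acc_hp_mean_", c("x", "y", "z")),
    paste0("acc_hp_sd_", c("x", "y", "z")),
    paste0("acc_hp_rms_", c("x", "y", "z")),
    "acc_hp_cor_xy", "acc_hp_cor_xz", "acc_hp_cor_yz",
    "acc_hp_mag_energy")
}

#' Compute the 27 wrist-IMU features for one window
#'
#' Gyroscope block (10, on the high-passed variant): per-axis mean and SD,
#' angular-speed magnitude max/min/RMS, and the zero-crossing count of the
#' underarm axis (`gx`). Accelerometer block (17): raw-magnitude mean, SD,
#' max, min; high-passed per-axis mean, SD and RMS; pairwise axis
#' correlations (0 for constant axes); and high-passed magnitude signal
#' energy.
#'
#' @param bundle IMU `format_bundle` with `raw` and `highpass` variants.
#' @param window One row of [fixed_windows()] output.
#' @return Named numeric vector of length 27.
#' @export
imu_features <- function(bundle, window) {
  if (window$i_end - window$i_start < 1) {
    stop("IMU window needs >= 2 samples", call. = FALSE)
  }
  hp <- bundle$variants$highpass
  raw <- bundle$variants$raw
  g <- lapply(c(x = "gx", y = "gy", z = "gz"),
              function(ch) slice(hp, window, ch))
  gmag <- sqrt(g$x^2 + g$y^2 + g$z^2)
  a_hp <- lapply(c(x = "ax", y = "ay", z = "az"),
                 function(ch) slice(hp, window, ch))
  a_raw <- lapply(c(x = "ax", y = "ay", z = "az"),
                  function(ch) slice(raw, window, ch))
  amag_raw <- sqrt(a_raw$x^2 + a_raw$y^2 + a_raw$z^2)
  amag_hp <- sqrt(a_hp$x^2 + a_hp$y^2 + a_hp$z^2)
  vals <- c(vapply(g, mean, numeric(1)),
            vapply(g, stats::sd, numeric(1)),
            max(gmag), min(gmag), rms(gmag),
            zero_crossings(g$x),
            mean(amag_raw), stats::sd(amag_raw), max(amag_raw),
            min(amag_raw),
            vapply(a_hp, mean, numeric(1)),
            vapply(a_hp, stats::sd, numeric(1)),
            vapply(a_hp, rms, numeric(1)),
            safe_cor(a_hp$x, a_hp$y), safe_cor(a_hp$x, a_hp$z),
            safe_cor(a_hp$y, a_hp$z),
            signal_energy(amag_hp))
  stats::setNames(vals, imu_feature_names())
}

#' Piezo feature registry names (29)
#' @return Character vector of feature names in registry order.
#' @export
piezo_feature_names <- function() {
  base <- c("mean", "sd", "max", "min", "rms", "energy", "zc", "peaks_1sd")
  c(paste0("hp_", base), paste0("bl_", base), paste0("bh_", base),
    "hp_domfreq", "hp_bandpow_low", "hp_bandpow_high",
    "hp_band_ratio", "hp_spec_entropy")
}

#' Compute the 29 jaw-piezo features for one window
#'
#' On each filtered variant (`highpass`, `bandpass_low`, `bandpass_high`):
#' mean, SD, max, min, RMS, signal energy, zero crossings, and the count of
#' local peaks above one window-SD (8 x 3 = 24). On the high-passed variant
#' only: dominant frequency, spectral power in the 0.5-5 Hz and 5-30 Hz
#' bands, their ratio, and normalized spectral entropy (5).
#'
#' @param bundle Piezo `format_bundle` with its four variants.
#' @param window One row of [fixed_windows()] output.
#' @return Named numeric vector of length 29.
#' @export
piezo_features <- function(bundle, window) {
  if (window$i_end - window$i_start < 1) {
    stop("piezo window needs >= 2 samples", call. = FALSE)
  }
  rate <- bundle$variants$highpass$nominal_rate
  per_variant <- function(x) {
    c(mean(x), stats::sd(x), max(x), min(x), rms(x), signal_energy(x),
      zero_crossings(x), count_peaks_above(x, stats::sd(x)))
  }
  hp <- slice(bundle$variants$highpass, window, "v")
  bl <- slice(bundle$variants$bandpass_low, window, "v")
  bh <- slice(bundle$variants$bandpass_high, window, "v")
  sp <- window_spectrum(hp, rate)
  pl <- band_power(sp, c(0.5, 5))
  ph <- band_power(sp, c(5, 30))
  vals <- c(per_variant(hp), per_variant(bl), per_variant(bh),
            dominant_frequency(hp, rate), pl, ph,
            if (ph > 0) pl / ph else 0,
            spectral_entropy(hp, rate))
  stats::setNames(vals, piezo_feature_names())
}

#' RIP feature registry names (36)
#' @return Character vector of feature names in registry order.
#' @export
rip_feature_names <- function() {
  c("duration", "inhale_dur", "exhale_dur", "inhale_exhale_ratio",
    "amplitude", "max", "min", "mean", "sd", "rms", "auc",
    "inhale_slope", "exhale_slope",
    "d1_max", "d1_min", "d1_sd", "n_extrema", "t_peak",
    "skewness", "kurtosis", "half_mean_diff", "half_sd_ratio",
    "dur_ratio_prev", "amp_ratio_prev", "dur_ratio_next", "amp_ratio_next",
    "norm_t_peak", "norm_auc", "norm_symmetry", "norm_mean", "norm_sd",
    "norm_skewness", "norm_kurtosis", "norm_y25", "norm_y50", "norm_y75")
}

#' Compute the 36 RIP breathing-cycle features
#'
#' Non-normalized block (26), on the scaled-volume cycle: duration, inhale
#' and exhale durations (split at the cycle maximum) and their ratio,
#' amplitude, max, min, mean, SD, RMS, area under the curve, inhale and
#' exhale slopes, first-derivative max/min/SD, local extrema count, time of
#' peak, skewness, kurtosis, first-half vs second-half mean difference and
#' SD ratio, and duration/amplitude ratios to the previous and next cycles
#' (1 when the neighbour is missing). Normalized block (10), on the
#' normalized shape: time of peak, area under the curve, symmetry score
#' (mean |y(t) - y(1-t)| on a uniform grid), mean, SD, skewness, kurtosis,
#' and the values at t = 0.25, 0.5, 0.75.
#'
#' @param cycle A `breathing_cycle` from [segment_breathing_cycles()].
#' @param prev_cycle,next_cycle Neighbouring cycles, or NULL at the record
#'   edges.
#' @return Named numeric vector of length 36.
#' @export
rip_features <- function(cycle, prev_cycle = NULL, next_cycle = NULL) {
  t <- cycle$t; y <- cycle$y
  dur <- cycle$duration
  ipk <- which.max(y)
  t_pk <- t[ipk] - t[1]
  inh <- max(t_pk, 1e-9)
  exh <- max(dur - t_pk, 1e-9)
  amp <- max(y) - min(y)
  d1 <- diff(y) / diff(t)
  half <- t < t[1] + dur / 2
  sd2 <- stats::sd(y[!half])
  neighbour_ratio <- function(nb, what) {
    if (is.null(nb)) return(1)
    ref <- if (what == "dur") nb$duration else max(nb$y) - min(nb$y)
    if (ref <= 1e-12) 1 else {
      if (what == "dur") dur / ref else amp / ref
    }
  }
  nm <- cycle$norm
  if (is.null(nm)) nm <- normalize_cycle(cycle)
  grid <- seq(0, 1, length.out = 101)
  yg <- stats::approx(nm$t, nm$y, xout = grid, rule = 2)$y
  vals <- c(dur, inh, exh, inh / exh,
            amp, max(y), min(y), mean(y), stats::sd(y), rms(y),
            trapz_area(t, y),
            (max(y) - y[1]) / inh, (y[length(y)] - max(y)) / exh,
            max(d1), min(d1), stats::sd(d1), local_extrema_count(y), t_pk,
            safe_skew(y), safe_kurt(y),
            mean(y[half]) - mean(y[!half]),
            if (is.finite(sd2) && sd2 > 0) stats::sd(y[half]) / sd2 else 1,
            neighbour_ratio(prev_cycle, "dur"),
            neighbour_ratio(prev_cycle, "amp"),
            neighbour_ratio(next_cycle, "dur"),
            neighbour_ratio(next_cycle, "amp"),
            nm$t[which.max(nm$y)], trapz_area(nm$t, nm$y),
            mean(abs(yg - rev(yg))), mean(nm$y), stats::sd(nm$y),
            safe_skew(nm$y), safe_kurt(nm$y),
            yg[26], yg[51], yg[76])
  stats::setNames(vals, rip_feature_names())
}

#' Compute all per-window features for a session
#'
#' Runs preprocessing, segmentation, and the three feature registries over a
#' session, producing one feature matrix per modality plus the window /
#' cycle tables needed by fusion.
#'
#' @param sess An [session()] object.
#' @param preproc Preprocessing configuration (see package defaults).
#' @param seg Segmentation configuration.
#' @return List of class `session_features` with elements `imu`, `piezo`,
#'   `rip`, each holding `windows` (data.frame with midpoints and extents)
#'   and `features` (matrix, one row per window in time order), plus
#'   `annotations`, `subject_id` and `registry_id`.
#' @export
session_features <- function(sess,
                             preproc = default_preproc_config(),
                             seg = default_segmentation_config()) {
  stopifnot(inherits(sess, "adm_session"))
  imu_b <- make_imu_formats(sess$streams$imu, preproc)
  pz_b <- make_piezo_formats(sess$streams$piezo, preproc)
  calib <- sess$annotations[sess$annotations$label == "breath_calibration", ]
  if (!nrow(calib)) {
    stop("session lacks a breath_calibration annotation; cannot scale RIP",
         call. = FALSE)
  }
  rip_b <- scale_rip_to_lung_volume(sess$streams$rip,
                                    c(calib$t_start[1], calib$t_end[1]),
                                    preproc)

  iw <- fixed_windows(imu_b, seg$imu_window_s)
  pw <- fixed_windows(pz_b, seg$piezo_window_s)
  cycles <- segment_breathing_cycles(rip_b, seg)

  imu_f <- t(vapply(seq_len(nrow(iw)), function(i)
    imu_features(imu_b, iw[i, ]), numeric(27)))
  pz_f <- t(vapply(seq_len(nrow(pw)), function(i)
    piezo_features(pz_b, pw[i, ]), numeric(29)))
  nc <- length(cycles)
  rip_f <- t(vapply(seq_len(nc), function(i)
    rip_features(cycles[[i]],
                 if (i > 1) cycles[[i - 1]] else NULL,
                 if (i < nc) cycles[[i + 1]] else NULL),
    numeric(36)))
  if (nc == 0) rip_f <- matrix(numeric(0), 0, 36,
                               dimnames = list(NULL, rip_feature_names()))
  cw <- data.frame(
    index = seq_len(nc),
    t_start = vapply(cycles, `[[`, numeric(1), "t_start"),
    t_end = vapply(cycles, `[[`, numeric(1), "t_end"))
  cw$midpoint <- (cw$t_start + cw$t_end) / 2

  structure(list(
    imu = list(windows = iw, features = imu_f),
    piezo = list(windows = pw, features = pz_f),
    rip = list(windows = cw, features = rip_f, cycles = cycles),
    annotations = sess$annotations,
    subject_id = sess$subject_id,
    registry_id = REGISTRY_ID),
    class = "session_features")
}
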