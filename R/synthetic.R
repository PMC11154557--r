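# Synthetic session generator.
#
# Emulates a scripted table-top protocol: a 20 s lung-volume calibration,
# a ~5 min spoon-fed course and a ~3 min hand-fed course, separated by
# confounder blocks (random arm movement, sitting still with periodic head
# scratching, reading aloud). Three modalities are rendered from the same
# event script so ground truth is exact by construction.

#' Generator configuration
#'
#' Tunable parameters of the synthetic session generator. Defaults encode the
#' protocol conditions the pipeline is designed for: nominal sampling rates of
#' 83 Hz (wrist IMU), 204 Hz (jaw piezo) and 6.2 Hz (RIP belts); a mean quiet
#' breathing period of 3.6 s; a chewing fundamental of 1.6 Hz; and a 0.6 s
#' swallow-induced breathing pause (>= 3 samples at 6.2 Hz).
#'
#' @param rates Named sampling rates in Hz for `imu`, `piezo`, `rip`.
#' @param noise_sd Named white-noise standard deviations: `accel` (m/s^2),
#'   `gyro` (rad/s), `piezo`, `rip` (arbitrary units).
#' @param breath_period_s Mean quiet breathing period in seconds.
#' @param breath_period_jitter SD of per-cycle period jitter in seconds.
#' @param chew_hz Chewing fundamental frequency in Hz.
#' @param chew_amp Piezo chew-burst amplitude (arbitrary units, pre-noise).
#' @param read_amp Piezo amplitude of reading-aloud wideband activity.
#' @param gesture_amp Named amplitude ranges (rad/s) for gesture pulses:
#'   `spoon_min`, `spoon_max`, `hand_min`, `hand_max`.
#' @param gesture_period_s Mean spacing between successive eating gestures
#'   within an eating course, in seconds.
#' @param swallow_pause_s Duration of the breathing plateau a swallow inserts.
#' @param gravity Gravitational acceleration (m/s^2) on the resting axis.
#' @param piezo_drift_slope,rip_drift_slope Linear drift slopes (units/s).
#' @param calib_amp Breathing amplitude multiplier during calibration (deep
#'   breaths); quiet cycles draw amplitudes in `quiet_amp_range`.
#' @param calib_trough Depth below the quiet end-exhale level reached during
#'   the calibration's forced exhale.
#' @param quiet_amp_range Range of per-cycle amplitude factors for quiet
#'   breathing.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(rates = c(imu = 83, piezo = 204, rip = 6.2),
                             noise_sd = c(accel = 0.15, gyro = 0.05,
                                          piezo = 0.08, rip = 0.012),
                             breath_period_s = 3.6,
                             breath_period_jitter = 0.25,
                             chew_hz = 1.6,
                             chew_amp = 1.0,
                             read_amp = 0.25,
                             gesture_amp = c(spoon_min = 1.5, spoon_max = 2.5,
                                             hand_min = 3.0, hand_max = 5.0),
                             gesture_period_s = 20,
                             swallow_pause_s = 0.6,
                             gravity = 9.81,
                             piezo_drift_slope = 0.002,
                             rip_drift_slope = 0.003,
                             calib_amp = 1.8,
                             calib_trough = 0.4,
                             quiet_amp_range = c(0.85, 1.1)) {
  stopifnot(all(rates > 0), breath_period_s > 1, all(noise_sd >= 0),
            chew_hz > 0, swallow_pause_s > 0)
  structure(list(rates = rates, noise_sd = noise_sd,
                 breath_period_s = breath_period_s,
                 breath_period_jitter = breath_period_jitter,
                 chew_hz = chew_hz, chew_amp = chew_amp, read_amp = read_amp,
                 gesture_amp = gesture_amp,
                 gesture_period_s = gesture_period_s,
                 swallow_pause_s = swallow_pause_s, gravity = gravity,
                 piezo_drift_slope = piezo_drift_slope,
                 rip_drift_slope = rip_drift_slope,
                 calib_amp = calib_amp, calib_trough = calib_trough,
                 quiet_amp_range = quiet_amp_range),
            class = "generator_config")
}

#' Build the protocol event script
#'
#' Produces the eight-action protocol in order: 20 s breath calibration, a
#' ~5 min spoon-fed course, 1 min random arm movement, 2 min sitting still
#' with a head scratch every 10 s, 3 min reading aloud, another 2 min
#' still/scratch block, a ~3 min hand-fed course, and a final 1 min of random
#' arm movement. The two "~" course durations are drawn uniformly within
#' +/-10 % of nominal. Within eating courses, micro-events are laid out as
#' gesture -> chew burst -> swallow cycles (spoon gestures ~3 s, hand
#' gestures ~2 s, chew bursts filling most of the inter-gesture interval).
#'
#' @param seed Integer seed; the same seed reproduces the same script.
#' @param config A [generator_config()].
#' @return Data.frame of class `event_script` with columns `label`,
#'   `t_start`, `t_end`, `level` ("action" or "micro"), `detail`
#'   ("spoon"/"hand" for gestures, "" otherwise).
#' @export
make_protocol_script <- function(seed = 1, config = generator_config()) {
  set.seed(as.integer(seed))
  approx_dur <- function(nominal) nominal * stats::runif(1, 0.9, 1.1)
  acts <- list(
    list(label = "breath_calibration", dur = 20, eat = NA),
    list(label = "eating",             dur = approx_dur(300), eat = "spoon"),
    list(label = "random_arm",         dur = 60, eat = NA),
    list(label = "still",              dur = 120, eat = NA),
    list(label = "reading_aloud",      dur = 180, eat = NA),
    list(label = "still",              dur = 120, eat = NA),
    list(label = "eating",             dur = approx_dur(180), eat = "hand"),
    list(label = "random_arm",         dur = 60, eat = NA))
  rows <- list()
  t <- 0
  add <- function(label, t0, t1, level, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, t_start = t0, t_end = t1, level = level,
      detail = detail, stringsAsFactors = FALSE)
  }
  for (a in acts) {
    t0 <- t; t1 <- t + a$dur
    if (a$label == "eating") {
      # course-level row is script bookkeeping (never annotated);
      # the nested micro-events carry the ground-truth labels
      add("eating", t0, t1, "action", a$eat)
      gest_dur <- if (a$eat == "spoon") 3 else 2
      tc <- t0 + 2
      while (tc + gest_dur + 8 < t1) {
        period <- stats::rnorm(1, config$gesture_period_s,
                               config$gesture_period_s * 0.075)
        period <- min(max(period, 0.85 * config$gesture_period_s),
                      1.15 * config$gesture_period_s)
        g0 <- tc
        g1 <- g0 + gest_dur * stats::runif(1, 0.9, 1.1)
        add("eating_gesture", g0, g1, "micro", a$eat)
        chew0 <- g1 + 0.5
        chew1 <- min(g0 + period - 1.5, t1 - 0.5)
        if (chew1 - chew0 >= 5) {
          add("chewing", chew0, chew1, "micro")
          sw <- chew1 - stats::runif(1, 0.5, 1.5)
          add("swallowing", sw, sw + config$swallow_pause_s, "micro")
        }
        tc <- g0 + period
      }
    } else if (a$label == "still") {
      add("still", t0, t1, "action")
      sc <- seq(t0 + 5, t1 - 2, by = 10)
      for (s0 in sc) add("scratch_head", s0, s0 + 1.5, "micro")
      # one saliva swallow mid-block, unrelated to eating
      sal <- (t0 + t1) / 2 + stats::runif(1, -5, 5)
      add("swallowing", sal, sal + config$swallow_pause_s, "micro")
    } else {
      add(a$label, t0, t1, "action")
    }
    t <- t1
  }
  script <- do.call(rbind, rows)
  script <- script[order(script$t_start, script$t_end), ]
  rownames(script) <- NULL
  class(script) <- c("event_script", "data.frame")
  script
}

script_duration <- function(script) max(script$t_end)

# raised-cosine ramp up over [0, r], hold, ramp down over [1-r, 1]
plateau_pulse <- function(u, r = 0.25) {
  y <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  yi <- rep(1, length(ui))
  up <- ui < r
  yi[up] <- 0.5 * (1 - cos(pi * ui[up] / r))
  dn <- ui > 1 - r
  yi[dn] <- 0.5 * (1 - cos(pi * (1 - ui[dn]) / r))
  y[inside] <- yi
  y
}

hann_win <- function(u) ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)

# smoothed gaussian noise: white noise convolved with a moving average
smooth_noise <- function(n, rate, tau_s) {
  k <- max(1L, round(tau_s * rate))
  x <- stats::rnorm(n + k)
  y <- stats::filter(x, rep(1 / k, k), sides = 1)
  as.numeric(y[(k + 1):(k + n)]) * sqrt(k)
}

#' Render a session from an event script
#'
#' Synthesizes the three sensor streams sample-by-sample from the script and
#' returns a [session()] whose annotation track records every rendered
#' micro-event as ground truth. The same `(script, config, seed)` triple
#' yields a bit-identical session.
#'
#' Signal model, per modality:
#' * IMU: gravity on the `az` axis plus white noise; each eating gesture adds
#'   a forearm-rotation pulse on the underarm gyroscope axis `gx` (smooth
#'   plateau for spoon gestures, sharp biphasic for hand gestures) with a
#'   correlated accelerometer excursion; head scratches add a 4 Hz
#'   oscillation on `gy`/`gz`; random-arm blocks add band-limited noise on
#'   all axes.
#' * Piezo: linear drift plus a slow baseline sinusoid and white noise; chew
#'   bursts add an amplitude-modulated oscillation at the chewing fundamental
#'   with 2nd/3rd harmonics; reading aloud adds lower-amplitude wideband
#'   activity with a syllabic envelope.
#' * RIP: abdomen and ribs are phase-locked quasi-sinusoidal fractions of a
#'   common lung-volume trace built cycle-by-cycle with jittered periods;
#'   each swallow inserts a plateau deforming exactly one cycle; the opening
#'   calibration action sweeps to the global volume extremes (deep breaths
#'   with a forced exhale below the quiet end-exhale level).
#'
#' Swallow annotations are snapped to the interior (phase 0.25-0.70) of the
#' breathing cycle containing them, so each lies inside exactly one cycle.
#'
#' @param script An event script from [make_protocol_script()].
#' @param config A [generator_config()].
#' @param seed Integer seed for the rendering noise.
#' @param subject_id Subject identifier for the returned session.
#' @return An [session()] object.
#' @export
synthesize_session <- function(script, config = generator_config(), seed = 1,
                               subject_id = sprintf("synth%03d", seed)) {
  if (!nrow(script)) stop("empty event script", call. = FALSE)
  if (any(config$rates <= 0)) stop("sampling rates must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  dur <- script_duration(script)

  grid <- function(rate) {
    n <- floor(dur * rate + 1e-9)
    (seq_len(n) - 1) / rate
  }
  t_imu <- grid(config$rates[["imu"]])
  t_pz  <- grid(config$rates[["piezo"]])
  t_rip <- grid(config$rates[["rip"]])

  ann <- script[script$level == "micro" | script$label %in%
                  c("random_arm", "reading_aloud", "still",
                    "breath_calibration"),
                c("t_start", "t_end", "label")]

  ## ---- RIP: cycle-by-cycle lung volume -------------------------------
  calib_end <- script$t_end[script$label == "breath_calibration"][1]
  if (is.na(calib_end)) calib_end <- 0
  starts <- numeric(0); periods <- numeric(0); amps <- numeric(0)
  troughs <- numeric(0); peaks_at <- numeric(0)
  tcur <- 0
  while (tcur < dur) {
    if (tcur < calib_end - 1e-9) {
      p <- stats::runif(1, 4.5, 5.5)          # slow, deep calibration breaths
      a <- config$calib_amp
      tr <- config$calib_trough
    } else {
      p <- stats::rnorm(1, config$breath_period_s, config$breath_period_jitter)
      p <- min(max(p, config$breath_period_s - 0.8),
               config$breath_period_s + 1.0)
      a <- stats::runif(1, config$quiet_amp_range[1], config$quiet_amp_range[2])
      tr <- 0
    }
    starts <- c(starts, tcur); periods <- c(periods, p); amps <- c(amps, a)
    troughs <- c(troughs, tr)
    peaks_at <- c(peaks_at, stats::runif(1, 0.40, 0.50))
    tcur <- tcur + p
  }
  cyc_of <- findInterval(t_rip, starts)
  u <- (t_rip - starts[cyc_of]) / periods[cyc_of]
  pk <- peaks_at[cyc_of]
  shape <- ifelse(u <= pk,
                  0.5 * (1 - cos(pi * u / pk)),
                  0.5 * (1 + cos(pi * (u - pk) / (1 - pk))))
  # calibration cycles start from a forced-exhale trough below the quiet
  # end-exhale level, so quiet breathing sits strictly inside the
  # calibration extremes after volume scaling
  vol <- amps[cyc_of] * shape - troughs[cyc_of] * (1 - u)

  # swallows: snap into cycle interiors and flatten the volume there
  sw <- ann$label == "swallowing"
  if (any(sw)) {
    for (i in which(sw)) {
      ts <- ann$t_start[i]
      ci <- findInterval(ts, starts)
      ci <- max(ci, findInterval(calib_end, starts) + 1L)
      ci <- min(ci, length(starts))
      ph <- (ts - starts[ci]) / periods[ci]
      ph <- min(max(ph, 0.25), 0.70)
      ts2 <- starts[ci] + ph * periods[ci]
      te2 <- ts2 + config$swallow_pause_s
      sel <- t_rip >= ts2 & t_rip <= te2
      if (any(sel)) {
        anchor_idx <- which(sel)[1]
        vol[sel] <- vol[max(anchor_idx - 1L, 1L)]
      }
      ann$t_start[i] <- ts2
      ann$t_end[i] <- te2
    }
  }

  drift_rip <- config$rip_drift_slope * t_rip +
    0.05 * sin(2 * pi * t_rip / 300 + stats::runif(1, 0, 2 * pi))
  n_rip <- length(t_rip)
  abdomen <- 0.6 * vol + 0.8 * drift_rip +
    stats::rnorm(n_rip, 0, config$noise_sd[["rip"]])
  ribs <- 0.4 * vol + 0.5 * drift_rip +
    stats::rnorm(n_rip, 0, config$noise_sd[["rip"]])

  ## ---- IMU ------------------------------------------------------------
  n_imu <- length(t_imu)
  imu <- list(
    ax = stats::rnorm(n_imu, 0, config$noise_sd[["accel"]]),
    ay = stats::rnorm(n_imu, 0, config$noise_sd[["accel"]]),
    az = config$gravity + stats::rnorm(n_imu, 0, config$noise_sd[["accel"]]),
    gx = stats::rnorm(n_imu, 0, config$noise_sd[["gyro"]]),
    gy = stats::rnorm(n_imu, 0, config$noise_sd[["gyro"]]),
    gz = stats::rnorm(n_imu, 0, config$noise_sd[["gyro"]]))

  gest <- script[script$label == "eating_gesture", ]
  if (nrow(gest)) for (i in seq_len(nrow(gest))) {
    g0 <- gest$t_start[i]; g1 <- gest$t_end[i]
    uu <- (t_imu - g0) / (g1 - g0)
    if (gest$detail[i] == "spoon") {
      A <- stats::runif(1, config$gesture_amp[["spoon_min"]],
                        config$gesture_amp[["spoon_max"]])
      pulse <- A * plateau_pulse(uu, r = 0.3)      # slow plateau rotation
    } else {
      A <- stats::runif(1, config$gesture_amp[["hand_min"]],
                        config$gesture_amp[["hand_max"]])
      pulse <- A * sin(2 * pi * uu) * hann_win(uu)  # sharp biphasic rotation
    }
    imu$gx <- imu$gx + pulse
    imu$ax <- imu$ax + 1.5 * plateau_pulse(uu, r = 0.4)
    imu$ay <- imu$ay - 1.0 * hann_win(uu)
  }
  scr <- script[script$label == "scratch_head", ]
  if (nrow(scr)) for (i in seq_len(nrow(scr))) {
    uu <- (t_imu - scr$t_start[i]) / (scr$t_end[i] - scr$t_start[i])
    env <- hann_win(uu)
    osc <- sin(2 * pi * 4 * (t_imu - scr$t_start[i]))
    imu$gy <- imu$gy + 1.5 * env * osc
    imu$gz <- imu$gz + 0.8 * env
    imu$ax <- imu$ax + 0.8 * env * osc
  }
  ra <- script[script$label == "random_arm", ]
  if (nrow(ra)) for (i in seq_len(nrow(ra))) {
    sel <- t_imu >= ra$t_start[i] & t_imu < ra$t_end[i]
    n <- sum(sel)
    if (n > 0) {
      for (ch in c("gx", "gy", "gz")) {
        imu[[ch]][sel] <- imu[[ch]][sel] +
          1.2 * smooth_noise(n, config$rates[["imu"]], 0.3)
      }
      for (ch in c("ax", "ay")) {
        imu[[ch]][sel] <- imu[[ch]][sel] +
          1.0 * smooth_noise(n, config$rates[["imu"]], 0.3)
      }
    }
  }

  ## ---- Piezo ----------------------------------------------------------
  n_pz <- length(t_pz)
  v <- config$piezo_drift_slope * t_pz +
    0.3 * sin(2 * pi * t_pz / 120 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n_pz, 0, config$noise_sd[["piezo"]])
  chews <- script[script$label == "chewing", ]
  if (nrow(chews)) for (i in seq_len(nrow(chews))) {
    c0 <- chews$t_start[i]; c1 <- chews$t_end[i]
    sel <- t_pz >= c0 & t_pz < c1
    tt <- t_pz[sel]
    uu <- (tt - c0) / (c1 - c0)
    f <- config$chew_hz * stats::runif(1, 0.98, 1.02)
    env <- plateau_pulse(uu, r = 0.1) *
      (0.8 + 0.2 * sin(2 * pi * tt / 4))          # slow bite-to-bite AM
    phi <- stats::runif(1, 0, 2 * pi)
    v[sel] <- v[sel] + config$chew_amp * env *
      (sin(2 * pi * f * tt + phi) +
         0.4 * sin(2 * pi * 2 * f * tt + phi) +
         0.2 * sin(2 * pi * 3 * f * tt + phi))
  }
  rd <- script[script$label == "reading_aloud", ]
  if (nrow(rd)) for (i in seq_len(nrow(rd))) {
    sel <- t_pz >= rd$t_start[i] & t_pz < rd$t_end[i]
    n <- sum(sel)
    if (n > 0) {
      syll <- 0.6 + 0.4 * sin(2 * pi * 4 * t_pz[sel])
      v[sel] <- v[sel] + config$read_amp * syll * stats::rnorm(n)
    }
  }

  streams <- list(
    imu = sensor_stream("imu", t_imu, imu, config$rates[["imu"]]),
    piezo = sensor_stream("piezo", t_pz, list(v = v),
                          config$rates[["piezo"]]),
    rip = sensor_stream("rip", t_rip, list(abdomen = abdomen, ribs = ribs),
                        config$rates[["rip"]]))
  session(subject_id, streams, ann, duration = dur)
}

#' Generate a complete synthetic session in one call
#'
#' Convenience wrapper: builds the protocol script and renders it.
#'
#' @inheritParams synthesize_session
#' @param seed Integer seed controlling both script layout and rendering.
#' @return An [session()] object.
#' @export
simulate_session <- function(seed = 1, config = generator_config(),
                             subject_id = sprintf("synth%03d", seed)) {
  script <- make_protocol_script(seed, config)
  synthesize_session(script, config, seed = seed + 1000L,
                     subject_id = subject_id)
}
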