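zero_imu_bundle <- function(n = 83) {
  s <- imu_stream_from(n)
  list_bundle <- structure(list(modality = "imu",
                                variants = list(raw = s, highpass = s)),
                           class = "format_bundle")
  list_bundle
}

one_window <- function(n) {
  data.frame(index = 1L, t_start = 0, t_end = n, midpoint = n / 2,
             i_start = 1L, i_end = n)
}

test_that("feature registries carry their contractual sizes", {
  sf <- cached_features()
  expect_equal(ncol(sf$imu$features), 27)
  expect_equal(ncol(sf$piezo$features), 29)
  expect_equal(ncol(sf$rip$features), 36)
  expect_length(imu_feature_names(), 27)
  expect_length(piezo_feature_names(), 29)
  expect_length(rip_feature_names(), 36)
  # gyroscope 10 + accelerometer 17; RIP 26 non-normalized + 10 normalized
  expect_equal(sum(startsWith(imu_feature_names(), "gyro_")), 10)
  expect_equal(sum(startsWith(imu_feature_names(), "acc_")), 17)
  expect_equal(sum(startsWith(rip_feature_names(), "norm_")), 10)
  expect_equal(sum(!startsWith(rip_feature_names(), "norm_")), 26)
})

test_that("no feature is NaN or Inf on a full synthetic session", {
  sf <- cached_features()
  expect_true(all(is.finite(sf$imu$features)))
  expect_true(all(is.finite(sf$piezo$features)))
  expect_true(all(is.finite(sf$rip$features)))
})

test_that("all-zero IMU windows obey the degenerate rules", {
  b <- zero_imu_bundle()
  f <- imu_features(b, one_window(83))
  expect_length(f, 27)
  expect_true(all(is.finite(f)))
  expect_true(all(f[c("gyro_hp_mean_x", "gyro_hp_sd_x", "gyro_hp_mag_rms",
                      "acc_hp_mag_energy", "acc_hp_cor_xy",
                      "acc_hp_cor_xz", "acc_hp_cor_yz")] == 0))
})

test_that("constant-magnitude rotation has magnitude RMS equal to it", {
  s <- imu_stream_from(83)
  # rotation vector of constant norm 2 spinning in the x-y gyro plane
  th <- seq(0, 4 * pi, length.out = 83)
  s$channels$gx <- 2 * cos(th)
  s$channels$gy <- 2 * sin(th)
  b <- structure(list(modality = "imu",
                      variants = list(raw = s, highpass = s)),
                 class = "format_bundle")
  f <- imu_features(b, one_window(83))
  expect_equal(unname(f["gyro_hp_mag_rms"]), 2, tolerance = 1e-12)
  expect_equal(unname(f["gyro_hp_mag_max"]), 2, tolerance = 1e-12)
})

test_that("window-size contract is enforced", {
  b <- zero_imu_bundle(2)
  w <- one_window(2); w$i_end <- 1L
  expect_error(imu_features(b, w), ">= 2 samples")
})

test_that("piezo features localize a pure tone (DFT oracle)", {
  t <- (0:(3 * 204 - 1)) / 204
  x <- sin(2 * pi * 1.6 * t)
  s <- piezo_stream(x)
  b <- structure(list(modality = "piezo",
                      variants = list(raw = s, highpass = s,
                                      bandpass_low = s, bandpass_high = s)),
                 class = "format_bundle")
  f <- piezo_features(b, one_window(length(t)))
  expect_length(f, 29)
  expect_lt(abs(f[["hp_domfreq"]] - 1.6), 204 / length(t) + 1e-9)
  expect_gt(f[["hp_bandpow_low"]], f[["hp_bandpow_high"]])
})

test_that("all-zero piezo windows obey the degenerate rules", {
  z <- piezo_stream(rep(0, 612))
  b <- structure(list(modality = "piezo",
                      variants = list(raw = z, highpass = z,
                                      bandpass_low = z, bandpass_high = z)),
                 class = "format_bundle")
  f <- piezo_features(b, one_window(612))
  expect_true(all(f == 0))
})

test_that("piezo high-pass features ignore a constant offset", {
  sess <- cached_session()
  shifted <- sess$streams$piezo
  shifted$channels$v <- shifted$channels$v + 11
  b1 <- make_piezo_formats(sess$streams$piezo)
  b2 <- make_piezo_formats(shifted)
  w <- fixed_windows(b1, 3)[5, ]
  f1 <- piezo_features(b1, w)
  f2 <- piezo_features(b2, w)
  hp_cols <- startsWith(names(f1), "hp_") | startsWith(names(f1), "bl_") |
    startsWith(names(f1), "bh_")
  expect_equal(f1[hp_cols], f2[hp_cols], tolerance = 1e-6)
})

test_that("breathing-cycle features read shape asymmetry correctly", {
  # slow inhale over 90 % of the cycle, near-instant exhale
  t <- seq(0, 4, length.out = 41)
  y <- c(seq(0, 1, length.out = 37), seq(0.8, 0, length.out = 4))
  cyc <- structure(list(t_start = 0, t_end = 4, duration = 4, t = t, y = y),
                   class = "breathing_cycle")
  f <- rip_features(cyc)
  expect_length(f, 36)
  expect_gt(f[["inhale_exhale_ratio"]], 5)
  expect_equal(unname(f[["dur_ratio_prev"]]), 1)   # missing neighbours
  expect_equal(unname(f[["amp_ratio_next"]]), 1)

  # symmetric cycle: peak centred, symmetry score ~ 0
  ts <- seq(0, 3.6, length.out = 37)
  ys <- 0.5 * (1 - cos(2 * pi * ts / 3.6))
  sym <- structure(list(t_start = 0, t_end = 3.6, duration = 3.6,
                        t = ts, y = ys), class = "breathing_cycle")
  fs <- rip_features(sym)
  expect_equal(unname(fs[["norm_t_peak"]]), 0.5, tolerance = 0.03)
  expect_lt(fs[["norm_symmetry"]], 0.02)
})

test_that("neighbour ratios use the adjacent cycles when present", {
  mk <- function(dur, amp) {
    t <- seq(0, dur, length.out = 25)
    structure(list(t_start = 0, t_end = dur, duration = dur, t = t,
                   y = amp * 0.5 * (1 - cos(2 * pi * t / dur))),
              class = "breathing_cycle")
  }
  f <- rip_features(mk(4, 1), prev_cycle = mk(2, 1), next_cycle = mk(4, 2))
  expect_equal(unname(f[["dur_ratio_prev"]]), 2)
  expect_equal(unname(f[["amp_ratio_next"]]), 0.5)
})
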