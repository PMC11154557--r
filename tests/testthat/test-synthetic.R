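test_that("protocol script follows the experiment layout", {
  for (seed in 1:5) {
    sc <- make_protocol_script(seed)
    acts <- sc[sc$level == "action", ]
    expect_equal(acts$label[1], "breath_calibration")
    expect_equal(acts$t_end[1] - acts$t_start[1], 20)
    expect_equal(acts$label,
                 c("breath_calibration", "eating", "random_arm", "still",
                   "reading_aloud", "still", "eating", "random_arm"))
    total <- max(sc$t_end)
    expect_gte(total, 15 * 60)
    expect_lte(total, 19 * 60)
    # micro-events stay inside their parent action
    for (i in which(sc$level == "micro")) {
      parent <- acts[acts$t_start <= sc$t_start[i] + 1e-9 &
                       acts$t_end >= sc$t_end[i] - 1e-9, ]
      expect_gte(nrow(parent), 1)
    }
  }
})

test_that("a ~5 min spoon course yields 12-18 eating gestures", {
  for (seed in 1:5) {
    sc <- make_protocol_script(seed)
    spoon <- sc[sc$level == "action" & sc$label == "eating" &
                  sc$detail == "spoon", ]
    g <- sc[sc$label == "eating_gesture" & sc$t_start >= spoon$t_start &
              sc$t_end <= spoon$t_end, ]
    expect_gte(nrow(g), 12)
    expect_lte(nrow(g), 18)
  }
})

test_that("script and rendering are deterministic in the seed", {
  expect_identical(make_protocol_script(3), make_protocol_script(3))
  s1 <- make_protocol_script(0); s2 <- make_protocol_script(1)
  expect_false(identical(s1$t_start[s1$level == "micro"],
                         s2$t_start[s2$level == "micro"]))
  a <- test_session(seed = 9)
  b <- test_session(seed = 9)
  expect_identical(a, b)
  c_ <- test_session(seed = 10)
  expect_false(identical(a$streams$piezo$channels$v,
                         c_$streams$piezo$channels$v))
})

test_that("sample counts match duration times nominal rate", {
  sc <- make_test_script()
  sc <- sc[sc$t_end <= 60 | sc$t_start < 60, ]
  sc$t_end <- pmin(sc$t_end, 60)
  sc <- sc[sc$t_end > sc$t_start, ]
  sess <- synthesize_session(sc, generator_config(), seed = 1)
  expect_equal(length(sess$streams$imu$timestamps), 60 * 83)
  expect_equal(length(sess$streams$piezo$timestamps), 60 * 204)
  expect_lte(abs(length(sess$streams$rip$timestamps) - 60 * 6.2), 1)
})

test_that("noise-free, event-free piezo reduces to its smooth drift term", {
  cfg <- noiseless_config()
  sc <- data.frame(label = c("breath_calibration", "still"),
                   t_start = c(0, 20), t_end = c(20, 80),
                   level = "action", detail = "", stringsAsFactors = FALSE)
  sess <- synthesize_session(sc, cfg, seed = 4)
  v <- sess$streams$piezo$channels$v
  # drift only: no oscillatory content, curvature numerically negligible
  expect_lt(max(abs(diff(v, differences = 2))), 1e-6)
  detr <- v - cfg$piezo_drift_slope * sess$streams$piezo$timestamps
  # remaining term is the baseline sinusoid of amplitude 0.3
  expect_lte(max(detr) - min(detr), 0.6 + 1e-9)
})

test_that("chew bursts carry the configured fundamental (DFT oracle)", {
  sess <- cached_clean_session()
  cfg <- noiseless_config()
  chews <- sess$annotations[sess$annotations$label == "chewing", ]
  t <- sess$streams$piezo$timestamps
  for (i in seq_len(nrow(chews))) {
    sel <- t >= chews$t_start[i] + 1 & t <= chews$t_end[i] - 1
    x <- sess$streams$piezo$channels$v[sel]
    n <- length(x)
    sp <- Mod(stats::fft(x - mean(x)))^2
    freqs <- (seq_len(n) - 1) * 204 / n
    half <- 2:floor(n / 2)
    dom <- freqs[half][which.max(sp[half])]
    expect_lt(abs(dom - cfg$chew_hz) / cfg$chew_hz, 0.10)
  }
})

test_that("every annotated swallow sits inside one clean breathing cycle", {
  sess <- cached_clean_session()
  calib <- sess$annotations[sess$annotations$label == "breath_calibration", ]
  bundle <- scale_rip_to_lung_volume(sess$streams$rip,
                                     c(calib$t_start, calib$t_end))
  cycles <- segment_breathing_cycles(bundle)
  expect_gt(length(cycles), 10)
  spans <- data.frame(t0 = vapply(cycles, `[[`, numeric(1), "t_start"),
                      t1 = vapply(cycles, `[[`, numeric(1), "t_end"))
  sw <- sess$annotations[sess$annotations$label == "swallowing", ]
  for (i in seq_len(nrow(sw))) {
    containing <- sum(spans$t0 <= sw$t_start[i] & spans$t1 >= sw$t_end[i])
    expect_equal(containing, 1)
  }
})

test_that("event and non-event windows are separable by >= 1 pooled SD", {
  sf <- cached_features()
  pooled_sep <- function(F, y) {
    if (length(unique(y)) < 2) return(0)
    m1 <- colMeans(F[y == 1, , drop = FALSE])
    m0 <- colMeans(F[y == 0, , drop = FALSE])
    s1 <- apply(F[y == 1, , drop = FALSE], 2, stats::sd)
    s0 <- apply(F[y == 0, , drop = FALSE], 2, stats::sd)
    sp <- sqrt((s1^2 + s0^2) / 2)
    ok <- is.finite(sp) & sp > 0
    max(abs(m1[ok] - m0[ok]) / sp[ok])
  }
  yg <- label_vectors(sf$imu$windows, sf$annotations, "eating_gesture")
  expect_gte(pooled_sep(sf$imu$features, yg), 1)
  yc <- label_vectors(sf$piezo$windows, sf$annotations, "chewing")
  expect_gte(pooled_sep(sf$piezo$features, yc), 1)
  ys <- label_vectors(sf$rip$windows, sf$annotations, "swallowing")
  expect_gte(pooled_sep(sf$rip$features, ys), 1)
})

test_that("degenerate generator inputs are rejected", {
  cfg <- generator_config()
  cfg$rates[["imu"]] <- -1
  expect_error(synthesize_session(make_test_script(), cfg, 1), "rates")
  expect_error(synthesize_session(make_test_script()[0, ],
                                  generator_config(), 1), "empty")
  expect_error(generator_config(breath_period_s = 0.5))
})
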