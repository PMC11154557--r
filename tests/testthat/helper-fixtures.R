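# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# A compact 140 s protocol: calibration, a short spoon course with three
# gesture/chew/swallow cycles, and a still block with scratches. Keeps
# per-test synthesis cheap while exercising every event family.
make_test_script <- function() {
  rows <- list(
    c("breath_calibration", 0, 20, "action", ""),
    c("eating", 20, 90, "action", "spoon"),
    c("eating_gesture", 22, 25, "micro", "spoon"),
    c("chewing", 25.5, 39, "micro", ""),
    c("swallowing", 38, 38.6, "micro", ""),
    c("eating_gesture", 44, 47, "micro", "spoon"),
    c("chewing", 47.5, 61, "micro", ""),
    c("swallowing", 60, 60.6, "micro", ""),
    c("eating_gesture", 66, 68, "micro", "hand"),
    c("chewing", 68.5, 84, "micro", ""),
    c("swallowing", 82.5, 83.1, "micro", ""),
    c("still", 90, 130, "action", ""),
    c("scratch_head", 95, 96.5, "micro", ""),
    c("scratch_head", 105, 106.5, "micro", ""),
    c("scratch_head", 115, 116.5, "micro", ""),
    c("swallowing", 110, 110.6, "micro", ""),
    c("random_arm", 130, 140, "action", ""))
  script <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r[1], t_start = as.numeric(r[2]),
               t_end = as.numeric(r[3]), level = r[4], detail = r[5],
               stringsAsFactors = FALSE)
  }))
  class(script) <- c("event_script", "data.frame")
  script
}

test_session <- function(seed = 42, config = generator_config()) {
  synthesize_session(make_test_script(), config, seed = seed,
                     subject_id = "testsubj")
}

cached_session <- function() fixture("session", function() test_session())

cached_features <- function() {
  fixture("features", function() session_features(cached_session()))
}

# noise-free variant for oracle-style spectral / cycle checks
noiseless_config <- function() {
  cfg <- generator_config()
  cfg$noise_sd[] <- 0
  cfg
}

cached_clean_session <- function() {
  fixture("clean_session", function() test_session(config = noiseless_config()))
}

# a bare single-channel piezo stream from a numeric vector
piezo_stream <- function(x, rate = 204) {
  sensor_stream("piezo", (seq_along(x) - 1) / rate, list(v = x), rate)
}

rip_stream <- function(abdomen, ribs, rate = 6.2) {
  sensor_stream("rip", (seq_along(abdomen) - 1) / rate,
                list(abdomen = abdomen, ribs = ribs), rate)
}

imu_stream_from <- function(n, rate = 83, fill = 0) {
  chn <- c("ax", "ay", "az", "gx", "gy", "gz")
  ch <- stats::setNames(rep(list(rep(fill, n)), length(chn)), chn)
  sensor_stream("imu", (seq_len(n) - 1) / rate, ch, rate)
}
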