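# Window segmentation: fixed-duration tiling for IMU (1 s) and piezo (3 s),
# and variable-length breathing cycles for RIP, split at inhalation minima.

default_segmentation_config <- function() {
  list(imu_window_s = 1,
       piezo_window_s = 3,
       min_prominence = 0.1,   # scaled lung-volume units
       min_separation_s = 1.5,
       min_cycle_s = 1.5)
}

#' Tile a format bundle into fixed-duration windows
#'
#' Produces consecutive, non-overlapping windows of `window_s` seconds
#' starting at t = 0. A trailing partial window shorter than `window_s` is
#' discarded, so every window carries the same nominal duration and the
#' per-window feature contract holds. All variants of a bundle share
#' timestamps, so the tiling is variant-independent.
#'
#' @param bundle A `format_bundle` (or a single [sensor_stream()]).
#' @param window_s Window duration in seconds (> 0).
#' @return Data.frame with columns `index`, `t_start`, `t_end`, `midpoint`,
#'   `i_start`, `i_end` (1-based sample index range, inclusive).
#' @export
fixed_windows <- function(bundle, window_s) {
  stopifnot(window_s > 0)
  stream <- if (inherits(bundle, "format_bundle")) {
    bundle$variants[[1]]
  } else {
    bundle
  }
  n <- length(stream$timestamps)
  empty <- data.frame(index = integer(0), t_start = numeric(0),
                      t_end = numeric(0), midpoint = numeric(0),
                      i_start = integer(0), i_end = integer(0))
  if (n == 0) return(empty)
  duration <- n / stream$nominal_rate
  n_win <- floor(duration / window_s + 1e-9)
  if (n_win < 1) return(empty)
  t_start <- (seq_len(n_win) - 1) * window_s
  t_end <- t_start + window_s
  # half-open sample assignment [t_start, t_end)
  i_start <- findInterval(t_start - 1e-12, stream$timestamps) + 1L
  i_end <- findInterval(t_end - 1e-12, stream$timestamps)
  data.frame(index = seq_len(n_win), t_start = t_start, t_end = t_end,
             midpoint = (t_start + t_end) / 2,
             i_start = i_start, i_end = i_end)
}

# Local minima with topographic prominence: a minimum's prominence is how
# far the signal must rise (on the lower of its two sides) before reaching
# a deeper minimum or the record edge.
find_minima <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] <= 0 & d[-1] > 0 & (d[-length(d)] < 0)) + 1L
  cand <- cand[x[cand - 1L] > x[cand] & x[cand + 1L] > x[cand]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    v <- x[i]
    # walk left: highest point before hitting a value below v (or the edge)
    left <- if (i == 1L) Inf else {
      xs <- x[seq_len(i - 1L)]
      below <- which(xs < v)
      if (length(below)) max(xs[(max(below) + 1L):(i - 1L)], -Inf)
      else max(xs)
    }
    right <- if (i == n) Inf else {
      xs <- x[(i + 1L):n]
      below <- which(xs < v)
      if (length(below)) max(xs[seq_len(min(below) - 1L)], -Inf)
      else max(xs)
    }
    min(left, right) - v
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  ord <- keep[order(x[keep])]
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(chosen - i) >= min_separation)) {
      chosen <- c(chosen, i)
    }
  }
  sort(chosen)
}

#' Split scaled RIP volume into breathing cycles
#'
#' Detects inhalation minima in the scaled, de-meaned lung-volume signal and
#' returns the segments between successive minima. Minima must reach a
#' minimum topographic prominence (default 0.1 scaled units) and be at least
#' `min_separation_s` apart (default 1.5 s); cycles shorter than
#' `min_cycle_s` are dropped.
#'
#' @param scaled_rip The RIP `format_bundle` from
#'   [scale_rip_to_lung_volume()], or its volume stream.
#' @param params Segmentation configuration list.
#' @return List of `breathing_cycle` objects, each with `t_start`, `t_end`,
#'   `duration`, `t` (sample times) and `y` (scaled volume, boundary minima
#'   included at both ends), plus the normalized form from
#'   [normalize_cycle()] as `norm`.
#' @export
segment_breathing_cycles <- function(scaled_rip,
                                     params = default_segmentation_config()) {
  stream <- if (inherits(scaled_rip, "format_bundle")) {
    scaled_rip$variants$volume_scaled_demeaned
  } else {
    scaled_rip
  }
  x <- stream$channels[[1]]
  tt <- stream$timestamps
  rate <- stream$nominal_rate
  mins <- find_minima(x, params$min_prominence,
                      round(params$min_separation_s * rate))
  if (length(mins) < 2) return(list())
  cycles <- list()
  for (k in seq_len(length(mins) - 1L)) {
    i0 <- mins[k]; i1 <- mins[k + 1L]
    dur <- tt[i1] - tt[i0]
    if (dur < params$min_cycle_s) next
    cyc <- structure(list(t_start = tt[i0], t_end = tt[i1], duration = dur,
                          t = tt[i0:i1], y = x[i0:i1],
                          i_start = i0, i_end = i1),
                     class = "breathing_cycle")
    cyc$norm <- tryCatch(normalize_cycle(cyc), error = function(e) NULL)
    if (is.null(cyc$norm)) next
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Normalize a breathing cycle in time and amplitude
#'
#' Maps the cycle's time axis affinely to \[0, 1\], subtracts the linear
#' baseline through the two endpoint values so that y(0) = 0 and y(1) = 0,
#' and divides by the maximum so the peak reaches 1. Applying the transform
#' to an already-normalized cycle reproduces it unchanged.
#'
#' @param cycle A `breathing_cycle` (needs `t` and `y`), or any list with
#'   numeric `t` and `y` of equal length >= 4.
#' @return List with `t` in \[0, 1\] and `y` with y(0) = y(1) = 0,
#'   max(y) = 1.
#' @export
normalize_cycle <- function(cycle) {
  t <- cycle$t; y <- cycle$y
  if (length(t) < 4) stop("cycle needs >= 4 samples", call. = FALSE)
  if (max(y) - min(y) < 1e-12) {
    stop("degenerate cycle: constant amplitude", call. = FALSE)
  }
  u <- (t - t[1]) / (t[length(t)] - t[1])
  base <- y[1] + (y[length(y)] - y[1]) * u
  z <- y - base
  m <- max(z)
  if (m < 1e-12) {
    stop("degenerate cycle: no positive excursion above baseline",
         call. = FALSE)
  }
  list(t = u, y = z / m)
}
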