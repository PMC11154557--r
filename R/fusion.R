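# Cross-sensor fusion: link windows across modalities by nearest midpoint,
# add past/future context windows, and concatenate their feature rows into
# fixed-length vectors.

SENSOR_CODES <- c(S = "imu", P = "piezo", R = "rip")
MEASURE_ANCHOR <- c(eating_gesture = "S", chewing = "P", swallowing = "R")

#' The eleven past/future context configurations
#'
#' Seconds of past and future data whose windows' features are appended to
#' each feature vector: 0-0, 0-3, 3-0, 3-3, 0-7, 7-0, 7-7, 0-10, 10-0,
#' 10-10, and 13-13.
#'
#' @return Data.frame with columns `past_s`, `future_s`.
#' @export
context_configurations <- function() {
  data.frame(past_s = c(0, 0, 3, 3, 0, 7, 7, 0, 10, 10, 13),
             future_s = c(0, 3, 0, 3, 7, 0, 7, 10, 0, 10, 13))
}

#' Sensor combinations per sensing measure
#'
#' Each measure's own sensor is always included (S for eating gestures, P
#' for chewing, R for swallowing), giving four combinations per measure.
#'
#' @param measure One of `"eating_gesture"`, `"chewing"`, `"swallowing"`.
#' @return Character vector of combinations, e.g. `"S", "SP", "SR", "SPR"`.
#' @export
sensor_combinations <- function(measure) {
  own <- MEASURE_ANCHOR[[match.arg(measure, names(MEASURE_ANCHOR))]]
  others <- setdiff(names(SENSOR_CODES), own)
  combos <- c(own,
              paste0(sort(c(own, others[1])), collapse = ""),
              paste0(sort(c(own, others[2])), collapse = ""),
              paste0(sort(names(SENSOR_CODES)), collapse = ""))
  # canonical S-P-R ordering within each combination
  vapply(combos, function(cb) {
    paste0(intersect(c("S", "P", "R"), strsplit(cb, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Nominal window durations used for context counting
#'
#' 1 s IMU windows, 3 s piezo windows, and the 3.6 s average breathing-cycle
#' duration standing in for the variable-length RIP windows.
#'
#' @return Named numeric vector (seconds).
#' @export
nominal_durations <- function() c(S = 1, P = 3, R = 3.6)

#' Number of context windows on one side
#'
#' Converts seconds of context into a per-side window count for a modality
#' with the given nominal window duration, rounding half away from zero.
#' This reproduces the 3 s-3 s worked layout: 3 one-second IMU windows, one
#' 3 s piezo window, and one (3 / 3.6 rounded) RIP cycle per side, for 13
#' windows in total across the three sensors.
#'
#' @param context_s Seconds of context (>= 0).
#' @param nominal_duration_s Nominal window duration (> 0).
#' @return Integer count per side.
#' @export
context_window_count <- function(context_s, nominal_duration_s) {
  stopifnot(context_s >= 0, nominal_duration_s > 0)
  as.integer(floor(context_s / nominal_duration_s + 0.5))
}

#' Link an anchor midpoint to the nearest candidate midpoint
#'
#' For each anchor midpoint, returns the index of the candidate whose
#' midpoint minimizes the absolute time difference; ties break toward the
#' earlier candidate.
#'
#' @param anchor_mid Numeric vector of anchor midpoints (seconds).
#' @param candidate_mid Sorted numeric vector of candidate midpoints.
#' @return Integer vector of candidate indices (NA if no candidates).
#' @export
link_nearest <- function(anchor_mid, candidate_mid) {
  m <- length(candidate_mid)
  if (m == 0) return(rep(NA_integer_, length(anchor_mid)))
  lo <- findInterval(anchor_mid, candidate_mid)
  lo_c <- pmin(pmax(lo, 1L), m)
  hi_c <- pmin(lo + 1L, m)
  d_lo <- abs(anchor_mid - candidate_mid[lo_c])
  d_hi <- abs(anchor_mid - candidate_mid[hi_c])
  use_lo <- lo >= 1L & (d_lo <= d_hi | hi_c == lo_c)
  out <- ifelse(use_lo, lo_c, hi_c)
  as.integer(out)
}

#' Assemble fused feature vectors for one session
#'
#' One vector per anchor window of the measure's own modality. For every
#' other included sensor the window with the nearest midpoint is linked;
#' past/future context windows are taken by index adjacency within each
#' modality's own window sequence, with per-side counts from
#' [context_window_count()]. Anchors whose full context extends beyond the
#' recording are excluded, so all vectors share one length. Feature rows are
#' concatenated in modality order S, P, R and in ascending time within each
#' modality.
#'
#' @param sf A [session_features()] object.
#' @param measure Sensing measure (decides the anchor modality).
#' @param sensors Sensor combination string, e.g. `"SPR"`; must contain the
#'   measure's own sensor.
#' @param past_s,future_s Seconds of past and future context.
#' @return List with `X` (matrix of vectors), `anchors` (data.frame of
#'   anchor extents and midpoints), and metadata (`measure`, `sensors`,
#'   `past_s`, `future_s`, `n_windows` per vector, `registry_id`).
#' @export
assemble_vectors <- function(sf, measure, sensors = "SPR",
                             past_s = 3, future_s = 3) {
  measure <- match.arg(measure, names(MEASURE_ANCHOR))
  own <- MEASURE_ANCHOR[[measure]]
  codes <- strsplit(sensors, "")[[1]]
  if (!all(codes %in% names(SENSOR_CODES))) {
    stop(sprintf("unknown sensor code in '%s'", sensors), call. = FALSE)
  }
  if (!(own %in% codes)) {
    stop(sprintf("combination '%s' must include the measure's own sensor %s",
                 sensors, own), call. = FALSE)
  }
  codes <- intersect(c("S", "P", "R"), codes)   # canonical order
  noms <- nominal_durations()
  counts <- lapply(stats::setNames(codes, codes), function(cd) {
    c(before = context_window_count(past_s, noms[[cd]]),
      after = context_window_count(future_s, noms[[cd]]))
  })
  mods <- SENSOR_CODES[codes]
  tabs <- lapply(mods, function(m) sf[[m]])
  names(tabs) <- codes

  anchors <- tabs[[own]]$windows
  if (!nrow(anchors)) {
    warning("no anchor windows for measure ", measure)
    return(empty_vector_set(measure, sensors, past_s, future_s, sf))
  }
  linked <- lapply(stats::setNames(codes, codes), function(cd) {
    if (cd == own) return(anchors$index)
    mids <- tabs[[cd]]$windows$midpoint
    link_nearest(anchors$midpoint, mids)
  })
  keep <- rep(TRUE, nrow(anchors))
  idx_block <- list()
  for (cd in codes) {
    n_m <- nrow(tabs[[cd]]$windows)
    ctr <- linked[[cd]]
    lo <- ctr - counts[[cd]][["before"]]
    hi <- ctr + counts[[cd]][["after"]]
    keep <- keep & !is.na(ctr) & lo >= 1L & hi <= n_m
    idx_block[[cd]] <- cbind(lo, hi)
  }
  if (!any(keep)) {
    warning("every anchor excluded by context boundaries for measure ",
            measure)
    return(empty_vector_set(measure, sensors, past_s, future_s, sf))
  }
  rows_per <- vapply(codes, function(cd)
    counts[[cd]][["before"]] + counts[[cd]][["after"]] + 1L, integer(1))
  reg_sizes <- vapply(codes, function(cd)
    ncol(tabs[[cd]]$features), integer(1))
  vec_len <- sum(rows_per * reg_sizes)

  kept <- which(keep)
  X <- matrix(NA_real_, length(kept), vec_len)
  col_names <- unlist(lapply(seq_along(codes), function(j) {
    cd <- codes[j]
    offs <- seq(-counts[[cd]][["before"]], counts[[cd]][["after"]])
    unlist(lapply(offs, function(o)
      sprintf("%s[%+d].%s", cd, o, colnames(tabs[[cd]]$features))))
  }))
  colnames(X) <- col_names
  for (r in seq_along(kept)) {
    i <- kept[r]
    parts <- lapply(codes, function(cd) {
      rng <- idx_block[[cd]][i, 1]:idx_block[[cd]][i, 2]
      as.numeric(t(tabs[[cd]]$features[rng, , drop = FALSE]))
    })
    X[r, ] <- unlist(parts)
  }
  list(X = X,
       anchors = anchors[kept, c("index", "t_start", "t_end", "midpoint")],
       measure = measure, sensors = paste0(codes, collapse = ""),
       past_s = past_s, future_s = future_s,
       n_windows = sum(rows_per), registry_id = sf$registry_id,
       subject_id = sf$subject_id)
}

empty_vector_set <- function(measure, sensors, past_s, future_s, sf) {
  list(X = matrix(numeric(0), 0, 0),
       anchors = data.frame(index = integer(0), t_start = numeric(0),
                            t_end = numeric(0), midpoint = numeric(0)),
       measure = measure, sensors = sensors, past_s = past_s,
       future_s = future_s, n_windows = 0L, registry_id = sf$registry_id,
       subject_id = sf$subject_id)
}
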