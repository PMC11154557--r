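#' @keywords internal
"_PACKAGE"

# Channel layout per modality; order is the on-disk column order.
MODALITIES <- c("imu", "piezo", "rip")

MODALITY_CHANNELS <- list(
  imu   = c("ax", "ay", "az", "gx", "gy", "gz"),
  piezo = "v",
  rip   = c("abdomen", "ribs")
)

#' Annotation label vocabulary
#'
#' The closed set of interval labels a session's ground-truth track may use:
#' the three sensing measures (`eating_gesture`, `chewing`, `swallowing`),
#' the protocol confounders (`scratch_head`, `random_arm`, `reading_aloud`,
#' `still`), and the lung-volume calibration action (`breath_calibration`).
#'
#' @return Character vector of valid labels.
#' @export
annotation_labels <- function() {
  c("eating_gesture", "chewing", "swallowing",
    "scratch_head", "random_arm", "reading_aloud",
    "still", "breath_calibration")
}

#' Construct a sensor stream
#'
#' A `sensor_stream` holds one modality's uniformly ordered, timestamped,
#' multichannel samples: wrist IMU (`ax,ay,az` in m/s^2, `gx,gy,gz` in rad/s,
#' nominally 83 Hz), jaw piezoelectric voltage (`v`, 204 Hz), or RIP belt
#' circumference (`abdomen`, `ribs`, 6.2 Hz, arbitrary units).
#'
#' @param modality One of `"imu"`, `"piezo"`, `"rip"`.
#' @param timestamps Numeric vector of strictly increasing session-relative
#'   times in seconds.
#' @param channels Named list (or data.frame) of numeric series, one per
#'   channel of the modality, each the same length as `timestamps`.
#' @param nominal_rate Nominal sampling rate in Hz (> 0).
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(modality, timestamps, channels, nominal_rate) {
  modality <- match.arg(modality, MODALITIES)
  channels <- lapply(as.list(channels), as.numeric)
  s <- structure(
    list(modality = modality,
         timestamps = as.numeric(timestamps),
         channels = channels,
         nominal_rate = as.numeric(nominal_rate)),
    class = "sensor_stream")
  validate_stream(s)
  s
}

validate_stream <- function(s) {
  expected <- MODALITY_CHANNELS[[s$modality]]
  if (!setequal(names(s$channels), expected)) {
    stop(sprintf("stream '%s' must have channels {%s}, got {%s}",
                 s$modality, paste(expected, collapse = ","),
                 paste(names(s$channels), collapse = ",")), call. = FALSE)
  }
  s$channels <- s$channels[expected]
  n <- length(s$timestamps)
  bad <- vapply(s$channels, function(ch) length(ch) != n, logical(1))
  if (any(bad)) {
    stop(sprintf("stream '%s': channel length mismatch with timestamps (%s)",
                 s$modality, paste(names(s$channels)[bad], collapse = ",")),
         call. = FALSE)
  }
  if (n > 1) {
    d <- diff(s$timestamps)
    if (any(d <= 0)) {
      stop(sprintf("stream '%s': timestamps not strictly increasing at row %d",
                   s$modality, which(d <= 0)[1] + 1L), call. = FALSE)
    }
  }
  if (!is.finite(s$nominal_rate) || s$nominal_rate <= 0) {
    stop(sprintf("stream '%s': nominal_rate must be > 0", s$modality),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream %s: %d samples, %.1f Hz nominal, %d channels>\n",
              x$modality, length(x$timestamps), x$nominal_rate,
              length(x$channels)))
  invisible(x)
}

n_samples <- function(stream) length(stream$timestamps)

#' Validate an annotation track
#'
#' An annotation track is a data.frame with columns `t_start`, `t_end`
#' (seconds, `t_start < t_end` per row) and `label` (from
#' [annotation_labels()]). Intervals of different labels may overlap: a chew
#' interval typically contains swallow intervals.
#'
#' @param ann Data.frame with columns `t_start`, `t_end`, `label`.
#' @return The validated data.frame (invisibly usable), with `label` as
#'   character.
#' @export
annotation_track <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  need <- c("t_start", "t_end", "label")
  if (!all(need %in% names(ann))) {
    stop("annotations need columns t_start, t_end, label", call. = FALSE)
  }
  ann <- ann[, need]
  ann$t_start <- as.numeric(ann$t_start)
  ann$t_end <- as.numeric(ann$t_end)
  ann$label <- as.character(ann$label)
  if (nrow(ann)) {
    bad <- which(!(ann$t_start < ann$t_end))
    if (length(bad)) {
      stop(sprintf("annotation row %d: t_end must exceed t_start", bad[1]),
           call. = FALSE)
    }
    unknown <- setdiff(unique(ann$label), annotation_labels())
    if (length(unknown)) {
      stop(sprintf("unknown annotation label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  ann
}

#' Construct a recording session
#'
#' Bundles one stream per modality with a ground-truth annotation track.
#' Timestamps are session-relative; every stream's last timestamp must not
#' exceed `duration`.
#'
#' @param subject_id Subject identifier string.
#' @param streams Named list with elements `imu`, `piezo`, `rip`, each a
#'   [sensor_stream()].
#' @param annotations Annotation data.frame (see [annotation_track()]).
#' @param duration Session duration in seconds; defaults to the latest
#'   timestamp across streams.
#' @return An object of class `adm_session`.
#' @export
session <- function(subject_id, streams, annotations, duration = NULL) {
  if (!all(MODALITIES %in% names(streams))) {
    stop(sprintf("missing modality: %s",
                 paste(setdiff(MODALITIES, names(streams)), collapse = ", ")),
         call. = FALSE)
  }
  streams <- streams[MODALITIES]
  for (s in streams) validate_stream(s)
  annotations <- annotation_track(annotations)
  last_t <- max(vapply(streams, function(s)
    if (n_samples(s)) max(s$timestamps) else 0, numeric(1)))
  if (is.null(duration)) duration <- last_t
  if (last_t > duration + 1e-9) {
    stop("stream timestamps exceed session duration", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), streams = streams,
         annotations = annotations, duration = as.numeric(duration)),
    class = "adm_session")
}

#' @export
print.adm_session <- function(x, ...) {
  cat(sprintf("<adm_session '%s': %.1f s, %d annotations>\n",
              x$subject_id, x$duration, nrow(x$annotations)))
  for (s in x$streams) print(s)
  invisible(x)
}

stream_filename <- function(modality) paste0(modality, ".csv")

#' Write a session to a directory of CSV files
#'
#' Writes one CSV per modality (`imu.csv`, `piezo.csv`, `rip.csv`; first
#' column `t`, remaining columns the modality's channels) plus
#' `annotations.csv` (`t_start,t_end,label`). Numeric values are serialized
#' with 15 significant digits, so a read/write round trip agrees to well
#' below 1e-9.
#'
#' @param sess An [session()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(sess, dir) {
  stopifnot(inherits(sess, "adm_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  paths <- character(0)
  for (m in MODALITIES) {
    s <- sess$streams[[m]]
    df <- data.frame(t = s$timestamps)
    for (ch in names(s$channels)) df[[ch]] <- s$channels[[ch]]
    p <- file.path(dir, stream_filename(m))
    write_csv15(df, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "annotations.csv")
  write_csv15(sess$annotations, p)
  invisible(c(paths, p))
}

write_csv15 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- sprintf("%.15g", out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a session from a directory of CSV files
#'
#' Inverse of [write_session()]. Expects exactly four files: `imu.csv`,
#' `piezo.csv`, `rip.csv`, and `annotations.csv`. Nominal rates are not
#' stored on disk and default to the hardware rates (83 / 204 / 6.2 Hz);
#' the session duration is taken from the latest timestamp. Timestamps are
#' re-based so the earliest sample across streams is 0; annotation times
#' are shifted by the same offset.
#'
#' @param dir Directory containing the session files.
#' @param rates Named nominal sampling rates (Hz) for `imu`, `piezo`, `rip`.
#' @param subject_id Subject identifier; defaults to the directory name.
#' @return An [session()] object.
#' @export
read_session <- function(dir, rates = c(imu = 83, piezo = 204, rip = 6.2),
                         subject_id = basename(dir)) {
  if (!dir.exists(dir)) stop(sprintf("no such session directory '%s'", dir))
  for (m in MODALITIES) {
    if (!file.exists(file.path(dir, stream_filename(m)))) {
      stop(sprintf("missing modality: %s (expected %s)", m,
                   stream_filename(m)), call. = FALSE)
    }
  }
  if (!file.exists(file.path(dir, "annotations.csv"))) {
    stop("missing annotation file annotations.csv", call. = FALSE)
  }
  streams <- list()
  for (m in MODALITIES) {
    df <- utils::read.csv(file.path(dir, stream_filename(m)),
                          stringsAsFactors = FALSE)
    if (names(df)[1] != "t") {
      stop(sprintf("%s: first column must be the timestamp column 't'",
                   stream_filename(m)), call. = FALSE)
    }
    tt <- as.numeric(df$t)
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      stop(sprintf("%s: timestamps not strictly increasing at row %d",
                   stream_filename(m), which(diff(tt) <= 0)[1] + 1L),
           call. = FALSE)
    }
    streams[[m]] <- sensor_stream(m, tt, df[MODALITY_CHANNELS[[m]]],
                                  rates[[m]])
  }
  ann_raw <- utils::read.csv(file.path(dir, "annotations.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c("numeric", "numeric", "character"))
  ann <- annotation_track(ann_raw)
  # re-base so the earliest sample across streams sits at t = 0
  t0 <- min(vapply(streams, function(s)
    if (n_samples(s)) s$timestamps[1] else Inf, numeric(1)))
  if (is.finite(t0) && t0 != 0) {
    for (m in MODALITIES) {
      streams[[m]]$timestamps <- streams[[m]]$timestamps - t0
    }
    ann$t_start <- ann$t_start - t0
    ann$t_end <- ann$t_end - t0
  }
  session(subject_id, streams, ann)
}
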