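#' Windowing configuration
#'
#' Controls the overlapping-window segmentation and how windows inherit binary
#' apnea labels from the annotations. Defaults follow the 11 s window / 10 s
#' overlap processing scheme.
#'
#' @param window_s Window length in seconds (default 11).
#' @param overlap_s Overlap between consecutive windows in seconds (default 10);
#'   must satisfy `0 <= overlap_s < window_s`.
#' @param label_rule For interval annotations: `"MIN_OVERLAP_FRACTION"` labels a
#'   window apneic when at least `min_overlap` of it lies inside an event;
#'   `"CENTER_IN_EVENT"` labels by the window's center time.
#' @param min_overlap Overlap fraction threshold in `[0, 1]` (default 0.5).
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(window_s = 11, overlap_s = 10,
                                label_rule = c("MIN_OVERLAP_FRACTION", "CENTER_IN_EVENT"),
                                min_overlap = 0.5) {
  label_rule <- match.arg(label_rule)
  assert_scalar_num(window_s, "window_s", lower = 1e-9)
  assert_scalar_num(overlap_s, "overlap_s", lower = 0)
  if (overlap_s >= window_s) stop("overlap_s must be < window_s", call. = FALSE)
  assert_scalar_num(min_overlap, "min_overlap", 0, 1)
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 label_rule = label_rule, min_overlap = min_overlap),
            class = "segmentation_config")
}

#' Construct a window set
#'
#' Aligned fixed-length windows cut from one or more records, with binary apnea
#' labels and provenance. Rows of `windows` are windows; all rows share one
#' sampling rate and length.
#'
#' @param windows Numeric matrix, `n_windows x window_samples`.
#' @param labels Integer vector in `{0, 1}` (1 = apnea).
#' @param fs Sampling rate in Hz.
#' @param channel `"ECG"` or `"SPO2"`.
#' @param source_ids Character provenance per window.
#' @param start_times_s Window start times in seconds (strictly increasing per
#'   source).
#' @param window_s Window length in seconds.
#' @return A `window_set` object.
#' @export
window_set <- function(windows, labels, fs, channel, source_ids, start_times_s,
                       window_s) {
  stopifnot(is.matrix(windows))
  labels <- as.integer(labels)
  if (length(labels) != nrow(windows) || any(!labels %in% c(0L, 1L))) {
    stop("labels must be one 0/1 value per window", call. = FALSE)
  }
  if (length(source_ids) != nrow(windows) || length(start_times_s) != nrow(windows)) {
    stop("source_ids and start_times_s must have one entry per window", call. = FALSE)
  }
  for (s in unique(source_ids)) {
    st <- start_times_s[source_ids == s]
    if (length(st) > 1 && any(diff(st) <= 0)) {
      stop("start times must be strictly increasing within a source", call. = FALSE)
    }
  }
  structure(list(windows = windows, labels = labels, fs = fs, channel = channel,
                 source_ids = as.character(source_ids),
                 start_times_s = as.numeric(start_times_s), window_s = window_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %s: %d windows x %d samples @ %g Hz (%d apnea, %d normal)\n",
              x$channel, nrow(x$windows), ncol(x$windows), x$fs,
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

n_windows <- function(set) nrow(set$windows)

subset_windows <- function(set, idx) {
  window_set(set$windows[idx, , drop = FALSE], set$labels[idx], set$fs,
             set$channel, set$source_ids[idx], set$start_times_s[idx],
             set$window_s)
}

#' Segment a record into overlapping fixed-length windows
#'
#' Cuts `floor((duration - window_s) / stride) + 1` windows at stride
#' `window_s - overlap_s`; no window crosses the record end and trailing
#' partial windows are dropped. Labels are initialized to 0; use
#' [label_windows()] to assign them from annotations.
#'
#' @param record A [signal_record()].
#' @param cfg A [segmentation_config()].
#' @param source_id Provenance string attached to every window.
#' @return A [window_set()].
#' @export
segment_record <- function(record, cfg = segmentation_config(),
                           source_id = "record") {
  stopifnot(inherits(record, "signal_record"), inherits(cfg, "segmentation_config"))
  dur <- record_duration(record)
  if (dur + 1e-9 < cfg$window_s) {
    stop(sprintf("record is %.2f s long; at least %.2f s (one window) is required",
                 dur, cfg$window_s), call. = FALSE)
  }
  stride <- cfg$window_s - cfg$overlap_s
  n <- floor((dur - cfg$window_s) / stride + 1e-9) + 1L
  m <- round(cfg$window_s * record$fs)
  starts <- (seq_len(n) - 1) * stride
  start_idx <- round(starts * record$fs)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    W[i, ] <- record$samples[(start_idx[i] + 1L):(start_idx[i] + m)]
  }
  window_set(W, integer(n), record$fs, record$channel,
             rep(source_id, n), starts, cfg$window_s)
}

# Minute labels derived from event intervals: a minute is apneic if any event
# overlaps it (half-open minute bins).
minute_labels_from_events <- function(events, duration_s) {
  n_min <- ceiling(duration_s / 60 - 1e-9)
  labs <- integer(max(n_min, 1L))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      lo <- floor(events$onset_s[i] / 60) + 1L
      hi <- ceiling((events$onset_s[i] + events$duration_s[i]) / 60 - 1e-9)
      labs[lo:min(hi, length(labs))] <- 1L
    }
  }
  labs
}

#' Assign binary apnea labels to windows from annotations
#'
#' Under the `EVENT_INTERVALS` dialect, each window is compared against the
#' half-open event intervals using the configured rule. Under `MINUTE_LABELS`,
#' a window inherits the label of the minute containing its center time;
#' `events` may be either a 0/1 minute-label vector or an event table (which is
#' first converted to minute labels).
#'
#' @param set A [window_set()].
#' @param events Event data frame (`onset_s`, `duration_s`) or, for
#'   `MINUTE_LABELS`, optionally an integer 0/1 vector of per-minute labels.
#' @param dialect `"EVENT_INTERVALS"` or `"MINUTE_LABELS"`.
#' @param cfg A [segmentation_config()] supplying the label rule.
#' @return The window set with labels filled in.
#' @export
label_windows <- function(set, events, dialect = c("EVENT_INTERVALS", "MINUTE_LABELS"),
                          cfg = segmentation_config()) {
  stopifnot(inherits(set, "window_set"))
  if (!is.character(dialect) || !all(dialect %in% c("EVENT_INTERVALS", "MINUTE_LABELS"))) {
    stop("unknown annotation dialect", call. = FALSE)
  }
  dialect <- match.arg(dialect)
  starts <- set$start_times_s
  ends <- starts + set$window_s
  labels <- integer(n_windows(set))
  if (dialect == "EVENT_INTERVALS") {
    if (nrow(events)) {
      ev_lo <- events$onset_s
      ev_hi <- events$onset_s + events$duration_s
      for (i in seq_along(starts)) {
        if (cfg$label_rule == "CENTER_IN_EVENT") {
          ctr <- starts[i] + set$window_s / 2
          labels[i] <- as.integer(any(ctr >= ev_lo & ctr < ev_hi))
        } else {
          ov <- pmin(ends[i], ev_hi) - pmax(starts[i], ev_lo)
          labels[i] <- as.integer(sum(pmax(ov, 0)) >= cfg$min_overlap * set$window_s - 1e-9)
        }
      }
    }
  } else {
    mins <- if (is.data.frame(events)) {
      minute_labels_from_events(events, max(ends))
    } else as.integer(events)
    ctr_min <- floor((starts + set$window_s / 2) / 60) + 1L
    if (any(ctr_min > length(mins))) {
      stop("minute labels do not cover all window centers", call. = FALSE)
    }
    labels <- mins[ctr_min]
  }
  set$labels <- labels
  set
}

#' Segment and label a record in one call
#'
#' @inheritParams segment_record
#' @return A labeled [window_set()].
#' @export
ingest_record <- function(record, cfg = segmentation_config(),
                          source_id = "record") {
  set <- segment_record(record, cfg, source_id)
  label_windows(set, record$events, record$annotation_dialect, cfg)
}

#' Resample a signal record to a new rate
#'
#' Linear-interpolation resampler used to harmonize heterogeneous sources
#' (128 Hz ECG down to 100 Hz; 100 Hz SpO2 down to 8 Hz) so each model branch
#' sees one fixed input length.
#'
#' @param record A [signal_record()].
#' @param fs_out Target rate in Hz.
#' @return A [signal_record()] at `fs_out`.
#' @export
resample_record <- function(record, fs_out) {
  stopifnot(inherits(record, "signal_record"))
  assert_scalar_num(fs_out, "fs_out", lower = 1e-9)
  if (abs(fs_out - record$fs) < 1e-12) return(record)
  dur <- record_duration(record)
  t_in <- (seq_along(record$samples) - 1) / record$fs
  n_out <- round(dur * fs_out)
  t_out <- (seq_len(n_out) - 1) / fs_out
  y <- stats::approx(t_in, record$samples, xout = t_out, rule = 2)$y
  out <- record
  out$samples <- y
  out$fs <- fs_out
  out
}
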