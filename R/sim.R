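#' Simulation configuration for paired ECG/SpO2 recordings
#'
#' Describes the stated world of the synthetic generator: recording length,
#' per-channel sampling rates, the apnea event process, the programmed
#' physiological responses (RR-interval shortening in ECG, lagged oxygen
#' desaturation in SpO2), artifact contamination, and the noise floor.
#'
#' Apnea events last at least 10 s (the clinical apnea definition) and
#' desaturations are at least 4 percentage points deep (the hypopnea
#' criterion); both bounds are enforced.
#'
#' @param duration_s Recording duration in seconds.
#' @param fs_ecg ECG sampling rate in Hz (default 100, the Apnea-ECG rate).
#' @param fs_spo2 SpO2 sampling rate in Hz (default 8, the UCD rate).
#' @param apnea_event_rate Events per hour. 30/h corresponds to severe OSA and
#'   yields roughly a 80/20 normal/apnea window balance at the default window
#'   scheme.
#' @param event_duration_s Length-2 range (min, max) of event durations in
#'   seconds; min must be >= 10.
#' @param desat_depth_pct Desaturation depth in percentage points (>= 4).
#' @param desat_lag_s Lag between event onset and start of the SpO2 fall.
#' @param rr_baseline_s Baseline RR interval in seconds (1.0 s = 60 bpm).
#' @param rr_apnea_modulation Fractional RR shortening inside/just after an
#'   event (0.25 means heart rate rises by ~33%).
#' @param artifact_window_fraction Fraction of 11 s spans overwritten by
#'   motion-like artifact bursts (applied by [inject_artifacts()]).
#' @param noise_floor_sd Gaussian noise standard deviation added to the ECG, in
#'   signal units (QRS peak amplitude is 1).
#' @param spo2_baseline Mean SpO2 baseline in percent (96-98 physiological).
#' @param spo2_noise_sd SpO2 measurement noise standard deviation in
#'   percentage points.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(duration_s,
                       fs_ecg = 100,
                       fs_spo2 = 8,
                       apnea_event_rate = 30,
                       event_duration_s = c(10, 30),
                       desat_depth_pct = 4,
                       desat_lag_s = 5,
                       rr_baseline_s = 1.0,
                       rr_apnea_modulation = 0.25,
                       artifact_window_fraction = 0,
                       noise_floor_sd = 0.05,
                       spo2_baseline = 97,
                       spo2_noise_sd = 0.2,
                       seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(fs_ecg, "fs_ecg", lower = 1e-9)
  assert_scalar_num(fs_spo2, "fs_spo2", lower = 1e-9)
  assert_scalar_num(apnea_event_rate, "apnea_event_rate", lower = 0)
  if (!is.numeric(event_duration_s) || length(event_duration_s) != 2L ||
      any(is.na(event_duration_s)) || event_duration_s[1] > event_duration_s[2]) {
    stop("`event_duration_s` must be a (min, max) pair", call. = FALSE)
  }
  if (event_duration_s[1] < 10) {
    stop("event_duration_s minimum must be >= 10 s (apnea is a cessation of breathing for at least 10 s)",
         call. = FALSE)
  }
  if (desat_depth_pct < 4) {
    stop("desat_depth_pct must be >= 4 (hypopnea-grade desaturation)", call. = FALSE)
  }
  assert_scalar_num(desat_lag_s, "desat_lag_s", lower = 0)
  assert_scalar_num(rr_baseline_s, "rr_baseline_s", lower = 1e-9)
  assert_scalar_num(rr_apnea_modulation, "rr_apnea_modulation", lower = 0, upper = 0.9)
  assert_scalar_num(artifact_window_fraction, "artifact_window_fraction", 0, 1)
  assert_scalar_num(noise_floor_sd, "noise_floor_sd", lower = 0)
  assert_scalar_num(spo2_baseline, "spo2_baseline", lower = 50, upper = 100)
  assert_scalar_num(spo2_noise_sd, "spo2_noise_sd", lower = 0)
  structure(list(
    duration_s = duration_s, fs_ecg = fs_ecg, fs_spo2 = fs_spo2,
    apnea_event_rate = apnea_event_rate, event_duration_s = event_duration_s,
    desat_depth_pct = desat_depth_pct, desat_lag_s = desat_lag_s,
    rr_baseline_s = rr_baseline_s, rr_apnea_modulation = rr_apnea_modulation,
    artifact_window_fraction = artifact_window_fraction,
    noise_floor_sd = noise_floor_sd, spo2_baseline = spo2_baseline,
    spo2_noise_sd = spo2_noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a single-channel signal record
#'
#' The basic container for one channel of a recording: the sample vector, its
#' sampling rate, the apnea event intervals (half-open `[onset, onset+duration)`
#' in seconds, sorted, non-overlapping) and the annotation dialect the events
#' were expressed in.
#'
#' @param samples Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param channel `"ECG"` or `"SPO2"`.
#' @param events Data frame with columns `onset_s`, `duration_s` (may have 0 rows).
#' @param annotation_dialect `"EVENT_INTERVALS"` or `"MINUTE_LABELS"`.
#' @return A `signal_record` object.
#' @export
signal_record <- function(samples, fs, channel = c("ECG", "SPO2"),
                          events = data.frame(onset_s = numeric(), duration_s = numeric()),
                          annotation_dialect = c("EVENT_INTERVALS", "MINUTE_LABELS")) {
  channel <- match.arg(channel)
  annotation_dialect <- match.arg(annotation_dialect)
  assert_scalar_num(fs, "fs", lower = 1e-9)
  if (!is.data.frame(events) || !all(c("onset_s", "duration_s") %in% names(events))) {
    stop("`events` must be a data frame with onset_s and duration_s", call. = FALSE)
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  dur <- length(samples) / fs
  if (nrow(events)) {
    if (any(events$duration_s <= 0)) stop("event durations must be positive", call. = FALSE)
    if (any(events$onset_s < 0) || any(events$onset_s + events$duration_s > dur + 1e-9)) {
      stop("events must lie within [0, duration]", call. = FALSE)
    }
    if (nrow(events) > 1) {
      ends <- events$onset_s + events$duration_s
      if (any(events$onset_s[-1] < ends[-nrow(events)] - 1e-9)) {
        stop("events must be non-overlapping", call. = FALSE)
      }
    }
  }
  if (channel == "SPO2" && length(samples) &&
      (min(samples) < 0 || max(samples) > 100)) {
    stop("SpO2 samples must lie in [0, 100]", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 events = events, annotation_dialect = annotation_dialect),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %s: %.1f s @ %g Hz, %d apnea event(s), dialect %s\n",
              x$channel, length(x$samples) / x$fs, x$fs, nrow(x$events),
              x$annotation_dialect))
  invisible(x)
}

record_duration <- function(record) length(record$samples) / record$fs

# Renewal-process event placement: exponential gaps at the requested hourly
# rate plus a refractory gap, durations uniform on the configured range.
draw_events <- function(config) {
  rate_s <- config$apnea_event_rate / 3600
  min_gap <- 15
  onsets <- numeric(0)
  durations <- numeric(0)
  t <- stats::rexp(1, rate_s)
  while (t + config$event_duration_s[1] + 1 < config$duration_s) {
    d <- stats::runif(1, config$event_duration_s[1], config$event_duration_s[2])
    d <- min(d, config$duration_s - t - 1)
    if (d >= config$event_duration_s[1]) {
      onsets <- c(onsets, t)
      durations <- c(durations, d)
      t <- t + d + min_gap + stats::rexp(1, rate_s)
    } else break
  }
  data.frame(onset_s = onsets, duration_s = durations)
}

# Gaussian-bump QRS template: amplitude 1, width sigma seconds.
qrs_template <- function(fs, sigma = 0.02) {
  half <- ceiling(4 * sigma * fs)
  u <- (-half:half) / fs
  exp(-0.5 * (u / sigma)^2)
}

simulate_ecg <- function(config, events) {
  fs <- config$fs_ecg
  n <- round(config$duration_s * fs)
  x <- numeric(n)
  # instantaneous RR: shortened inside each event and for 5 s after
  # (post-apneic sympathetic surge)
  in_surge <- function(t) {
    if (!nrow(events)) return(FALSE)
    any(t >= events$onset_s & t < events$onset_s + events$duration_s + 5)
  }
  tmpl <- qrs_template(fs)
  half <- (length(tmpl) - 1L) / 2L
  t <- stats::runif(1, 0, config$rr_baseline_s)
  while (t < config$duration_s) {
    idx <- round(t * fs) + 1L
    lo <- idx - half; hi <- idx + half
    src_lo <- max(1L, lo); src_hi <- min(n, hi)
    if (src_lo <= src_hi) {
      x[src_lo:src_hi] <- x[src_lo:src_hi] + tmpl[(src_lo - lo + 1L):(src_hi - lo + 1L)]
    }
    rr <- config$rr_baseline_s * (if (in_surge(t)) 1 - config$rr_apnea_modulation else 1)
    t <- t + rr * (1 + stats::rnorm(1, 0, 0.02))
  }
  x + stats::rnorm(n, 0, config$noise_floor_sd)
}

# Desaturation profile: linear fall over the first third of the event starting
# desat_lag_s after onset, plateau at full depth until event end + lag, then
# exponential recovery (tau = 4 s).
desat_profile <- function(t, onset, duration, depth, lag) {
  t0 <- onset + lag
  fall <- pmax(duration / 3, 1e-6)
  t1 <- t0 + fall
  t2 <- onset + duration + lag
  d <- numeric(length(t))
  rising <- t >= t0 & t < t1
  d[rising] <- depth * (t[rising] - t0) / fall
  d[t >= t1 & t < t2] <- depth
  rec <- t >= t2
  d[rec] <- depth * exp(-(t[rec] - t2) / 4)
  d
}

simulate_spo2 <- function(config, events) {
  fs <- config$fs_spo2
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  dip <- numeric(n)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      dip <- pmax(dip, desat_profile(t, events$onset_s[i], events$duration_s[i],
                                     config$desat_depth_pct, config$desat_lag_s))
    }
  }
  x <- config$spo2_baseline - dip + stats::rnorm(n, 0, config$spo2_noise_sd)
  pmin(100, pmax(0, x))
}

#' Simulate a paired ECG/SpO2 recording with programmed apnea events
#'
#' Generates one ECG record and one SpO2 record sharing a single ground-truth
#' apnea event list. The ECG is a Gaussian-bump QRS pulse train whose
#' instantaneous RR interval shrinks by `rr_apnea_modulation` inside and just
#' after each event; the SpO2 trace holds its baseline and dips by
#' `desat_depth_pct` starting `desat_lag_s` after each event onset, recovering
#' exponentially after the event. Output is bit-identical for a given seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `ecg` and `spo2`, both [signal_record()]s
#'   sharing the same event table.
#' @examples
#' pair <- simulate_pair(sim_config(duration_s = 120, apnea_event_rate = 30, seed = 7))
#' pair$ecg
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$apnea_event_rate > 0 &&
      config$duration_s < config$event_duration_s[1] + 2) {
    stop(sprintf(paste0("duration_s = %.1f s is too short to host one apnea event ",
                        "(needs at least %.1f s: minimum event duration %.1f s plus margin)"),
                 config$duration_s, config$event_duration_s[1] + 2,
                 config$event_duration_s[1]), call. = FALSE)
  }
  with_seed(config$seed, {
    events <- if (config$apnea_event_rate > 0) draw_events(config) else
      data.frame(onset_s = numeric(), duration_s = numeric())
    ecg <- simulate_ecg(config, events)
    spo2 <- simulate_spo2(config, events)
    list(
      ecg = signal_record(ecg, config$fs_ecg, "ECG", events, "EVENT_INTERVALS"),
      spo2 = signal_record(spo2, config$fs_spo2, "SPO2", events, "EVENT_INTERVALS")
    )
  })
}

#' Overwrite a fraction of 11 s spans with motion-artifact bursts
#'
#' Splits the record into consecutive non-overlapping 11 s spans, selects
#' `round(fraction * n_spans)` of them without replacement (seeded), and
#' overwrites each with a high-amplitude low-frequency swing plus wideband
#' noise, emulating electrode motion. The returned index list is exact ground
#' truth for quality-screening tests.
#'
#' @param record A [signal_record()].
#' @param fraction Fraction of spans to corrupt, in `[0, 1]`.
#' @param seed Integer seed.
#' @param span_s Span length in seconds (default 11, the processing window).
#' @return List with `record` (corrupted copy) and `corrupted` (sorted 1-based
#'   span indices).
#' @export
inject_artifacts <- function(record, fraction, seed = 1L, span_s = 11) {
  stopifnot(inherits(record, "signal_record"))
  assert_scalar_num(fraction, "fraction", 0, 1)
  n_spans <- floor(record_duration(record) / span_s)
  n_corrupt <- round(fraction * n_spans)
  if (n_corrupt == 0L) {
    return(list(record = record, corrupted = integer(0)))
  }
  with_seed(seed, {
    idx <- sort(sample.int(n_spans, n_corrupt))
    span_len <- round(span_s * record$fs)
    amp <- 8 * max(stats::sd(record$samples), 1e-6)
    samples <- record$samples
    for (k in idx) {
      lo <- (k - 1L) * span_len + 1L
      hi <- min(lo + span_len - 1L, length(samples))
      tt <- (seq(lo, hi) - lo) / record$fs
      burst <- amp * sin(2 * pi * 0.7 * tt + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(length(tt), 0, amp / 2)
      if (record$channel == "SPO2") burst <- pmin(100, pmax(0, 50 + burst))
      samples[lo:hi] <- burst
    }
    out <- record
    out$samples <- samples
    list(record = out, corrupted = idx)
  })
}
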