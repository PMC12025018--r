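test_that("segmentation counts follow the stride formula", {
  p <- fixture_pair(duration_s = 60, rate = 0, seed = 1)
  ws <- segment_record(p$ecg)  # 11 s window, 10 s overlap -> stride 1 s
  expect_identical(nrow(ws$windows), 50L)        # floor((60-11)/1) + 1
  expect_identical(ncol(ws$windows), 1100L)
  expect_equal(ws$start_times_s, 0:49)

  one <- simulate_pair(sim_config(11, apnea_event_rate = 0, seed = 1))
  expect_identical(nrow(segment_record(one$ecg)$windows), 1L)

  short <- simulate_pair(sim_config(10.5, apnea_event_rate = 0, seed = 1))
  expect_error(segment_record(short$ecg), "at least 11.00 s")
})

test_that("segmentation is exhaustive: windows reproduce the record prefix", {
  p <- fixture_pair(duration_s = 30, rate = 0, seed = 4)
  cfg <- segmentation_config(window_s = 5, overlap_s = 0)
  ws <- segment_record(p$ecg, cfg)
  reconstructed <- as.vector(t(ws$windows))
  m <- length(reconstructed)
  expect_identical(reconstructed, p$ecg$samples[seq_len(m)])
})

test_that("interval labeling follows the overlap and center rules", {
  events <- data.frame(onset_s = 30, duration_s = 15)  # [30, 45)
  mk <- function(starts) {
    window_set(matrix(0, length(starts), 88), integer(length(starts)), 8,
               "SPO2", rep("r", length(starts)), starts, 11)
  }
  # window [35, 46): overlap 10/11 >= 0.5 -> apnea
  ws <- label_windows(mk(35), events, "EVENT_INTERVALS",
                      segmentation_config(label_rule = "MIN_OVERLAP_FRACTION"))
  expect_identical(ws$labels, 1L)
  # window [44.5, 55.5): center 50 outside [30, 45) -> normal
  ws <- label_windows(mk(44.5), events, "EVENT_INTERVALS",
                      segmentation_config(label_rule = "CENTER_IN_EVENT"))
  expect_identical(ws$labels, 0L)
  # exactly half overlap counts as apnea (>= threshold)
  ws <- label_windows(mk(39.5), events, "EVENT_INTERVALS",
                      segmentation_config(label_rule = "MIN_OVERLAP_FRACTION"))
  expect_identical(ws$labels, 1L)
  # no events -> all normal
  ws <- label_windows(mk(c(0, 10, 20)),
                      data.frame(onset_s = numeric(), duration_s = numeric()),
                      "EVENT_INTERVALS", segmentation_config())
  expect_identical(ws$labels, c(0L, 0L, 0L))
  expect_error(label_windows(mk(0), events, "WEEKLY"), "dialect")
})

test_that("minute labeling assigns by the window's center minute", {
  events <- data.frame(onset_s = 60, duration_s = 60)  # minute 2 apneic
  mk <- function(starts) {
    window_set(matrix(0, length(starts), 88), integer(length(starts)), 8,
               "SPO2", rep("r", length(starts)), starts, 11)
  }
  ws <- label_windows(mk(c(40, 55, 80, 115, 120)), events, "MINUTE_LABELS")
  # centers: 45.5 (min 1), 60.5 (min 2), 85.5 (min 2), 120.5 (min 3), 125.5 (min 3)
  expect_identical(ws$labels, c(0L, 1L, 1L, 0L, 0L))
  # a plain 0/1 minute vector works too
  ws2 <- label_windows(mk(c(40, 55)), c(0L, 1L, 0L), "MINUTE_LABELS")
  expect_identical(ws2$labels, c(0L, 1L))
})

test_that("dialects agree when events align to whole minutes", {
  events <- data.frame(onset_s = c(60, 240), duration_s = c(60, 120))
  p <- simulate_pair(sim_config(420, apnea_event_rate = 0, seed = 9))
  rec <- signal_record(p$ecg$samples, p$ecg$fs, "ECG", events)
  ws <- segment_record(rec)
  li <- label_windows(ws, events, "EVENT_INTERVALS", segmentation_config())$labels
  lm <- label_windows(ws, events, "MINUTE_LABELS")$labels
  expect_identical(li, lm)
})

test_that("text records round-trip exactly", {
  p <- fixture_pair(duration_s = 90, seed = 12)
  path <- file.path(tempdir(), "rt_ecg.txt")
  write_record(p$ecg, path)
  back <- read_record(path, "TEXT")
  expect_identical(back$samples, p$ecg$samples)
  expect_identical(back$fs, p$ecg$fs)
  expect_identical(back$channel, p$ecg$channel)
  expect_equal(back$events, p$ecg$events)
  # minute-label dialect round-trips through its coarser representation
  recm <- p$spo2
  recm$annotation_dialect <- "MINUTE_LABELS"
  pm <- file.path(tempdir(), "rt_spo2.txt")
  write_record(recm, pm)
  backm <- read_record(pm, "TEXT")
  expect_identical(backm$samples, recm$samples)
  expect_identical(backm$annotation_dialect, "MINUTE_LABELS")
})

test_that("malformed inputs are rejected with located errors", {
  empty <- file.path(tempdir(), "empty.txt")
  file.create(empty)
  expect_error(read_record(empty), "empty")
  expect_error(read_record(file.path(tempdir(), "nope.txt")), "no such file")

  p <- fixture_pair(duration_s = 60, rate = 0, seed = 1)
  path <- file.path(tempdir(), "bad.txt")
  write_record(p$ecg, path)
  writeLines(c("5 x10"), paste0(path, ".ann"))
  expect_error(read_record(path), "line 1")
  writeLines(c("5 20", "10 20"), paste0(path, ".ann"))  # overlapping
  expect_error(read_record(path), "non-overlapping")
  # fs <= 0
  lines <- readLines(path)
  writeLines(sub("^#fs=.*", "#fs=0", lines), path)
  unlink(paste0(path, ".ann"))
  expect_error(read_record(path), "fs must be > 0")
})

test_that("minimal WFDB layout round-trips within gain quantization", {
  p <- fixture_pair(duration_s = 60, seed = 5)
  base <- write_record_wfdb(p$ecg, tempdir(), "w001", gain = 400)
  back <- read_record(base, "WFDB")
  expect_identical(back$fs, p$ecg$fs)
  expect_equal(back$events, p$ecg$events)
  expect_lt(max(abs(back$samples - p$ecg$samples)), 1 / 400)
})

test_that("resampling preserves duration and harmonizes rates", {
  p <- fixture_pair(duration_s = 60, rate = 0, seed = 6)
  r <- resample_record(p$ecg, 128)
  expect_identical(length(r$samples), 60L * 128L)
  back <- resample_record(r, 100)
  expect_identical(length(back$samples), length(p$ecg$samples))
  # slow SpO2-like content survives a 100 -> 8 Hz round trip closely
  t <- (0:5999) / 100
  slow <- signal_record(96 + sin(2 * pi * 0.05 * t), 100, "SPO2")
  down <- resample_record(slow, 8)
  expect_lt(max(abs(down$samples - (96 + sin(2 * pi * 0.05 * (0:479) / 8)))), 0.01)
})
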