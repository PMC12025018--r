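#' Write a signal record as delimited text with a sidecar annotation file
#'
#' The ground-truth interchange format: a header of `#key=value` lines
#' (`fs`, `channel`, `dialect`) followed by one sample per line, plus a
#' `<path>.ann` sidecar holding either `onset_s duration_s` pairs
#' (EVENT_INTERVALS) or one 0/1 minute label per line (MINUTE_LABELS).
#'
#' @param record A [signal_record()].
#' @param path Output file path for the sample file.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#fs=%.10g", record$fs),
               sprintf("#channel=%s", record$channel),
               sprintf("#dialect=%s", record$annotation_dialect)), con)
  writeLines(sprintf("%.17g", record$samples), con)
  ann <- paste0(path, ".ann")
  if (record$annotation_dialect == "EVENT_INTERVALS") {
    lines <- sprintf("%.10g %.10g", record$events$onset_s, record$events$duration_s)
  } else {
    lines <- as.character(minute_labels_from_events(record$events,
                                                    record_duration(record)))
  }
  writeLines(lines, ann)
  invisible(path)
}

parse_header_value <- function(lines, key, path) {
  pat <- paste0("^#", key, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) stop(sprintf("missing #%s= header in %s", key, path), call. = FALSE)
  sub(pat, "", hit[1])
}

#' Read a signal record written by [write_record()] or a minimal WFDB layout
#'
#' `TEXT` round-trips exactly with [write_record()]. `WFDB` reads the minimal
#' subset written by [write_record_wfdb()]: a `.hea` header, a format-16
#' little-endian `.dat` signal file with integer gain, and a `.events` text
#' annotation file (gain quantization makes WFDB round-trips approximate).
#'
#' @param path Sample file path (TEXT) or record base path without extension (WFDB).
#' @param format `"TEXT"` or `"WFDB"`.
#' @return A [signal_record()].
#' @export
read_record <- function(path, format = c("TEXT", "WFDB")) {
  format <- match.arg(format)
  if (format == "WFDB") return(read_record_wfdb(path))
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("empty record file: %s", path), call. = FALSE)
  fs <- as.numeric(parse_header_value(lines, "fs", path))
  if (is.na(fs) || fs <= 0) stop(sprintf("fs must be > 0 in %s", path), call. = FALSE)
  channel <- parse_header_value(lines, "channel", path)
  dialect <- parse_header_value(lines, "dialect", path)
  body <- lines[!startsWith(lines, "#")]
  samples <- suppressWarnings(as.numeric(body))
  if (!length(samples) || anyNA(samples)) {
    bad <- which(is.na(samples))[1] + sum(startsWith(lines, "#"))
    stop(sprintf("malformed sample at line %d of %s", bad, path), call. = FALSE)
  }
  ann_path <- paste0(path, ".ann")
  events <- data.frame(onset_s = numeric(), duration_s = numeric())
  if (file.exists(ann_path)) {
    ann <- readLines(ann_path)
    ann <- ann[nzchar(trimws(ann))]
    if (dialect == "EVENT_INTERVALS") {
      if (length(ann)) {
        parts <- strsplit(trimws(ann), "\\s+")
        for (i in seq_along(parts)) {
          v <- suppressWarnings(as.numeric(parts[[i]]))
          if (length(v) != 2L || anyNA(v)) {
            stop(sprintf("malformed annotation at line %d of %s", i, ann_path),
                 call. = FALSE)
          }
        }
        m <- do.call(rbind, lapply(parts, as.numeric))
        events <- data.frame(onset_s = m[, 1], duration_s = m[, 2])
      }
    } else {
      v <- suppressWarnings(as.integer(ann))
      if (anyNA(v) || any(!v %in% c(0L, 1L))) {
        bad <- which(is.na(v) | !v %in% c(0L, 1L))[1]
        stop(sprintf("malformed minute label at line %d of %s", bad, ann_path),
             call. = FALSE)
      }
      # minute labels carry no onsets; represent each apneic minute as an event
      runs <- rle(v)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths
      keep <- runs$values == 1L
      events <- data.frame(onset_s = starts[keep] * 60,
                           duration_s = runs$lengths[keep] * 60)
      dur <- length(samples) / fs
      events$duration_s <- pmin(events$duration_s, dur - events$onset_s)
      events <- events[events$duration_s > 0, , drop = FALSE]
    }
  }
  signal_record(samples, fs, channel, events, dialect)
}

#' Write a minimal WFDB-compatible record
#'
#' Single-signal format 16: `<name>.hea` header, `<name>.dat` 16-bit
#' little-endian samples at the stated gain, `<name>.events` text annotations
#' in the record's dialect. Intended for interop smoke tests; the text dialect
#' ([write_record()]) is the lossless ground-truth format.
#'
#' @param record A [signal_record()].
#' @param dir Output directory.
#' @param name Record name (file stem).
#' @param gain ADC units per physical unit (default 200).
#' @return The record base path (`file.path(dir, name)`), invisibly.
#' @export
write_record_wfdb <- function(record, dir, name, gain = 200) {
  stopifnot(inherits(record, "signal_record"))
  base <- file.path(dir, name)
  n <- length(record$samples)
  writeLines(c(sprintf("%s 1 %.10g %d", name, record$fs, n),
               sprintf("%s.dat 16 %g 16 0 0 0 0 %s", name, gain, record$channel)),
             paste0(base, ".hea"))
  adc <- as.integer(pmin(32767, pmax(-32768, round(record$samples * gain))))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(adc, con, size = 2L, endian = "little")
  close(con)
  if (record$annotation_dialect == "EVENT_INTERVALS") {
    lines <- sprintf("%.10g %.10g", record$events$onset_s, record$events$duration_s)
  } else {
    lines <- as.character(minute_labels_from_events(record$events,
                                                    record_duration(record)))
  }
  writeLines(c(sprintf("#dialect=%s", record$annotation_dialect), lines),
             paste0(base, ".events"))
  invisible(base)
}

read_record_wfdb <- function(base) {
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop(sprintf("no such header: %s", hea), call. = FALSE)
  lines <- readLines(hea)
  if (length(lines) < 2L) stop(sprintf("malformed header: %s", hea), call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (is.na(fs) || fs <= 0) stop(sprintf("fs must be > 0 in %s", hea), call. = FALSE)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain <- as.numeric(sig[3])
  channel <- sig[length(sig)]
  con <- file(paste0(base, ".dat"), "rb")
  adc <- readBin(con, "integer", n = n, size = 2L, endian = "little", signed = TRUE)
  close(con)
  ev_path <- paste0(base, ".events")
  dialect <- "EVENT_INTERVALS"
  events <- data.frame(onset_s = numeric(), duration_s = numeric())
  if (file.exists(ev_path)) {
    ann <- readLines(ev_path)
    d <- grep("^#dialect=", ann, value = TRUE)
    if (length(d)) dialect <- sub("^#dialect=", "", d[1])
    body <- ann[!startsWith(ann, "#") & nzchar(trimws(ann))]
    if (dialect == "EVENT_INTERVALS" && length(body)) {
      m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
      events <- data.frame(onset_s = m[, 1], duration_s = m[, 2])
    } else if (dialect == "MINUTE_LABELS" && length(body)) {
      v <- as.integer(body)
      runs <- rle(v); ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
      keep <- runs$values == 1L
      events <- data.frame(onset_s = starts[keep] * 60, duration_s = runs$lengths[keep] * 60)
      dur <- n / fs
      events$duration_s <- pmin(events$duration_s, dur - events$onset_s)
      events <- events[events$duration_s > 0, , drop = FALSE]
    }
  }
  signal_record(adc / gain, fs, channel, events, dialect)
}
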