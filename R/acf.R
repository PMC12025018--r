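#' Autocorrelation of a window via the Wiener-Khinchin theorem
#'
#' The ACF is obtained as the inverse Fourier transform of the power spectral
#' density, computed with zero padding so the result equals the linear (not
#' circular) autocorrelation, then truncated to `lag_max` lags and normalized
#' so the lag-0 value is exactly 1.
#'
#' @param window Numeric sample vector (must not be all zero).
#' @param lag_max Largest lag to keep (default `length(window) - 1`). The
#'   quality graph uses 1 s of lags (`lag_max = fs`).
#' @return Numeric vector of length `lag_max + 1`; element 1 is lag 0.
#' @export
compute_acf <- function(window, lag_max = length(window) - 1L) {
  n <- length(window)
  if (n < 2L) stop("window must have at least 2 samples", call. = FALSE)
  if (all(window == 0)) stop("all-zero window: ACF normalization undefined", call. = FALSE)
  lag_max <- as.integer(min(lag_max, n - 1L))
  nfft <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(window, rep(0, nfft - n)))
  s <- Mod(f)^2
  r <- Re(stats::fft(s, inverse = TRUE)) / nfft
  r[seq_len(lag_max + 1L)] / r[1L]
}

#' Pairwise cosine-similarity graph of ACF vectors
#'
#' Every window's ACF is a vertex; edge weights are cosine similarities
#' `cos(theta) = A1 . A2 / (||A1|| ||A2||)`. A vertex's degree weight is the sum
#' of its similarities to all other vertices; artifact-contaminated windows
#' have dissimilar ACFs and therefore low degree.
#'
#' @param acfs Matrix with one ACF vector per row (>= 2 rows).
#' @return List with `similarity` (symmetric matrix, unit diagonal) and
#'   `weights` (per-row degree, self-similarity excluded).
#' @export
similarity_graph <- function(acfs) {
  if (is.null(dim(acfs))) acfs <- matrix(acfs, nrow = 1)
  n <- nrow(acfs)
  if (n < 2L) stop("need at least 2 ACF vectors", call. = FALSE)
  norms <- sqrt(rowSums(acfs^2))
  if (any(norms == 0)) stop("zero-norm ACF vector", call. = FALSE)
  S <- tcrossprod(acfs / norms)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  list(similarity = S, weights = rowSums(S) - 1)
}

#' Discard artifact-contaminated windows via the ACF similarity graph
#'
#' Computes the per-window ACF (1 s of lags), builds the cosine-similarity
#' graph, and keeps the `ceil(percentile * n)` windows with the highest degree
#' weights (ties broken stably by window index). Intended for ECG window sets;
#' SpO2 windows are not screened.
#'
#' @param set A [window_set()] with at least 20 windows.
#' @param percentile Retention fraction (default 0.95: keep the top 95% by
#'   weight, discarding the bottom 5% as outliers).
#' @param lag_s ACF truncation in seconds of lag (default 1).
#' @return List with `kept` (the retained [window_set()]) and `report`, an
#'   `acf_quality_report` holding `acfs`, `similarity`, `weights`, `keep_mask`
#'   and `percentile`.
#' @export
reject_noisy <- function(set, percentile = 0.95, lag_s = 1) {
  stopifnot(inherits(set, "window_set"))
  n <- n_windows(set)
  if (n < 20L) stop("need at least 20 windows for percentile screening", call. = FALSE)
  assert_scalar_num(percentile, "percentile", 1e-9, 1)
  lag_max <- round(lag_s * set$fs)
  acfs <- t(apply(set$windows, 1L, compute_acf, lag_max = lag_max))
  g <- similarity_graph(acfs)
  n_keep <- ceiling(percentile * n)
  ord <- order(-g$weights, seq_len(n))  # ties broken stably by window index
  keep_mask <- logical(n)
  keep_mask[ord[seq_len(n_keep)]] <- TRUE
  report <- structure(list(acfs = acfs, similarity = g$similarity,
                           weights = g$weights, keep_mask = keep_mask,
                           percentile = percentile), class = "acf_quality_report")
  list(kept = subset_windows(set, keep_mask), report = report)
}

#' @export
print.acf_quality_report <- function(x, ...) {
  cat(sprintf("<acf_quality_report> %d windows, %d kept (%.0f%%), weight range [%.3f, %.3f]\n",
              length(x$keep_mask), sum(x$keep_mask), 100 * x$percentile,
              min(x$weights), max(x$weights)))
  invisible(x)
}

#' Serialize a quality report as a delimited table
#'
#' One row per window: id, start time, degree weight, kept flag. The keep mask
#' can be re-read and applied to a later run.
#'
#' @param report An `acf_quality_report` from [reject_noisy()].
#' @param set The [window_set()] the report was computed on.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, set, path) {
  df <- data.frame(window = seq_along(report$keep_mask),
                   start_time_s = set$start_times_s,
                   weight = report$weights,
                   kept = as.integer(report$keep_mask))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restore ECG/SpO2 pairing after quality screening
#'
#' Quality rejection drops ECG windows; the matching SpO2 windows must be
#' dropped too so the fusion model always sees aligned pairs. Windows are
#' matched on (source id, start time).
#'
#' @param ecg,spo2 [window_set()]s from the same recordings.
#' @return List with aligned `ecg` and `spo2` window sets.
#' @export
align_pair <- function(ecg, spo2) {
  key_e <- paste(ecg$source_ids, round(ecg$start_times_s, 6))
  key_s <- paste(spo2$source_ids, round(spo2$start_times_s, 6))
  common <- intersect(key_e, key_s)
  list(ecg = subset_windows(ecg, match(common, key_e)),
       spo2 = subset_windows(spo2, match(common, key_s)))
}
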