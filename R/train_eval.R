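#' Train/validation/test split plan
#'
#' Ratios default to 8:1:1. `RECORD`-level splitting (the default) assigns
#' whole recordings to one partition, preventing the near-duplicate leakage
#' that 10 s-overlap windows cause under segment-level splitting; `SEGMENT`
#' splits individual windows.
#'
#' @param ratios Positive (train, val, test) weights; normalized internally.
#' @param level `"RECORD"` or `"SEGMENT"`.
#' @param seed Integer seed.
#' @return A `split_plan` object.
#' @export
split_plan <- function(ratios = c(8, 1, 1), level = c("RECORD", "SEGMENT"), seed = 1L) {
  level <- match.arg(level)
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("ratios must be three positive numbers", call. = FALSE)
  }
  structure(list(ratios = ratios / sum(ratios), level = level,
                 seed = as.integer(seed)), class = "split_plan")
}

#' Split an aligned window pair into train/val/test
#'
#' @param pair List with aligned `ecg` and `spo2` [window_set()]s.
#' @param plan A [split_plan()].
#' @return List with `train`, `val`, `test`, each an aligned pair.
#' @export
split_pair <- function(pair, plan = split_plan()) {
  check_aligned_pair(pair)
  n <- n_windows(pair$ecg)
  idx <- with_seed(plan$seed, {
    if (plan$level == "RECORD") {
      recs <- unique(pair$ecg$source_ids)
      n_rec <- length(recs)
      n_tr <- max(1L, round(plan$ratios[1] * n_rec))
      n_va <- max(1L, round(plan$ratios[2] * n_rec))
      if (n_tr + n_va >= n_rec) {
        n_tr <- max(1L, n_rec - 2L); n_va <- 1L
      }
      # stratified retry: short recordings may carry no apnea windows at all,
      # so reshuffle (deterministically) until every partition sees both
      # classes, when the pooled data makes that possible
      out <- NULL
      for (try in 1:25) {
        sh <- sample(recs)
        groups <- list(train = sh[seq_len(n_tr)],
                       val = sh[n_tr + seq_len(n_va)],
                       test = sh[(n_tr + n_va + 1L):n_rec])
        cand <- lapply(groups, function(g) which(pair$ecg$source_ids %in% g))
        ok <- all(vapply(cand, function(i)
          length(unique(pair$ecg$labels[i])) == 2L, logical(1)))
        if (ok || is.null(out)) out <- cand
        if (ok) break
      }
      out
    } else {
      perm <- sample.int(n)
      n_tr <- round(plan$ratios[1] * n)
      n_va <- round(plan$ratios[2] * n)
      list(train = sort(perm[seq_len(n_tr)]),
           val = sort(perm[n_tr + seq_len(n_va)]),
           test = sort(perm[(n_tr + n_va + 1L):n]))
    }
  })
  lapply(idx, function(i) list(ecg = subset_windows(pair$ecg, i),
                               spo2 = subset_windows(pair$spo2, i)))
}

#' Oversample the minority class, then augment by time reversal
#'
#' Random oversampling with replacement brings the minority class up to the
#' majority count; every window (original and oversampled) is then duplicated
#' as its time-reversed copy, doubling the set. Starting from an unbalanced
#' two-class set of majority size M, the result has exactly `4 * M` windows.
#'
#' @param set A labeled [window_set()] containing both classes.
#' @param seed Integer seed for the oversampling draw.
#' @return An augmented [window_set()] (start times inherited; provenance
#'   suffixed for duplicates).
#' @export
balance_and_augment <- function(set, seed = 1L) {
  stopifnot(inherits(set, "window_set"))
  tab <- table(factor(set$labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present to balance", call. = FALSE)
  minority <- as.integer(names(tab)[which.min(tab)])
  n_extra <- max(tab) - min(tab)
  idx_min <- which(set$labels == minority)
  extra <- if (n_extra > 0) with_seed(seed, sample(idx_min, n_extra, replace = TRUE)) else integer(0)
  W <- rbind(set$windows, set$windows[extra, , drop = FALSE])
  labels <- c(set$labels, set$labels[extra])
  src <- c(set$source_ids, paste0(set$source_ids[extra], "+os"))
  st <- c(set$start_times_s, set$start_times_s[extra])
  # augmentation: append the time-reversed copy of every window
  W <- rbind(W, W[, rev(seq_len(ncol(W))), drop = FALSE])
  labels <- c(labels, labels)
  src <- c(src, paste0(src, "+flip"))
  st <- c(st, st)
  out <- set
  out$windows <- W; out$labels <- labels; out$source_ids <- src; out$start_times_s <- st
  out
}

#' Corrupt a fraction of windows with additive white Gaussian noise
#'
#' Exactly `round(fraction * n)` windows are drawn without replacement
#' (seeded); each selected window is fully corrupted with zero-mean Gaussian
#' noise whose power is `P_signal / 10^(snr_db / 10)`, with signal power
#' measured per window. At -20 dB the noise power is 100x the signal power.
#'
#' @param set A [window_set()].
#' @param snr_db Signal-to-noise ratio in dB (default -20).
#' @param fraction Fraction of windows to corrupt.
#' @param seed Integer seed.
#' @return List with `set` (corrupted copy) and `corrupted` (sorted indices).
#' @export
add_awgn <- function(set, snr_db = -20, fraction, seed = 1L) {
  stopifnot(inherits(set, "window_set"))
  assert_scalar_num(fraction, "fraction", 0, 1)
  if (!is.finite(snr_db)) stop("snr_db must be finite", call. = FALSE)
  n <- n_windows(set)
  m <- round(fraction * n)
  if (m == 0L) return(list(set = set, corrupted = integer(0)))
  with_seed(seed, {
    idx <- sort(sample.int(n, m))
    W <- set$windows
    for (i in idx) {
      p_sig <- mean(W[i, ]^2)
      if (p_sig == 0) stop(sprintf("window %d has zero power; SNR undefined", i), call. = FALSE)
      noise <- stats::rnorm(ncol(W))
      # scale the realization to the exact target power so the per-window SNR
      # is -snr_db by construction, not just in expectation (short windows
      # would otherwise fluctuate by ~1 dB)
      noise <- noise * sqrt(p_sig * 10^(-snr_db / 10) / mean(noise^2))
      W[i, ] <- W[i, ] + noise
    }
    out <- set
    out$windows <- W
    list(set = out, corrupted = idx)
  })
}

#' Confusion-matrix metrics report
#'
#' @param tp,fp,fn,tn Confusion counts (positive class = apnea).
#' @return A `metrics_report`: counts plus accuracy, precision, recall,
#'   specificity and F1 (harmonic mean of precision and recall). Undefined
#'   ratios (zero denominators) are reported as `NA`.
#' @export
metrics_report <- function(tp, fp, fn, tn) {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rat(tp, tp + fp)
  recall <- rat(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) NA_real_ else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = rat(tp + tn, tp + fp + fn + tn),
                 precision = precision, recall = recall,
                 specificity = rat(tn, tn + fp), f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d  acc %.4f  prec %.4f  rec %.4f  ",
                     "spec %.4f  F1 %.4f\n"),
              x$tp + x$fp + x$fn + x$tn, x$accuracy, x$precision, x$recall,
              x$specificity, x$f1))
  invisible(x)
}

#' Evaluate a model on a labeled test set
#'
#' Decisions are the argmax of the softmax output; metrics come from the
#' resulting confusion matrix with apnea as the positive class.
#'
#' @param model An `nn_model` (pass a [window_set()]) or `fusion_model` (pass
#'   an aligned pair list).
#' @param test A [window_set()] or aligned pair.
#' @return A [metrics_report()].
#' @export
evaluate <- function(model, test) {
  if (inherits(model, "fusion_model")) {
    check_aligned_pair(test)
    if (n_windows(test$ecg) == 0L) stop("empty test set", call. = FALSE)
    probs <- fusion_predict(model, test$ecg$windows, test$spo2$windows)
    y <- test$ecg$labels
  } else {
    stopifnot(inherits(test, "window_set"))
    if (n_windows(test) == 0L) stop("empty test set", call. = FALSE)
    probs <- nn_predict(model, test$windows)
    y <- test$labels
  }
  pred <- max.col(probs) - 1L
  metrics_report(tp = sum(pred == 1L & y == 1L), fp = sum(pred == 1L & y == 0L),
                 fn = sum(pred == 0L & y == 1L), tn = sum(pred == 0L & y == 0L))
}

#' Noise-robustness protocol configuration
#'
#' Defaults follow the stated evaluation: -20 dB white Gaussian noise, 20% of
#' windows corrupted in train/validation sets, 11.42% in the test set, under
#' three scenarios (ECG-only, SpO2-only, both corrupted).
#'
#' @param snr_db SNR in dB (default -20).
#' @param train_val_fraction Fraction of train/val windows corrupted (0.20).
#' @param test_fraction Fraction of test windows corrupted (0.1142).
#' @param scenarios Character subset of `c("ECG_ONLY", "SPO2_ONLY", "BOTH")`.
#' @param seed Integer seed; each scenario derives its own disjoint stream.
#' @return A `noise_protocol` object.
#' @export
noise_protocol <- function(snr_db = -20, train_val_fraction = 0.20,
                           test_fraction = 0.1142,
                           scenarios = c("ECG_ONLY", "SPO2_ONLY", "BOTH"),
                           seed = 1L) {
  if (!is.finite(snr_db)) stop("snr_db must be finite", call. = FALSE)
  assert_scalar_num(train_val_fraction, "train_val_fraction", 0, 1)
  assert_scalar_num(test_fraction, "test_fraction", 0, 1)
  scenarios <- match.arg(scenarios, c("ECG_ONLY", "SPO2_ONLY", "BOTH"),
                         several.ok = TRUE)
  structure(list(snr_db = snr_db, train_val_fraction = train_val_fraction,
                 test_fraction = test_fraction, scenarios = scenarios,
                 seed = as.integer(seed)), class = "noise_protocol")
}

#' Run the noise-robustness protocol
#'
#' For each scenario, the stated fraction of test windows is corrupted at the
#' protocol SNR (ECG set only, SpO2 set only, or both, each scenario drawing
#' its own seeded window subset), and every model is evaluated on the
#' scenario's data: branch models on their own channel, the fusion model on
#' the pair.
#'
#' @param branch_models List with `ecg` and `spo2` trained `nn_model`s.
#' @param fusion_model A trained `fusion_model`.
#' @param test_pair Aligned test pair.
#' @param protocol A [noise_protocol()].
#' @return Named list per scenario; each element holds `ecg`, `spo2`, `fusion`
#'   [metrics_report()]s and the corrupted index sets.
#' @export
run_noise_protocol <- function(branch_models, fusion_model, test_pair,
                               protocol = noise_protocol()) {
  check_aligned_pair(test_pair)
  out <- list()
  for (si in seq_along(protocol$scenarios)) {
    sc <- protocol$scenarios[si]
    seed_sc <- derive_seed(protocol$seed, si)
    ecg_set <- test_pair$ecg; spo2_set <- test_pair$spo2
    idx_ecg <- integer(0); idx_spo2 <- integer(0)
    if (sc %in% c("ECG_ONLY", "BOTH")) {
      r <- add_awgn(ecg_set, protocol$snr_db, protocol$test_fraction, seed_sc)
      ecg_set <- r$set; idx_ecg <- r$corrupted
    }
    if (sc %in% c("SPO2_ONLY", "BOTH")) {
      # in the BOTH scenario one noisy epoch hits both sensors: the same
      # window subset is corrupted in each channel (noise values independent)
      r <- add_awgn(spo2_set, protocol$snr_db, protocol$test_fraction,
                    if (sc == "BOTH") seed_sc else derive_seed(seed_sc, 7L))
      spo2_set <- r$set; idx_spo2 <- r$corrupted
    }
    out[[sc]] <- list(
      ecg = evaluate(branch_models$ecg, ecg_set),
      spo2 = evaluate(branch_models$spo2, spo2_set),
      fusion = evaluate(fusion_model, list(ecg = ecg_set, spo2 = spo2_set)),
      corrupted_ecg = idx_ecg, corrupted_spo2 = idx_spo2)
  }
  out
}

#' Serialize a metrics report (or per-scenario list) to JSON
#'
#' @param x A [metrics_report()] or the output of [run_noise_protocol()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  strip <- function(m) if (inherits(m, "metrics_report")) unclass(m) else
    if (is.list(m)) lapply(m, strip) else m
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
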