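# Scaled-down end-to-end study shared by the acceptance tests and the
# acceptance report script: ~2000 synthetic window pairs, record-level 8:1:1
# split, the full preprocessing chain, both branches, the fused head, the
# -20 dB BOTH-corrupted protocol, and Grad-CAM localization on apneic SpO2
# test windows.
#
# Scale note: 20 records x 110 s at 1 s stride gives 100 window pairs per
# record (2000 total), the spec's desk-scale study size; 20 records keep at
# least 2 recordings in each of the validation and test partitions. Branch
# hyperparameters are fixed here once (ECG: 3 epochs, batch 128; SpO2: 6
# epochs, batch 64 — the SpO2 branch is ~40x cheaper per epoch).

# The study states the spec's "strong desat/RR effects" separable regime:
# deeper desaturations (6 pp), stronger RR shortening (0.35) and longer events
# (15-40 s) than the package defaults (which mirror the published class
# statistics); see the methods vignette for the rationale.
study_sim_config <- function(duration_s, seed) {
  sim_config(duration_s, apnea_event_rate = 30, event_duration_s = c(15, 40),
             desat_depth_pct = 6, rr_apnea_modulation = 0.35, seed = seed)
}

run_study <- function(seed, n_records = 20L, duration_s = 110) {
  ecg_sets <- list(); spo2_sets <- list(); events_by_src <- list()
  for (i in seq_len(n_records)) {
    p <- simulate_pair(study_sim_config(duration_s, seed = apneafusion:::derive_seed(seed, i)))
    id <- sprintf("rec%02d", i)
    ecg_sets[[id]] <- ingest_record(p$ecg, source_id = id)
    spo2_sets[[id]] <- ingest_record(p$spo2, source_id = id)
    events_by_src[[id]] <- p$ecg$events
  }
  ecg <- bandpass(apneafusion:::bind_window_sets(ecg_sets))
  spo2 <- apneafusion:::bind_window_sets(spo2_sets)

  # ACF quality screening per record, then restore pairing
  kept <- list()
  for (src in unique(ecg$source_ids)) {
    sub <- apneafusion:::subset_windows(ecg, which(ecg$source_ids == src))
    kept[[src]] <- reject_noisy(sub, 0.95)$kept
  }
  pair <- align_pair(apneafusion:::bind_window_sets(kept), spo2)

  sp <- split_pair(pair, split_plan(seed = apneafusion:::derive_seed(seed, 50)))
  tr_e <- balance_and_augment(sp$train$ecg, apneafusion:::derive_seed(seed, 51))
  tr_s <- balance_and_augment(sp$train$spo2, apneafusion:::derive_seed(seed, 52))

  hy_ecg <- train_hyper(epochs = 3L, batch_size = 128L, patience = 2L)
  hy_spo2 <- train_hyper(epochs = 8L, batch_size = 64L, patience = 3L)
  res_e <- train_branch(build_branch(branch_spec("ECG"), apneafusion:::derive_seed(seed, 53)),
                        tr_e, sp$val$ecg, hy_ecg, apneafusion:::derive_seed(seed, 54))
  res_s <- train_branch(build_branch(branch_spec("SPO2"), apneafusion:::derive_seed(seed, 55)),
                        tr_s, sp$val$spo2, hy_spo2, apneafusion:::derive_seed(seed, 56))

  fm <- build_fusion(res_e$model, res_s$model, fusion_plan(),
                     fs_pair = c(pair$ecg$fs, pair$spo2$fs),
                     seed = apneafusion:::derive_seed(seed, 57))
  tr_pair <- apneafusion:::balance_pair(sp$train, apneafusion:::derive_seed(seed, 58))
  # the stated protocol trains every model on clean data and corrupts the
  # test set only; train-time corruption variants exist (see
  # corrupt_pair_for_head below, kept for the robustness experiments the
  # noise_protocol's train_val_fraction field supports) but are not part of
  # this study
  res_f <- train_fusion(fm, tr_pair, sp$val,
                        train_hyper(epochs = 8L, batch_size = 64L, patience = 2L),
                        apneafusion:::derive_seed(seed, 59))

  clean <- list(ecg = evaluate(res_e$model, sp$test$ecg),
                spo2 = evaluate(res_s$model, sp$test$spo2),
                fusion = evaluate(res_f$model, sp$test))
  noisy <- run_noise_protocol(list(ecg = res_e$model, spo2 = res_s$model),
                              res_f$model, sp$test,
                              noise_protocol(scenarios = "BOTH",
                                             seed = apneafusion:::derive_seed(seed, 60)))

  # Grad-CAM localization on apneic SpO2 test windows against the known event
  # interval intersected with each window
  loc <- gradcam_localization_rates(res_s$model, sp$test$spo2, events_by_src)
  apneafusion:::.conv_buffers_free_cpp()
  list(n_pairs = apneafusion:::n_windows(pair$ecg),
       history_ecg = res_e$history, history_spo2 = res_s$history,
       clean = clean, both = noisy$BOTH, localization = loc)
}

# corrupt `fraction` of an aligned pair's windows at -20 dB, half ECG-only
# and half SpO2-only
corrupt_pair_for_head <- function(pair, fraction, seed) {
  n <- nrow(pair$ecg$windows)
  m <- round(fraction * n)
  idx <- apneafusion:::with_seed(seed, sample.int(n, m))
  halves <- split(idx, rep(1:2, length.out = m))
  corrupt <- function(set, rows, seed_off) {
    if (!length(rows)) return(set)
    rows <- sort(rows)
    sub <- apneafusion:::subset_windows(set, rows)
    sub <- add_awgn(sub, -20, 1, apneafusion:::derive_seed(seed, seed_off))$set
    set$windows[rows, ] <- sub$windows
    set
  }
  pair$ecg <- corrupt(pair$ecg, halves[[1]], 1L)
  pair$spo2 <- corrupt(pair$spo2, halves[[2]], 2L)
  pair
}

# fraction of apneic SpO2 windows whose inside/outside importance ratio
# exceeds 1, where "inside" is the window's overlap with its ground-truth
# apnea event(s)
gradcam_localization_rates <- function(spo2_model, test_spo2, events_by_src,
                                       max_windows = 40L) {
  idx <- which(test_spo2$labels == 1L)
  if (!length(idx)) return(numeric(0))
  idx <- utils::head(idx, max_windows)
  ratios <- vapply(idx, function(i) {
    w <- test_spo2$windows[i, ]
    start <- test_spo2$start_times_s[i]
    ev <- events_by_src[[test_spo2$source_ids[i]]]
    # score against the programmed desaturation support, which lags the
    # airway event by desat_lag_s (the region a SpO2 model can actually see)
    lag <- 5
    ov_lo <- pmax(ev$onset_s + lag, start)
    ov_hi <- pmin(ev$onset_s + ev$duration_s + lag, start + test_spo2$window_s)
    keep <- which(ov_hi - ov_lo > 0.5)
    if (!length(keep)) return(NA_real_)
    lo <- floor((ov_lo[keep[1]] - start) * test_spo2$fs) + 1
    hi <- ceiling((ov_hi[keep[1]] - start) * test_spo2$fs)
    hi <- min(hi, ncol(test_spo2$windows))
    if (lo <= 1 && hi >= ncol(test_spo2$windows)) return(NA_real_)
    res <- gradcam(spo2_model, w, "apnea")
    localization_score(res, c(lo, hi))
  }, numeric(1))
  ratios[!is.na(ratios)]
}
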