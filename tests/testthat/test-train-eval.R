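mk_set <- function(n, labels, fs = 8, m = 88) {
  set.seed(n + sum(labels))
  window_set(matrix(rnorm(n * m), n, m), labels, fs, "SPO2",
             rep("r", n), seq_len(n) - 1, 11)
}

test_that("oversample + flip counts are exact", {
  s <- mk_set(100, rep(c(1L, 0L), c(30, 70)))
  out <- balance_and_augment(s, seed = 1)
  expect_identical(nrow(out$windows), 280L)          # 70/70 then doubled
  expect_identical(sum(out$labels == 1L), 140L)
  expect_identical(sum(out$labels == 0L), 140L)
  bal <- mk_set(100, rep(c(1L, 0L), c(50, 50)))
  expect_identical(nrow(balance_and_augment(bal, 1)$windows), 200L)
  expect_error(balance_and_augment(mk_set(10, rep(0L, 10)), 1), "both classes")
})

test_that("flip is a time-reversal involution", {
  s <- mk_set(4, c(0L, 1L, 0L, 1L))
  out <- balance_and_augment(s, seed = 2)
  n <- nrow(s$windows)
  flipped <- out$windows[nrow(out$windows) / 2 + seq_len(n), ]
  expect_identical(flipped[, rev(seq_len(ncol(flipped)))], s$windows)
})

test_that("training is deterministic and zero epochs is the identity", {
  pair <- fixture_window_pair(1, 90, seed = 31)
  m0 <- build_branch(branch_spec("SPO2"), seed = 1)
  hy <- train_hyper(epochs = 2, batch_size = 32)
  r1 <- train_branch(m0, pair$spo2, pair$spo2, hy, seed = 5)
  r2 <- train_branch(m0, pair$spo2, pair$spo2, hy, seed = 5)
  expect_identical(nn_param_vector(r1$model), nn_param_vector(r2$model))
  expect_identical(r1$history, r2$history)
  r3 <- train_branch(m0, pair$spo2, pair$spo2, hy, seed = 6)
  expect_false(identical(nn_param_vector(r1$model), nn_param_vector(r3$model)))
  rz <- train_branch(m0, pair$spo2, pair$spo2, train_hyper(epochs = 0), seed = 5)
  expect_identical(nn_param_vector(rz$model), nn_param_vector(m0))
  expect_identical(nrow(rz$history), 0L)
})

test_that("AWGN hits the requested SNR and corruption count exactly", {
  s <- mk_set(50, rep(0L, 50))
  res <- add_awgn(s, snr_db = -20, fraction = 0.2, seed = 3)
  expect_length(res$corrupted, 10L)                    # round(0.2 * 50)
  for (i in res$corrupted[1:5]) {
    noise <- res$set$windows[i, ] - s$windows[i, ]
    snr <- 10 * log10(mean(s$windows[i, ]^2) / mean(noise^2))
    expect_lt(abs(snr - (-20)), 0.5)
  }
  untouched <- setdiff(seq_len(50), res$corrupted)
  expect_identical(res$set$windows[untouched, ], s$windows[untouched, ])
  expect_identical(add_awgn(s, -20, 0, 1)$set$windows, s$windows)
  # the protocol fractions: 0.1142 and 0.20
  big <- mk_set(500, rep(0L, 500))
  expect_length(add_awgn(big, -20, 0.1142, 1)$corrupted, round(0.1142 * 500))
  zero <- s; zero$windows[3, ] <- 0
  expect_error(add_awgn(zero, -20, 1, 1), "zero power")
})

test_that("metric definitions hold on fixed confusion matrices", {
  m <- metrics_report(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$f1, 0.75)
  perfect <- metrics_report(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "specificity", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, specificity = 1, f1 = 1))
  # identities hold exactly; F1 is the harmonic mean
  set.seed(6)
  for (i in 1:10) {
    cm <- sample(1:40, 4)
    r <- metrics_report(cm[1], cm[2], cm[3], cm[4])
    expect_identical(r$tp + r$fp + r$fn + r$tn, sum(cm))
    expect_equal(r$recall, cm[1] / (cm[1] + cm[3]), tolerance = 1e-12)
    expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$recall), tolerance = 1e-12)
  }
})

test_that("evaluate agrees with a brute-force confusion recount", {
  pair <- fixture_window_pair(1, 220, seed = 41)
  m <- build_branch(branch_spec("SPO2"), seed = 2)
  rep_ <- evaluate(m, pair$spo2)
  probs <- nn_predict(m, pair$spo2$windows)
  pred <- apply(probs, 1, which.max) - 1L   # independent argmax
  y <- pair$spo2$labels
  cm <- table(factor(pred, c(0, 1)), factor(y, c(0, 1)))
  expect_identical(rep_$tp, as.integer(cm["1", "1"]))
  expect_identical(rep_$tn, as.integer(cm["0", "0"]))
  expect_identical(rep_$fp, as.integer(cm["1", "0"]))
  expect_identical(rep_$fn, as.integer(cm["0", "1"]))
  expect_equal(rep_$accuracy, mean(pred == y))
  expect_error(evaluate(m, apneafusion:::subset_windows(pair$spo2, integer(0))),
               "empty test set")
})

test_that("record-level split separates sources; segment-level splits windows", {
  pair <- fixture_window_pair(4, 80, seed = 51)
  sp <- split_pair(pair, split_plan(seed = 1))
  srcs <- lapply(sp, function(p) unique(p$ecg$source_ids))
  expect_length(intersect(srcs$train, srcs$test), 0)
  expect_length(intersect(srcs$train, srcs$val), 0)
  n_total <- sum(vapply(sp, function(p) nrow(p$ecg$windows), numeric(1)))
  expect_identical(as.integer(n_total), nrow(pair$ecg$windows))
  sp2 <- split_pair(pair, split_plan(level = "SEGMENT", seed = 2))
  n2 <- vapply(sp2, function(p) nrow(p$ecg$windows), numeric(1))
  expect_identical(as.integer(sum(n2)), nrow(pair$ecg$windows))
  expect_equal(n2[["train"]] / sum(n2), 0.8, tolerance = 0.02)
})

test_that("noise protocol: zero fraction reproduces clean metrics; draws are per-scenario", {
  pair <- fixture_window_pair(2, 90, seed = 61, filter_ecg = TRUE)
  hy <- train_hyper(epochs = 1, batch_size = 32)
  be <- train_branch(build_branch(branch_spec("ECG"), 1), pair$ecg, pair$ecg, hy, 2)$model
  bs <- train_branch(build_branch(branch_spec("SPO2"), 3), pair$spo2, pair$spo2, hy, 4)$model
  fm <- train_fusion(build_fusion(be, bs, seed = 5), pair, pair, hy, 6)$model
  models <- list(ecg = be, spo2 = bs)
  clean <- list(ecg = evaluate(be, pair$ecg), spo2 = evaluate(bs, pair$spo2),
                fusion = evaluate(fm, pair))
  p0 <- noise_protocol(test_fraction = 0, seed = 9)
  res0 <- run_noise_protocol(models, fm, pair, p0)
  for (sc in names(res0)) {
    expect_identical(res0[[sc]]$ecg[1:4], clean$ecg[1:4])
    expect_identical(res0[[sc]]$spo2[1:4], clean$spo2[1:4])
    expect_identical(res0[[sc]]$fusion[1:4], clean$fusion[1:4])
  }
  res <- run_noise_protocol(models, fm, pair, noise_protocol(seed = 9))
  expect_identical(res$ECG_ONLY$corrupted_spo2, integer(0))
  expect_identical(res$SPO2_ONLY$corrupted_ecg, integer(0))
  expect_length(res$BOTH$corrupted_ecg, round(0.1142 * nrow(pair$ecg$windows)))
  # one noisy epoch hits both sensors in the BOTH scenario
  expect_identical(res$BOTH$corrupted_ecg, res$BOTH$corrupted_spo2)
  # misaligned pair is rejected
  bad <- list(ecg = pair$ecg, spo2 = apneafusion:::subset_windows(pair$spo2, 1:10))
  expect_error(run_noise_protocol(models, fm, bad, p0), "misaligned")
})

test_that("degradation is monotone in SNR (median over noise seeds)", {
  pair <- fixture_window_pair(3, 160, seed = 81, filter_ecg = TRUE)
  tr <- balance_and_augment(pair$ecg, 1)
  m <- train_branch(build_branch(branch_spec("ECG"), 1), tr, pair$ecg,
                    train_hyper(epochs = 1, batch_size = 64), 2)$model
  f1_at <- function(snr, seed) evaluate(m, add_awgn(pair$ecg, snr, 1, seed)$set)$f1
  clean <- evaluate(m, pair$ecg)$f1
  m20 <- median(vapply(1:5, function(s) f1_at(-20, s), numeric(1)))
  p20 <- median(vapply(1:5, function(s) f1_at(20, s), numeric(1)))
  expect_lte(m20, p20)
  expect_lte(p20, clean + 1e-12)
})

test_that("non-finite loss aborts with a diagnostic", {
  pair <- fixture_window_pair(3, 160, seed = 81)
  tr <- balance_and_augment(pair$ecg, 1)
  tr$windows[1, 5] <- NaN
  expect_error(train_branch(build_branch(branch_spec("ECG"), 1), tr, pair$ecg,
                            train_hyper(epochs = 1), 3),
               "diverged")
})

test_that("metrics reports serialize to JSON", {
  m <- metrics_report(3, 1, 1, 5)
  path <- file.path(tempdir(), "metrics.json")
  write_metrics(list(clean = m), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$clean$accuracy, 0.8)
})
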