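test_that("grad-cam raw map matches the finite-difference oracle on a toy model", {
  m <- tiny_conv_model(seed = 2, input_len = 16L)  # one conv: 2 channels, W = 8
  set.seed(3)
  x <- rnorm(16)
  res <- gradcam(m, x, target_class = "apnea")
  conv_idx <- which(vapply(m$layers, function(l) l$type == "conv", logical(1)))
  relu_idx <- conv_idx + 1L
  A <- apneafusion:::replay_to_layer(m, matrix(x, 1), relu_idx)
  W_len <- dim(A)[2]; K <- dim(A)[3]
  # finite-difference gradient of the apnea logit w.r.t. each map element:
  # forward the tail of the network from perturbed activations
  forward_tail <- function(Amaps) {
    a <- Amaps
    for (i in (relu_idx + 1L):length(m$layers)) {
      ly <- m$layers[[i]]
      a <- switch(ly$type,
        maxpool = apneafusion:::pool_fwd(a)$out,
        flatten = matrix(aperm(a, c(1, 3, 2)), dim(a)[1], dim(a)[2] * dim(a)[3]),
        dropout = a,
        dense = a %*% ly$params$W + rep(ly$params$b, each = nrow(a)),
        relu = pmax(a, 0))
    }
    a[1, 2]  # apnea logit
  }
  eps <- 1e-5
  grads <- array(0, dim(A))
  for (i in seq_len(length(A))) {
    Ap <- A; Ap[i] <- Ap[i] + eps
    Am <- A; Am[i] <- Am[i] - eps
    grads[i] <- (forward_tail(Ap) - forward_tail(Am)) / (2 * eps)
  }
  a_k_fd <- colMeans(matrix(grads[1, , ], W_len, K))
  expect_equal(res$channel_weights, a_k_fd, tolerance = 1e-6)
  raw_fd <- pmax(as.vector(matrix(A[1, , ], W_len, K) %*% a_k_fd), 0)
  expect_equal(res$raw_map, raw_fd, tolerance = 1e-6)
})

test_that("single-channel and all-negative-weight degenerate cases", {
  # with one channel and constant positive gradient, the normalized map is the
  # normalized (rectified) feature map itself
  m <- build_branch(branch_spec("SPO2", input_len = 16L,
                                conv_layers = list(c(1L, 3L, 1L))), seed = 5)
  set.seed(6)
  x <- rnorm(16)
  res <- gradcam(m, x, "apnea")
  A <- res$feature_maps[, 1]
  w <- res$channel_weights[1]
  expected <- pmax(A * w, 0)
  expect_equal(res$raw_map, expected, tolerance = 1e-10)
  # ReLU annihilation: force an all-negative head column so the channel
  # weight is negative while the post-ReLU maps are nonnegative -> zero map
  m_neg <- m
  di <- length(m_neg$layers)
  m_neg$layers[[di]]$params$W[, 2] <- -1
  res_neg <- gradcam(m_neg, x, "apnea")
  expect_lt(res_neg$channel_weights[1], 0)
  expect_true(all(res_neg$raw_map == 0))
})

test_that("normalized maps live in [0,1] and are scale covariant", {
  m <- tiny_conv_model(seed = 7)
  set.seed(8)
  x <- rnorm(16)
  res <- gradcam(m, x, "normal")
  expect_true(all(res$raw_map >= 0))
  expect_true(all(res$upsampled_map >= 0 & res$upsampled_map <= 1))
  expect_length(res$upsampled_map, 16L)
  # scaling all conv weights (hence activations) by c > 0 leaves the
  # normalized map unchanged up to numerics
  m2 <- m
  ci <- which(vapply(m$layers, function(l) l$type == "conv", logical(1)))
  m2$layers[[ci]]$params$W <- m2$layers[[ci]]$params$W * 3
  m2$layers[[ci]]$params$b <- m2$layers[[ci]]$params$b * 3
  res2 <- gradcam(m2, x, "normal")
  if (!res$degenerate && !res2$degenerate) {
    expect_equal(res2$upsampled_map, res$upsampled_map, tolerance = 1e-6)
  }
})

test_that("band quantization uses half-open bins and flags degenerate maps", {
  mk <- function(v) structure(list(upsampled_map = v, degenerate = FALSE),
                              class = "gradcam_result")
  cfg <- band_config()
  r <- quantize_bands(mk(c(0, 1 / 3 - 1e-9, 1 / 3, 2 / 3 - 1e-9, 2 / 3, 1)), cfg)
  expect_identical(as.character(r$bands),
                   c("LOW", "LOW", "MODERATE", "MODERATE", "HIGH", "HIGH"))
  expect_warning(quantize_bands(mk(rep(0.5, 10))), "one band")
  expect_error(band_config(c(0.7, 0.3)), "t_low < t_high")
  custom <- quantize_bands(mk(c(0.05, 0.5, 0.95)), band_config(c(0.1, 0.9)))
  expect_identical(as.character(custom$bands), c("LOW", "MODERATE", "HIGH"))
})

test_that("localization score behaves on indicator and uniform maps", {
  mk <- function(v) structure(list(upsampled_map = v), class = "gradcam_result")
  v <- rep(0, 88); v[30:50] <- 1
  expect_gte(localization_score(mk(v), c(30, 50)), 1e10)
  expect_equal(localization_score(mk(rep(0.4, 88)), c(30, 50)), 1)
  expect_error(localization_score(mk(v), c(1, 88)), "whole window")
  expect_error(localization_score(mk(v), c(50, 30)), "empty")
})

test_that("fusion grad-cam produces per-modality maps from the fused logit", {
  pair <- fixture_window_pair(1, 60, seed = 71)
  be <- build_branch(branch_spec("ECG"), 1)
  bs <- build_branch(branch_spec("SPO2"), 2)
  fm <- build_fusion(be, bs, seed = 3)
  g_s <- gradcam_fusion(fm, pair$ecg$windows[1, ], pair$spo2$windows[1, ], "SPO2")
  g_e <- gradcam_fusion(fm, pair$ecg$windows[1, ], pair$spo2$windows[1, ], "ECG")
  expect_length(g_s$upsampled_map, 88L)
  expect_length(g_e$upsampled_map, 1100L)
  expect_true(all(g_s$raw_map >= 0))
})

test_that("export writes band table and plot", {
  pair <- fixture_window_pair(1, 60, seed = 73)
  m <- build_branch(branch_spec("SPO2"), seed = 2)
  res <- quantize_bands(gradcam(m, pair$spo2$windows[1, ], "apnea"))
  tsv <- file.path(tempdir(), "bands.tsv")
  png <- file.path(tempdir(), "bands.png")
  df <- export_gradcam(res, pair$spo2$windows[1, ], 8, png, tsv)
  expect_true(file.exists(tsv))
  expect_true(file.exists(png))
  tab <- utils::read.delim(tsv)
  expect_identical(nrow(tab), 88L)
  expect_true(all(tab$band %in% c("LOW", "MODERATE", "HIGH")))
})
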