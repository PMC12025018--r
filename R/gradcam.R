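#' 1D Grad-CAM for a branch model
#'
#' Channel weights are the temporal average of the gradient of the target
#' class score (the pre-softmax logit) with respect to the target conv layer's
#' activation maps: `a_c^k = (1/Z) sum_i dy^c / dA_i^k` with `Z = W`, the
#' temporal width (height is 1 in 1D). The raw map is
#' `L_c = ReLU(sum_k a_c^k A^k)`, linearly upsampled to the input length and
#' min-max normalized to `[0, 1]`.
#'
#' @param model A trained `nn_model`.
#' @param window Numeric vector, one input window.
#' @param target_class `"apnea"` or `"normal"` (or 1/0).
#' @param target_layer Index of the conv layer to explain; default the last
#'   conv layer (standard Grad-CAM practice). The layer's post-ReLU activation
#'   is used as the feature map.
#' @return A `gradcam_result`: `feature_maps` (W x K), `channel_weights` (K),
#'   `raw_map` (W, nonnegative), `upsampled_map` (input length, in `[0, 1]`),
#'   `target_class`, `Z`, plus `bands` once [quantize_bands()] has run.
#' @export
gradcam <- function(model, window, target_class = "apnea", target_layer = NULL) {
  stopifnot(inherits(model, "nn_model"))
  cls <- normalize_class(target_class)
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv", logical(1)))
  if (!length(conv_idx)) stop("model has no conv layer to explain", call. = FALSE)
  li <- if (is.null(target_layer)) conv_idx[length(conv_idx)] else as.integer(target_layer)
  if (!(li %in% conv_idx)) stop("target_layer must be a conv layer index", call. = FALSE)
  relu_idx <- li + 1L  # ReLU directly follows each conv in branch models
  if (model$layers[[relu_idx]]$type != "relu") relu_idx <- li
  X <- matrix(window, nrow = 1L)
  fwd <- nn_forward(model, X, train = FALSE, keep_cache = TRUE)
  logits <- fwd$out
  dTop <- matrix(0, 1L, ncol(logits))
  dTop[1L, cls + 1L] <- 1
  # activation maps at the explained layer (post-ReLU output)
  A <- replay_to_layer(model, X, relu_idx)
  if (length(dim(A)) != 3L || dim(A)[2] < 1L) {
    stop("target layer has no temporal extent", call. = FALSE)
  }
  bwd <- nn_backward(model, fwd$caches, dTop, stop_layer = relu_idx)
  dA <- bwd$dA  # gradient w.r.t. the post-ReLU maps, dims (1, W, K)
  W_len <- dim(A)[2]; K <- dim(A)[3]
  maps <- matrix(A[1L, , ], W_len, K)
  grads <- matrix(dA[1L, , ], W_len, K)
  a_k <- colMeans(grads)            # global average pooling, Z = W
  raw <- pmax(as.vector(maps %*% a_k), 0)
  up <- upsample_linear(raw, model$input_len)
  rng <- range(up)
  norm <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else rep(0, length(up))
  structure(list(feature_maps = maps, channel_weights = a_k, raw_map = raw,
                 upsampled_map = norm, bands = NULL, target_class = cls,
                 Z = W_len, degenerate = diff(rng) <= 0),
            class = "gradcam_result")
}

normalize_class <- function(target_class) {
  if (is.character(target_class)) {
    match(match.arg(target_class, c("normal", "apnea")), c("normal", "apnea")) - 1L
  } else as.integer(target_class)
}

# forward to (and including) layer `li`, eval mode
replay_to_layer <- function(model, X, li) {
  A <- array(X, c(nrow(X), ncol(X), 1L))
  for (i in seq_len(li)) {
    ly <- model$layers[[i]]
    A <- switch(ly$type,
      batchnorm = bn_fwd(ly, A, train = FALSE)$out,
      conv = conv_fwd(ly, A, model$padding, slot = i)$out,
      relu = pmax(A, 0),
      maxpool = pool_fwd(A)$out,
      flatten = matrix(aperm(A, c(1L, 3L, 2L)), dim(A)[1], dim(A)[2] * dim(A)[3]),
      dropout = A,
      dense = {
        Z <- A %*% ly$params$W + rep(ly$params$b, each = nrow(A))
        if (ly$activation == "relu") pmax(Z, 0) else Z
      })
  }
  A
}

upsample_linear <- function(v, n_out) {
  if (length(v) == 1L) return(rep(v, n_out))
  x <- seq(0, 1, length.out = length(v))
  stats::approx(x, v, xout = seq(0, 1, length.out = n_out), method = "linear")$y
}

#' Grad-CAM through the fusion model for one modality
#'
#' Computes the gradient of the fused model's class logit through the chosen
#' branch's last conv layer, yielding one heatmap per modality from a single
#' fused decision.
#'
#' @param fm A trained `fusion_model`.
#' @param ecg_window,spo2_window The aligned input pair (numeric vectors).
#' @param branch `"ECG"` or `"SPO2"`: which modality to explain.
#' @param target_class `"apnea"` or `"normal"`.
#' @return A `gradcam_result` for the chosen branch's input.
#' @export
gradcam_fusion <- function(fm, ecg_window, spo2_window, branch = c("SPO2", "ECG"),
                           target_class = "apnea") {
  stopifnot(inherits(fm, "fusion_model"))
  branch <- match.arg(branch)
  cls <- normalize_class(target_class)
  Xe <- matrix(ecg_window, 1L); Xs <- matrix(spo2_window, 1L)
  Fe <- branch_features(fm$branch_ecg, Xe)
  Fs <- branch_features(fm$branch_spo2, Xs)
  Fcat <- cbind(Fe, Fs)
  fwd <- nn_forward(fm$head, Fcat, keep_cache = TRUE)
  dTop <- matrix(0, 1L, 2L); dTop[1L, cls + 1L] <- 1
  dF <- nn_backward(fm$head, fwd$caches, dTop)$dA
  b <- if (branch == "ECG") fm$branch_ecg else fm$branch_spo2
  cols <- if (branch == "ECG") seq_len(fm$widths[1]) else fm$widths[1] + seq_len(fm$widths[2])
  X <- if (branch == "ECG") Xe else Xs
  # backprop the feature gradient through the branch down to its last conv ReLU
  conv_idx <- which(vapply(b$layers, function(l) l$type == "conv", logical(1)))
  li <- conv_idx[length(conv_idx)] + 1L  # post-ReLU
  # gradient at flatten output = head gradient for this branch's block;
  # upstream of flatten the branch's own dropout/dense layers are not involved
  sub_layers <- b$layers[seq_len(b$flatten_layer)]
  sub_model <- structure(list(layers = sub_layers, padding = b$padding,
                              input_len = b$input_len), class = "nn_model")
  sfwd <- nn_forward(sub_model, X, keep_cache = TRUE)
  dA <- nn_backward(sub_model, sfwd$caches, dF[, cols, drop = FALSE],
                    stop_layer = li)$dA
  A <- replay_to_layer(b, X, li)
  W_len <- dim(A)[2]; K <- dim(A)[3]
  maps <- matrix(A[1L, , ], W_len, K)
  grads <- matrix(dA[1L, , ], W_len, K)
  a_k <- colMeans(grads)
  raw <- pmax(as.vector(maps %*% a_k), 0)
  up <- upsample_linear(raw, b$input_len)
  rng <- range(up)
  norm <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else rep(0, length(up))
  structure(list(feature_maps = maps, channel_weights = a_k, raw_map = raw,
                 upsampled_map = norm, bands = NULL, target_class = cls,
                 Z = W_len, degenerate = diff(rng) <= 0),
            class = "gradcam_result")
}

#' Importance-band configuration
#'
#' Thresholds quantize the normalized heatmap into three bands with the
#' conventional palette: blue = LOW, red = MODERATE, green = HIGH importance.
#'
#' @param thresholds `(t_low, t_high)` with `0 < t_low < t_high < 1`
#'   (default `(1/3, 2/3)`).
#' @return A `band_config` object.
#' @export
band_config <- function(thresholds = c(1 / 3, 2 / 3)) {
  if (length(thresholds) != 2L || thresholds[1] <= 0 || thresholds[2] >= 1 ||
      thresholds[1] >= thresholds[2]) {
    stop("thresholds must satisfy 0 < t_low < t_high < 1", call. = FALSE)
  }
  structure(list(thresholds = thresholds,
                 palette = c(LOW = "blue", MODERATE = "red", HIGH = "green")),
            class = "band_config")
}

#' Quantize a normalized heatmap into importance bands
#'
#' Half-open bins: `[0, t_low)` LOW, `[t_low, t_high)` MODERATE,
#' `[t_high, 1]` HIGH. A degenerate (constant) map yields a single band with a
#' warning.
#'
#' @param result A `gradcam_result` with `upsampled_map` populated.
#' @param cfg A [band_config()].
#' @return The result with `bands` set (factor LOW/MODERATE/HIGH per sample).
#' @export
quantize_bands <- function(result, cfg = band_config()) {
  stopifnot(inherits(result, "gradcam_result"))
  v <- result$upsampled_map
  if (is.null(v)) stop("upsampled_map not populated", call. = FALSE)
  t1 <- cfg$thresholds[1]; t2 <- cfg$thresholds[2]
  bands <- ifelse(v < t1, "LOW", ifelse(v < t2, "MODERATE", "HIGH"))
  if (isTRUE(result$degenerate) || length(unique(bands)) == 1L &&
      diff(range(v)) == 0) {
    warning("degenerate (constant) heatmap: all samples fall in one band")
  }
  result$bands <- factor(bands, levels = c("LOW", "MODERATE", "HIGH"))
  result
}

#' Inside/outside importance ratio for a known event region
#'
#' Quantifies localization: the mean normalized importance inside the event
#' region divided by the mean outside (epsilon-guarded). A ratio above 1 means
#' the model concentrates importance on the event.
#'
#' @param result A `gradcam_result`.
#' @param event_region Integer sample interval `c(first, last)` (1-based,
#'   inclusive) within the window.
#' @param eps Guard against division by zero (default 1e-12).
#' @return The ratio (numeric scalar).
#' @export
localization_score <- function(result, event_region, eps = 1e-12) {
  stopifnot(inherits(result, "gradcam_result"))
  v <- result$upsampled_map
  n <- length(v)
  lo <- max(1L, as.integer(event_region[1]))
  hi <- min(n, as.integer(event_region[2]))
  if (hi < lo) stop("event region is empty", call. = FALSE)
  if (lo == 1L && hi == n) stop("event region covers the whole window; no outside samples", call. = FALSE)
  inside <- v[lo:hi]
  outside <- v[-(lo:hi)]
  mean(inside) / max(mean(outside), eps)
}

#' Export a banded heatmap overlay figure and band table
#'
#' Draws the trace colored by importance band over a color-bar legend and
#' writes the per-sample band assignments as a TSV next to it.
#'
#' @param result A banded `gradcam_result` (after [quantize_bands()]).
#' @param window The input window (numeric vector).
#' @param fs Sampling rate in Hz (for the time axis).
#' @param path_png Output PNG path (optional plot; skipped if NULL).
#' @param path_tsv Output TSV path for the band table (optional).
#' @return Invisibly, a data frame of sample, time, value, band.
#' @export
export_gradcam <- function(result, window, fs, path_png = NULL, path_tsv = NULL) {
  stopifnot(inherits(result, "gradcam_result"))
  if (is.null(result$bands)) result <- quantize_bands(result)
  t <- (seq_along(window) - 1) / fs
  df <- data.frame(sample = seq_along(window), time_s = t, value = window,
                   importance = result$upsampled_map, band = as.character(result$bands))
  if (!is.null(path_png)) {
    grDevices::png(path_png, width = 900, height = 300)
    on.exit(grDevices::dev.off())
    cols <- c(LOW = "blue", MODERATE = "red", HIGH = "green")[df$band]
    graphics::plot(t, window, type = "n", xlab = "time (s)", ylab = "signal",
                   main = sprintf("Grad-CAM bands (class %s)",
                                  c("normal", "apnea")[result$target_class + 1L]))
    graphics::segments(t[-length(t)], window[-length(window)], t[-1], window[-1],
                       col = cols[-length(cols)], lwd = 2)
    graphics::legend("topright", legend = names(c(LOW = 1, MODERATE = 2, HIGH = 3)),
                     col = c("blue", "red", "green"), lwd = 2, cex = 0.8)
  }
  if (!is.null(path_tsv)) {
    utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
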