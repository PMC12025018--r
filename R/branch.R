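#' Fixed branch architectures for the ECG and SpO2 models
#'
#' The two printed architectures: input batch normalization, three
#' convolution/max-pool stages, flatten, dropout 0.25, and a dense 2-unit
#' softmax head; ReLU everywhere else. ECG convs are (3 kernels, size 100,
#' stride 2), (50, 10, 1), (30, 30, 1); SpO2 convs are (6, 25, 1), (50, 10, 1),
#' (30, 15, 1). Max pooling is size 2, stride 2 after every conv.
#'
#' @param channel `"ECG"` or `"SPO2"`.
#' @param input_len Input window length in samples (defaults: 1100 for ECG at
#'   100 Hz, 88 for SpO2 at 8 Hz, both 11 s).
#' @param conv_layers List of `(n_kernels, kernel_size, stride)` triples;
#'   defaults to the printed stacks and normally should not be changed.
#' @param dropout_rate Dropout before the head (default 0.25).
#' @param padding `"same"` (default; the printed SpO2 stack is infeasible under
#'   `"valid"` padding at 8 Hz) or `"valid"`.
#' @return A `branch_spec` object.
#' @export
branch_spec <- function(channel = c("ECG", "SPO2"), input_len = NULL,
                        conv_layers = NULL, dropout_rate = 0.25,
                        padding = c("same", "valid")) {
  channel <- match.arg(channel)
  padding <- match.arg(padding)
  if (is.null(input_len)) input_len <- if (channel == "ECG") 1100L else 88L
  if (is.null(conv_layers)) {
    conv_layers <- if (channel == "ECG") {
      list(c(3L, 100L, 2L), c(50L, 10L, 1L), c(30L, 30L, 1L))
    } else {
      list(c(6L, 25L, 1L), c(50L, 10L, 1L), c(30L, 15L, 1L))
    }
  }
  structure(list(channel = channel, input_len = as.integer(input_len),
                 conv_layers = conv_layers, dropout_rate = dropout_rate,
                 padding = padding), class = "branch_spec")
}

#' Propagate shapes through a branch's conv/pool stack
#'
#' Returns the temporal length after each conv and pool stage and the flatten
#' width; errors (naming the failing layer) if any stage is infeasible, e.g.
#' a kernel longer than its input under `"valid"` padding.
#'
#' @param spec A [branch_spec()].
#' @return List with `stages` (data frame of per-stage lengths) and
#'   `flatten_width`.
#' @export
propagate_shape <- function(spec) {
  len <- spec$input_len
  stages <- data.frame(stage = character(), out_len = integer(), channels = integer())
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    out <- conv_out_len(len, cl[2], cl[3], spec$padding)
    if (is.na(out) || out < 1L) {
      stop(sprintf("conv%d (kernel %d) infeasible: input length %d under '%s' padding",
                   i, cl[2], len, spec$padding), call. = FALSE)
    }
    stages <- rbind(stages, data.frame(stage = sprintf("conv%d", i),
                                       out_len = out, channels = cl[1]))
    len <- out
    pooled <- len %/% 2L
    if (pooled < 1L) {
      stop(sprintf("pool after conv%d infeasible: input length %d", i, len),
           call. = FALSE)
    }
    stages <- rbind(stages, data.frame(stage = sprintf("pool%d", i),
                                       out_len = pooled, channels = cl[1]))
    len <- pooled
  }
  last <- spec$conv_layers[[length(spec$conv_layers)]]
  list(stages = stages, flatten_width = len * last[1])
}

#' Flatten width of a branch
#'
#' @param spec A [branch_spec()].
#' @return Integer neuron count at the flatten layer (2040 for the default ECG
#'   branch, 330 for SpO2).
#' @export
flatten_width <- function(spec) propagate_shape(spec)$flatten_width

#' Build a branch model
#'
#' Layer sequence: input batchnorm, then `conv -> ReLU -> maxpool` per conv
#' spec, flatten, dropout, dense 2-unit head (softmax applied at prediction).
#' Weight initialization is seeded.
#'
#' @param spec A [branch_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An `nn_model`.
#' @export
build_branch <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "branch_spec"))
  shape <- propagate_shape(spec)  # errors early if infeasible
  with_seed(seed, {
    layers <- list(layer_batchnorm(1L))
    c_in <- 1L
    for (cl in spec$conv_layers) {
      layers <- c(layers, list(layer_conv(cl[2], c_in, cl[1], cl[3]),
                               layer_relu(), layer_maxpool()))
      c_in <- cl[1]
    }
    layers <- c(layers, list(layer_flatten(),
                             layer_dropout(spec$dropout_rate),
                             layer_dense(shape$flatten_width, 2L)))
    structure(list(layers = layers, spec = spec, padding = spec$padding,
                   input_len = spec$input_len,
                   flatten_width = shape$flatten_width,
                   flatten_layer = length(layers) - 2L),
              class = "nn_model")
  })
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s branch: input %d, flatten %d, %d layers\n",
              x$spec$channel, x$input_len, x$flatten_width, length(x$layers)))
  invisible(x)
}

#' Selective dropout rates for multi-rate sensor fusion
#'
#' Dropout applied (during fusion training only) to the flatten features of the
#' denser modality, so the fusion head does not overfit to the sensor with the
#' higher sampling rate. Two modes:
#' \describe{
#'   \item{MATCHED_FS}{Structures matched to the rate ratio: the j-th branch
#'     gets `Dr_j = 1 - min(Fs) / Fs_j`, so the slowest sensor always gets 0.}
#'   \item{MISMATCHED_NEURONS}{Flatten widths do not follow the rate ratio
#'     (the case for the printed architectures: 2040 vs 330): the wider branch
#'     gets `Dr = 1 - neurons_low / neurons_high`, the narrower gets 0.}
#' }
#'
#' @param fs Per-branch sampling rates in Hz.
#' @param neurons Per-branch flatten widths.
#' @param mode `"MISMATCHED_NEURONS"` (default; matches the fixed
#'   architectures) or `"MATCHED_FS"`.
#' @return A `dropout_plan`: list with `rates`, `fs`, `neurons`, `mode`.
#' @export
selective_dropout_rates <- function(fs, neurons,
                                    mode = c("MISMATCHED_NEURONS", "MATCHED_FS")) {
  mode <- match.arg(mode)
  if (length(fs) != length(neurons)) stop("fs and neurons must have equal length", call. = FALSE)
  if (any(fs <= 0) || any(neurons <= 0)) stop("fs and neurons must be positive", call. = FALSE)
  if (length(fs) == 1L) {
    warning("single branch: selective dropout is a no-op")
    rates <- 0
  } else if (mode == "MATCHED_FS") {
    rates <- 1 - min(fs) / fs
  } else {
    rates <- 1 - min(neurons) / neurons
  }
  structure(list(rates = rates, fs = fs, neurons = neurons, mode = mode),
            class = "dropout_plan")
}

#' Fusion plan
#'
#' @param head_hidden Widths of the trainable dense layers between the
#'   concatenated flatten features and the 2-unit softmax output (default 64;
#'   a tuning knob, not a printed value).
#' @param dropout_plan A `dropout_plan` from [selective_dropout_rates()], or
#'   NULL to derive one from the branches at fusion time.
#' @return A `fusion_plan` object.
#' @export
fusion_plan <- function(head_hidden = 64L, dropout_plan = NULL) {
  structure(list(head_hidden = as.integer(head_hidden), dropout_plan = dropout_plan),
            class = "fusion_plan")
}

#' Build the fused model from two trained branches
#'
#' Removes both output heads, concatenates the flatten features (ECG first),
#' attaches a new dense head, and freezes every pre-concatenation parameter.
#' Selective dropout (per the plan) is applied to the designated branch's
#' flatten features during fusion training only, with inverted scaling so
#' inference is scale-consistent and dropout-free.
#'
#' @param branch_ecg,branch_spo2 Trained `nn_model`s.
#' @param plan A [fusion_plan()].
#' @param fs_pair Sampling rates (ECG, SpO2) used when deriving a dropout plan.
#' @param seed Seed for head weight initialization.
#' @return A `fusion_model`.
#' @export
build_fusion <- function(branch_ecg, branch_spo2, plan = fusion_plan(),
                         fs_pair = c(100, 8), seed = 1L) {
  stopifnot(inherits(branch_ecg, "nn_model"), inherits(branch_spo2, "nn_model"))
  widths <- c(branch_ecg$flatten_width, branch_spo2$flatten_width)
  dp <- plan$dropout_plan
  if (is.null(dp)) {
    dp <- selective_dropout_rates(fs_pair, widths)
  } else if (!all(dp$neurons == widths)) {
    stop(sprintf("dropout plan widths (%s) inconsistent with branch flatten widths (%s)",
                 paste(dp$neurons, collapse = ", "),
                 paste(widths, collapse = ", ")), call. = FALSE)
  }
  concat <- sum(widths)
  with_seed(seed, {
    head_layers <- list()
    n_in <- concat
    for (h in plan$head_hidden) {
      head_layers <- c(head_layers, list(layer_dense(n_in, h, activation = "relu")))
      n_in <- h
    }
    head_layers <- c(head_layers, list(layer_dense(n_in, 2L)))
    head <- structure(list(layers = head_layers, input_len = concat,
                           spec = list(channel = "FUSION"),
                           padding = "same"), class = "nn_model")
    structure(list(branch_ecg = branch_ecg, branch_spo2 = branch_spo2,
                   head = head, dropout_plan = dp, widths = widths,
                   concat_width = concat, plan = plan),
              class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> concat width %d (ECG %d + SpO2 %d), dropout rates [%s], mode %s\n",
              x$concat_width, x$widths[1], x$widths[2],
              paste(sprintf("%.3f", x$dropout_plan$rates), collapse = ", "),
              x$dropout_plan$mode))
  invisible(x)
}

# Frozen-branch forward to the flatten layer (eval mode, dropout inactive).
# Chunked to bound the conv patch-buffer size.
branch_features <- function(branch, X) {
  do.call(rbind, lapply(chunk_indices(nrow(X)), function(idx) {
    branch_features_block(branch, X[idx, , drop = FALSE])
  }))
}

branch_features_block <- function(branch, X) {
  A <- array(X, c(nrow(X), ncol(X), 1L))
  for (i in seq_len(branch$flatten_layer)) {
    ly <- branch$layers[[i]]
    A <- switch(ly$type,
      batchnorm = bn_fwd(ly, A, train = FALSE)$out,
      conv = conv_fwd(ly, A, branch$padding, slot = i)$out,
      relu = pmax(A, 0),
      maxpool = pool_fwd(A)$out,
      flatten = matrix(aperm(A, c(1L, 3L, 2L)), dim(A)[1], dim(A)[2] * dim(A)[3]),
      stop("unexpected layer before flatten: ", ly$type))
  }
  A
}

fusion_features <- function(fm, ecg_X, spo2_X) {
  cbind(branch_features(fm$branch_ecg, ecg_X),
        branch_features(fm$branch_spo2, spo2_X))
}

# Apply selective dropout masks to concatenated features (training only).
apply_selective_dropout <- function(F, fm) {
  rates <- fm$dropout_plan$rates
  offs <- c(0, cumsum(fm$widths))
  for (j in seq_along(rates)) {
    if (rates[j] <= 0) next
    cols <- (offs[j] + 1L):offs[j + 1L]
    mask <- matrix(stats::runif(nrow(F) * length(cols)) >= rates[j], nrow(F)) /
      (1 - rates[j])
    F[, cols] <- F[, cols] * mask
  }
  F
}

#' Train the fusion head (branches frozen)
#'
#' Branch parameters are frozen: flatten features are computed once in eval
#' mode and only the head's dense layers are updated. Selective dropout is
#' applied to the designated feature block each training batch.
#'
#' @param fm A `fusion_model` from [build_fusion()].
#' @param train_pair,val_pair Lists with aligned `ecg` and `spo2`
#'   [window_set()]s (labels taken from the ECG set).
#' @param hyper A [train_hyper()].
#' @param seed Integer seed.
#' @return List with `model` (trained fusion model) and `history`.
#' @export
train_fusion <- function(fm, train_pair, val_pair, hyper = train_hyper(), seed = 1L) {
  stopifnot(inherits(fm, "fusion_model"))
  check_aligned_pair(train_pair)
  check_aligned_pair(val_pair)
  Ftr <- fusion_features(fm, train_pair$ecg$windows, train_pair$spo2$windows)
  Fva <- fusion_features(fm, val_pair$ecg$windows, val_pair$spo2$windows)
  y <- train_pair$ecg$labels
  yv <- val_pair$ecg$labels
  head <- fm$head
  history <- data.frame()
  if (hyper$epochs > 0L) {
    res <- with_seed(seed, {
      opt <- adam_init(nn_params(head))
      best <- list(loss = Inf, params = nn_params(head), wait = 0L)
      history <- data.frame()
      for (epoch in seq_len(hyper$epochs)) {
        perm <- sample.int(nrow(Ftr))
        n_batches <- ceiling(nrow(Ftr) / hyper$batch_size)
        tot_loss <- 0; tot_correct <- 0
        for (bi in seq_len(n_batches)) {
          idx <- perm[(((bi - 1L) * hyper$batch_size) + 1L):min(bi * hyper$batch_size, nrow(Ftr))]
          Fb <- apply_selective_dropout(Ftr[idx, , drop = FALSE], fm)
          yb <- y[idx]
          fwd <- nn_forward(head, Fb, train = TRUE, keep_cache = TRUE)
          P <- softmax_rows(fwd$out)
          loss <- cross_entropy(P, yb)
          if (!is.finite(loss)) stop("fusion head training diverged (non-finite loss)", call. = FALSE)
          tot_loss <- tot_loss + loss * length(idx)
          tot_correct <- tot_correct + sum(max.col(P) - 1L == yb)
          Y <- matrix(0, length(yb), 2L); Y[cbind(seq_along(yb), yb + 1L)] <- 1
          bwd <- nn_backward(head, fwd$caches, (P - Y) / length(yb))
          upd <- adam_step(nn_params(head), bwd$grads, opt, lr = hyper$lr)
          head <- nn_set_params(head, upd$params)
          opt <- upd$state
        }
        Pv <- softmax_rows(nn_forward(head, Fva)$out)
        val_loss <- cross_entropy(Pv, yv)
        history <- rbind(history, data.frame(
          epoch = epoch, loss = tot_loss / nrow(Ftr), acc = tot_correct / nrow(Ftr),
          val_loss = val_loss, val_acc = mean(max.col(Pv) - 1L == yv)))
        if (val_loss < best$loss - 1e-9) {
          best$loss <- val_loss; best$params <- nn_params(head); best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
          if (best$wait >= hyper$patience) break
        }
      }
      list(head = nn_set_params(head, best$params), history = history)
    })
    head <- res$head
    history <- res$history
  }
  fm$head <- head
  list(model = fm, history = history)
}

#' Predict class probabilities from the fusion model
#'
#' Inference is dropout-free: inverted scaling during training makes the clean
#' forward pass scale-consistent, so every flatten feature contributes.
#'
#' @param fm A `fusion_model`.
#' @param ecg_X,spo2_X Aligned window matrices.
#' @return `n x 2` softmax probability matrix.
#' @export
fusion_predict <- function(fm, ecg_X, spo2_X) {
  F <- fusion_features(fm, ecg_X, spo2_X)
  softmax_rows(nn_forward(fm$head, F)$out)
}

check_aligned_pair <- function(pair) {
  if (!is.list(pair) || !all(c("ecg", "spo2") %in% names(pair))) {
    stop("expected a list with `ecg` and `spo2` window sets", call. = FALSE)
  }
  if (n_windows(pair$ecg) != n_windows(pair$spo2) ||
      !isTRUE(all.equal(pair$ecg$start_times_s, pair$spo2$start_times_s)) ||
      !identical(pair$ecg$source_ids, pair$spo2$source_ids)) {
    stop("ECG/SpO2 window sets are misaligned (start times or sources differ)",
         call. = FALSE)
  }
  if (!identical(pair$ecg$labels, pair$spo2$labels)) {
    stop("ECG/SpO2 window sets carry different labels", call. = FALSE)
  }
  invisible(pair)
}

#' Save / load a model checkpoint with an architecture manifest
#'
#' Parameters are written as plain text (one value per line, full precision)
#' next to a JSON manifest recording the branch specs, fusion plan, dropout
#' plan and seeds, so a checkpoint is reproducible and diffable.
#'
#' @param model An `nn_model` or `fusion_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- nn_param_vector_full(model)
  writeLines(sprintf("%.17g", v), file.path(dir, "params.txt"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- if (inherits(model, "fusion_model")) {
    list(kind = "fusion", ecg_spec = strip(model$branch_ecg$spec),
         spo2_spec = strip(model$branch_spo2$spec),
         head_hidden = model$plan$head_hidden,
         dropout_plan = strip(model$dropout_plan[c("rates", "fs", "neurons", "mode")]))
  } else {
    list(kind = "branch", spec = strip(model$spec))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# full parameter vector including head for fusion models
nn_param_vector_full <- function(model) {
  if (inherits(model, "fusion_model")) {
    c(nn_param_vector(model$branch_ecg), nn_param_vector(model$branch_spo2),
      nn_param_vector(model$head))
  } else nn_param_vector(model)
}
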