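# Minimal 1D-CNN engine on BLAS matrix ops.
#
# Activations flow as 3D arrays (batch, length, channels) until the flatten
# layer, then as (batch, features) matrices. Convolutions use im2col so the
# inner loop is a single dgemm. Every layer implements fwd(layer, A, train)
# returning list(out, cache) and bwd(layer, cache, dOut) returning
# list(dA, grads). Parameters live in layer$params; gradients mirror them.

nn_layer <- function(type, params = list(), ...) {
  structure(c(list(type = type, params = params), list(...)), class = "nn_layer")
}

# He-uniform init, seeded by the caller
init_mat <- function(nr, nc, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

layer_batchnorm <- function(channels = 1L, momentum = 0.9, eps = 1e-5) {
  nn_layer("batchnorm",
           params = list(gamma = rep(1, channels), beta = rep(0, channels)),
           run_mean = rep(0, channels), run_var = rep(1, channels),
           momentum = momentum, eps = eps)
}

layer_conv <- function(kernel, c_in, c_out, stride = 1L) {
  W <- array(init_mat(kernel * c_in, c_out, kernel * c_in), c(kernel, c_in, c_out))
  nn_layer("conv", params = list(W = W, b = rep(0, c_out)),
           kernel = kernel, c_in = c_in, c_out = c_out, stride = as.integer(stride))
}

layer_relu <- function() nn_layer("relu")
layer_maxpool <- function() nn_layer("maxpool")
layer_flatten <- function() nn_layer("flatten")
layer_dropout <- function(rate) nn_layer("dropout", rate = rate)

layer_dense <- function(n_in, n_out, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  nn_layer("dense", params = list(W = init_mat(n_in, n_out, n_in), b = rep(0, n_out)),
           n_in = n_in, n_out = n_out, activation = activation)
}

conv_out_len <- function(len, kernel, stride, padding) {
  if (padding == "same") return(as.integer(ceiling(len / stride)))
  if (len < kernel) return(NA_integer_)
  as.integer(floor((len - kernel) / stride) + 1L)
}

# Convolution forward/backward live in src/conv.cpp: the patch (im2col)
# matrix is built into a persistent per-slot C++ buffer and consumed by BLAS
# dgemm; the backward pass of the same batch re-reads it. `slot` is the
# layer's position in its model, unique among the conv layers active between
# one forward and its matching backward.
conv_fwd <- function(layer, A, padding = "same", slot = layer$slot %||% 0L) {
  d <- dim(A); n <- d[1]; len <- d[2]; c_in <- d[3]
  k <- layer$kernel; stride <- layer$stride; c_out <- layer$c_out
  out_len <- conv_out_len(len, k, stride, padding)
  if (is.na(out_len) || out_len < 1L) {
    stop(sprintf("conv layer (kernel %d) infeasible for input length %d under '%s' padding",
                 k, len, padding), call. = FALSE)
  }
  if (padding == "same") {
    pad_total <- max(0L, (out_len - 1L) * stride + k - len)
  } else pad_total <- 0L
  pl <- pad_total %/% 2L
  lenp <- len + pad_total
  if (pad_total > 0L) {
    Ap <- array(0, c(n, lenp, c_in))
    Ap[, pl + seq_len(len), ] <- A
  } else Ap <- A
  starts <- as.integer((seq_len(out_len) - 1L) * stride)
  Wm <- layer$params$W
  dim(Wm) <- c(k * c_in, c_out)
  Z <- .conv_fwd_cpp(Ap, n, lenp, c_in, k, starts, Wm, layer$params$b, slot)
  list(out = Z, cache = list(dims = d, out_len = out_len, pl = pl,
                             lenp = lenp, starts = starts, slot = slot))
}

conv_bwd <- function(layer, cache, dOut) {
  d <- cache$dims; n <- d[1]; len <- d[2]; c_in <- d[3]
  k <- layer$kernel; c_out <- layer$c_out
  Wm <- layer$params$W
  dim(Wm) <- c(k * c_in, c_out)
  res <- .conv_bwd_cpp(dOut, n, cache$lenp, c_in, k, cache$starts, Wm,
                       cache$slot)
  dA <- res$dAp[, cache$pl + seq_len(len), , drop = FALSE]
  list(dA = dA, grads = list(W = array(res$dW, dim(layer$params$W)),
                             b = res$db))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bn_fwd <- function(layer, A, train) {
  d <- dim(A); ch <- d[3]
  out <- A
  cache <- list(dims = d)
  if (train) {
    mu <- numeric(ch); va <- numeric(ch); xhat <- A
    for (c in seq_len(ch)) {
      x <- A[, , c]
      mu[c] <- mean(x)
      va[c] <- mean((x - mu[c])^2)
      xh <- (x - mu[c]) / sqrt(va[c] + layer$eps)
      xhat[, , c] <- xh
      out[, , c] <- layer$params$gamma[c] * xh + layer$params$beta[c]
    }
    cache$mu <- mu; cache$va <- va; cache$xhat <- xhat
    cache$new_run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    cache$new_run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
  } else {
    for (c in seq_len(ch)) {
      xh <- (A[, , c] - layer$run_mean[c]) / sqrt(layer$run_var[c] + layer$eps)
      out[, , c] <- layer$params$gamma[c] * xh + layer$params$beta[c]
    }
  }
  list(out = out, cache = cache)
}

bn_bwd <- function(layer, cache, dOut) {
  d <- cache$dims; ch <- d[3]; m <- d[1] * d[2]
  dA <- dOut
  dgamma <- numeric(ch); dbeta <- numeric(ch)
  for (c in seq_len(ch)) {
    dy <- dOut[, , c]
    xh <- cache$xhat[, , c]
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    inv_sd <- 1 / sqrt(cache$va[c] + layer$eps)
    dxh <- dy * layer$params$gamma[c]
    dA[, , c] <- inv_sd * (dxh - mean(dxh) - xh * mean(dxh * xh))
  }
  list(dA = dA, grads = list(gamma = dgamma, beta = dbeta))
}

pool_fwd <- function(A) {
  d <- dim(A); out_len <- d[2] %/% 2L
  i1 <- seq(1L, 2L * out_len, by = 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  take1 <- A1 >= A2
  out <- pmax(A1, A2)
  dim(out) <- c(d[1], out_len, d[3])
  list(out = out, cache = list(dims = d, out_len = out_len, take1 = take1, i1 = i1))
}

pool_bwd <- function(cache, dOut) {
  d <- cache$dims
  dA <- array(0, d)
  d1 <- dOut * cache$take1
  d2 <- dOut * !cache$take1
  dA[, cache$i1, ] <- d1
  dA[, cache$i1 + 1L, ] <- d2
  dA
}

# Forward pass through a stack of layers.
# X: (n, len) input matrix (single-channel). Returns logits plus caches.
nn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  n <- nrow(X)
  # dense-only models (fusion heads) consume the feature matrix directly;
  # conv stacks get a (batch, length, channel) array
  A <- if (model$layers[[1]]$type == "dense") X else array(X, c(n, ncol(X), 1L))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      batchnorm = bn_fwd(ly, A, train),
      conv = conv_fwd(ly, A, model$padding, slot = i),
      relu = list(out = pmax(A, 0), cache = list(mask = A > 0)),
      maxpool = pool_fwd(A),
      flatten = {
        d <- dim(A)
        out <- matrix(aperm(A, c(1L, 3L, 2L)), d[1], d[2] * d[3])
        list(out = out, cache = list(dims = d))
      },
      dropout = {
        if (train && ly$rate > 0) {
          mask <- matrix(stats::runif(length(A)) >= ly$rate, nrow(A)) / (1 - ly$rate)
          list(out = A * mask, cache = list(mask = mask))
        } else list(out = A, cache = list(mask = NULL))
      },
      dense = {
        Z <- A %*% ly$params$W + rep(ly$params$b, each = nrow(A))
        out <- if (ly$activation == "relu") pmax(Z, 0) else Z
        list(out = out, cache = list(A = A, Z = Z))
      },
      stop("unknown layer type: ", ly$type)
    )
    A <- res$out
    if (keep_cache) caches[[i]] <- res$cache
    if (train && ly$type == "batchnorm") {
      # stash updated running stats in the cache for the training loop to commit
      caches[[i]] <- res$cache
    }
  }
  list(out = A, caches = caches)
}

# Backward pass from dTop (gradient w.r.t. final layer output) down to
# stop_layer (exclusive); returns per-layer grads and the gradient at the
# output of stop_layer (or the input if stop_layer = 0).
nn_backward <- function(model, caches, dTop, stop_layer = 0L) {
  grads <- vector("list", length(model$layers))
  dA <- dTop
  for (i in rev(seq_along(model$layers))) {
    if (i <= stop_layer) break
    ly <- model$layers[[i]]
    cache <- caches[[i]]
    res <- switch(ly$type,
      batchnorm = bn_bwd(ly, cache, dA),
      conv = conv_bwd(ly, cache, dA),
      relu = list(dA = dA * cache$mask, grads = NULL),
      maxpool = list(dA = pool_bwd(cache, dA), grads = NULL),
      flatten = {
        d <- cache$dims
        dArr <- array(dA, c(d[1], d[3], d[2]))
        list(dA = aperm(dArr, c(1L, 3L, 2L)), grads = NULL)
      },
      dropout = {
        if (!is.null(cache$mask)) list(dA = dA * cache$mask, grads = NULL)
        else list(dA = dA, grads = NULL)
      },
      dense = {
        dZ <- if (ly$activation == "relu") dA * (cache$Z > 0) else dA
        list(dA = tcrossprod(dZ, ly$params$W),
             grads = list(W = crossprod(cache$A, dZ), b = colSums(dZ)))
      }
    )
    dA <- res$dA
    grads[i] <- list(res$grads)  # [[<-]] with NULL would drop the slot
  }
  list(grads = grads, dA = dA)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Predict class probabilities from a branch model
#'
#' Inference runs in chunks (option `apneafusion.chunk`, default 256 windows)
#' to bound the size of the convolution patch buffers.
#'
#' @param model An `nn_model` (see [build_branch()]).
#' @param X Window matrix (`n x input_len`).
#' @return `n x 2` matrix of softmax probabilities (columns: normal, apnea).
#' @export
nn_predict <- function(model, X) {
  do.call(rbind, lapply(chunk_indices(nrow(X)), function(idx) {
    softmax_rows(nn_forward(model, X[idx, , drop = FALSE], train = FALSE)$out)
  }))
}

chunk_indices <- function(n, size = getOption("apneafusion.chunk", 256L)) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# ---- parameter plumbing ------------------------------------------------------

nn_params <- function(model) {
  lapply(model$layers, function(ly) ly$params)
}

nn_set_params <- function(model, params) {
  for (i in seq_along(params)) model$layers[[i]]$params <- params[[i]]
  model
}

#' Flatten all model parameters into one numeric vector
#'
#' Used for freezing checks: two models have identical parameters iff their
#' vectors are `identical()`.
#'
#' @param model An `nn_model` or `fusion_model`.
#' @return Numeric vector of all parameters (and batchnorm running stats).
#' @export
nn_param_vector <- function(model) {
  if (inherits(model, "fusion_model")) {
    return(c(nn_param_vector(model$branch_ecg), nn_param_vector(model$branch_spo2)))
  }
  unlist(lapply(model$layers, function(ly) {
    c(unlist(ly$params, use.names = FALSE),
      if (ly$type == "batchnorm") c(ly$run_mean, ly$run_var))
  }), use.names = FALSE)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- training ----------------------------------------------------------------

#' Training hyperparameters
#'
#' None of these are printed in the source architecture; all are exposed here.
#'
#' @param epochs Maximum epochs (default 10).
#' @param batch_size Minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience on validation loss (default 3).
#' @return A list of hyperparameters.
#' @export
train_hyper <- function(epochs = 10L, batch_size = 64L, lr = 1e-3, patience = 3L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, patience = as.integer(patience))
}

cross_entropy <- function(P, y) {
  p <- P[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a branch model with Adam and early stopping
#'
#' Deterministic given `seed` (shuffling and dropout are the only stochastic
#' elements). Stops early when validation loss fails to improve for `patience`
#' epochs and restores the best-validation parameters. Aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param model An `nn_model` from [build_branch()].
#' @param train A labeled [window_set()].
#' @param val Validation [window_set()].
#' @param hyper A [train_hyper()] list.
#' @param seed Integer seed.
#' @return List with `model` (trained) and `history` (per-epoch data frame:
#'   loss, acc, val_loss, val_acc).
#' @export
train_branch <- function(model, train, val, hyper = train_hyper(), seed = 1L) {
  stopifnot(inherits(model, "nn_model"))
  X <- train$windows; y <- train$labels
  Xv <- val$windows; yv <- val$labels
  if (ncol(X) != model$input_len) {
    stop(sprintf("training windows have %d samples; model expects %d",
                 ncol(X), model$input_len), call. = FALSE)
  }
  history <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  if (hyper$epochs == 0L) return(list(model = model, history = history))
  with_seed(seed, {
    opt <- adam_init(nn_params(model))
    best <- list(loss = Inf, params = nn_params(model), bn = NULL, wait = 0L)
    for (epoch in seq_len(hyper$epochs)) {
      perm <- sample.int(nrow(X))
      n_batches <- ceiling(nrow(X) / hyper$batch_size)
      tot_loss <- 0; tot_correct <- 0
      for (bi in seq_len(n_batches)) {
        idx <- perm[(((bi - 1L) * hyper$batch_size) + 1L):min(bi * hyper$batch_size, nrow(X))]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        fwd <- nn_forward(model, Xb, train = TRUE, keep_cache = TRUE)
        P <- softmax_rows(fwd$out)
        loss <- cross_entropy(P, yb)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d batch %d",
                       epoch, bi), call. = FALSE)
        }
        tot_loss <- tot_loss + loss * length(idx)
        tot_correct <- tot_correct + sum(max.col(P) - 1L == yb)
        Y <- matrix(0, length(yb), 2L); Y[cbind(seq_along(yb), yb + 1L)] <- 1
        dlogits <- (P - Y) / length(yb)
        bwd <- nn_backward(model, fwd$caches, dlogits)
        upd <- adam_step(nn_params(model), bwd$grads, opt, lr = hyper$lr)
        model <- nn_set_params(model, upd$params)
        opt <- upd$state
        # commit batchnorm running stats
        for (li in seq_along(model$layers)) {
          if (model$layers[[li]]$type == "batchnorm") {
            model$layers[[li]]$run_mean <- fwd$caches[[li]]$new_run_mean
            model$layers[[li]]$run_var <- fwd$caches[[li]]$new_run_var
          }
        }
      }
      Pv <- nn_predict(model, Xv)
      val_loss <- cross_entropy(Pv, yv)
      val_acc <- mean(max.col(Pv) - 1L == yv)
      history <- rbind(history, data.frame(
        epoch = epoch, loss = tot_loss / nrow(X), acc = tot_correct / nrow(X),
        val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss - 1e-9) {
        best$loss <- val_loss
        best$params <- nn_params(model)
        best$bn <- lapply(model$layers, function(ly)
          if (ly$type == "batchnorm") list(m = ly$run_mean, v = ly$run_var))
        best$wait <- 0L
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= hyper$patience) break
      }
    }
    model <- nn_set_params(model, best$params)
    if (!is.null(best$bn)) {
      for (li in seq_along(model$layers)) {
        if (!is.null(best$bn[[li]])) {
          model$layers[[li]]$run_mean <- best$bn[[li]]$m
          model$layers[[li]]$run_var <- best$bn[[li]]$v
        }
      }
    }
    list(model = model, history = history)
  })
}
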