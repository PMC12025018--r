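#' Bandpass filter configuration
#'
#' Diagnostic-band ECG defaults: 1-40 Hz passband, removing baseline drift and
#' high-frequency noise. Order is the analog prototype order (the bandpass
#' transform doubles it); zero-phase applies the filter forward and backward so
#' QRS latencies are preserved for heatmap overlays.
#'
#' @param low_hz Lower cutoff in Hz (default 1).
#' @param high_hz Upper cutoff in Hz (default 40).
#' @param order Prototype order (default 4).
#' @param zero_phase Apply forward-backward (default TRUE).
#' @return A `filter_config` object.
#' @export
filter_config <- function(low_hz = 1, high_hz = 40, order = 4L, zero_phase = TRUE) {
  assert_scalar_num(low_hz, "low_hz", lower = 1e-9)
  assert_scalar_num(high_hz, "high_hz", lower = 1e-9)
  if (low_hz >= high_hz) stop("low_hz must be < high_hz", call. = FALSE)
  assert_scalar_num(order, "order", lower = 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)), class = "filter_config")
}

#' Design a digital Butterworth bandpass filter
#'
#' Classic zpk route: analog lowpass prototype poles, lowpass-to-bandpass
#' transform about the prewarped band edges, bilinear transform. Returns
#' transfer-function coefficients `b`, `a` (the bandpass filter has order
#' `2 * order`).
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param fs Sampling rate in Hz; requires `high_hz < fs / 2`.
#' @param order Prototype order.
#' @return List with numeric vectors `b` and `a` (length `2 * order + 1`).
#' @export
butter_bandpass <- function(low_hz, high_hz, fs, order = 4L) {
  if (high_hz >= fs / 2) {
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency %g", high_hz, fs / 2),
         call. = FALSE)
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz", call. = FALSE)
  order <- as.integer(order)
  # analog Butterworth prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # prewarped band edges for the bilinear transform
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each prototype pole spawns a conjugate pair
  ph <- p * bw / 2
  rt <- sqrt(ph^2 - w0^2)
  poles_s <- c(ph + rt, ph - rt)
  gain_s <- bw^order                       # order zeros at s = 0, order at Inf
  # bilinear transform to the z-plane
  pz <- (1 + poles_s / fs2) / (1 - poles_s / fs2)
  zz <- c(rep(1, order), rep(-1, order))   # s-zeros at 0 -> z = 1; at Inf -> z = -1
  # gain through bilinear: k_z = k_s * Re(prod(fs2 - zeros_s) / prod(fs2 - poles_s));
  # the bandpass has `order` s-zeros at 0, each contributing a factor fs2
  gain_z <- gain_s * Re(fs2^order / prod(fs2 - poles_s))
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(zz)) * gain_z
  list(b = b, a = a)
}

# expand prod (x - r_i) into descending-power coefficients
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

#' Complex frequency response of a digital filter
#'
#' @param b,a Transfer-function coefficients.
#' @param f_hz Frequencies at which to evaluate, in Hz.
#' @param fs Sampling rate in Hz.
#' @return Complex vector `H(e^{i 2 pi f / fs})`.
#' @export
freq_response <- function(b, a, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  z <- exp(-1i * w)
  num <- vapply(seq_along(w), function(i) sum(b * z[i]^(seq_along(b) - 1)), complex(1))
  den <- vapply(seq_along(w), function(i) sum(a * z[i]^(seq_along(a) - 1)), complex(1))
  num / den
}

# single-pass IIR filtering via stats::filter (convolution for the MA part,
# recursive for the AR part). Initial conditions assume the signal sat at x[1]
# forever, i.e. steady-state startup (the role scipy's lfilter_zi plays in
# filtfilt), which removes edge transients on constant inputs exactly.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(x[1], nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  y_ss <- x[1] * sum(b) / sum(a)
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(y_ss, length(a) - 1L))
  as.numeric(y)
}

#' Zero-phase forward-backward filtering
#'
#' Odd-reflection edge padding (3x the filter length, as in common
#' implementations) suppresses startup transients; the signal is filtered
#' forward, reversed, filtered again and reversed back, squaring the magnitude
#' response and cancelling phase.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

#' Bandpass-filter every window of a window set
#'
#' @param set A [window_set()].
#' @param cfg A [filter_config()].
#' @return A [window_set()] of identical shape with filtered rows.
#' @export
bandpass <- function(set, cfg = filter_config()) {
  stopifnot(inherits(set, "window_set"), inherits(cfg, "filter_config"))
  coef <- butter_bandpass(cfg$low_hz, cfg$high_hz, set$fs, cfg$order)
  W <- set$windows
  for (i in seq_len(nrow(W))) {
    W[i, ] <- if (cfg$zero_phase) filtfilt_zp(coef$b, coef$a, W[i, ]) else
      iir_filter(coef$b, coef$a, W[i, ])
  }
  out <- set
  out$windows <- W
  out
}
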