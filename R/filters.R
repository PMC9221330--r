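# Filtering primitives. Second-order (biquad) IIR sections applied
# forward-backward for zero phase; Gaussian / sliding-average smoothing for the
# slow channels; a db4 discrete wavelet transform with soft universal
# thresholding for baseline-noise reduction.

# --- biquad design (audio-cookbook forms, Butterworth Q for LP/HP) ----------

biquad <- function(type = c("lowpass", "highpass", "notch"), f0, fs, Q) {
  type <- match.arg(type)
  if (missing(Q)) Q <- if (type == "notch") 30 else 1 / sqrt(2)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  cw <- cos(w0)
  coefs <- switch(type,
    lowpass = list(b = c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)),
    highpass = list(b = c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)),
    notch = list(b = c(1, -2 * cw, 1)))
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = coefs$b / a[1], a = a / a[1], type = type, f0 = f0, fs = fs, Q = Q)
}

# Direct-form IIR: MA part via one-sided convolution, AR part via the
# recursive filter (both in C inside stats::filter).
iir_apply <- function(b, a, x) {
  n <- length(x)
  xp <- c(rep(0, length(b) - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):(length(b) - 1 + n)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Zero-phase application: odd-reflection padding, forward pass, reverse pass.
filtfilt_biquad <- function(bq, x, pad_s = 3) {
  n <- length(x)
  if (n < 4) return(x)
  p <- min(n - 1, max(8, round(pad_s * bq$fs)))
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  xp <- c(left, x, right)
  y <- iir_apply(bq$b, bq$a, xp)
  y <- rev(iir_apply(bq$b, bq$a, rev(y)))
  y[(p + 1):(p + n)]
}

# --- smoothing kernels -------------------------------------------------------

kernel_smooth <- function(x, kernel) {
  n <- length(x)
  r <- (length(kernel) - 1) / 2
  if (n <= 2 * r + 1) return(rep(mean(x), n))
  xp <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])  # even reflection
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y)[(r + 1):(r + n)]
}

#' Gaussian smoothing
#' @param x numeric signal.
#' @param rate sampling rate (Hz).
#' @param sigma_s kernel SD in seconds.
#' @return smoothed signal, same length.
#' @export
gaussian_smooth <- function(x, rate, sigma_s = 0.25) {
  sigma <- sigma_s * rate
  r <- max(1, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  kernel_smooth(x, k / sum(k))
}

#' Centered sliding-average smoothing
#' @inheritParams gaussian_smooth
#' @param width_s window width in seconds.
#' @export
sliding_average <- function(x, rate, width_s = 1) {
  w <- max(1, round(width_s * rate))
  if (w %% 2 == 0) w <- w + 1
  kernel_smooth(x, rep(1 / w, w))
}

# --- db4 wavelet denoising ---------------------------------------------------

# 8-tap Daubechies-4 decomposition lowpass (least-asymmetric ordering).
db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                0.030841381835986965, -0.187034811718881140,
                -0.027983769416983850, 0.630880767929590400,
                0.714846570552541500, 0.230377813308855230)

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n / 2
  i2 <- 2 * (seq_len(half) - 1)  # 0-based even anchors
  a <- numeric(half)
  d <- numeric(half)
  L <- length(lo)
  for (k in seq_len(L)) {
    idx <- (i2 + (k - 1)) %% n + 1
    a <- a + lo[k] * x[idx]
    d <- d + hi[k] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  L <- length(lo)
  i2 <- 2 * (seq_len(half) - 1)
  for (k in seq_len(L)) {
    idx <- (i2 + (k - 1)) %% n + 1
    add <- a * lo[k] + d * hi[k]
    if (n >= L) {
      x[idx] <- x[idx] + add  # idx has no duplicates when n >= L
    } else {
      agg <- tapply(add, idx, sum)
      x[as.integer(names(agg))] <- x[as.integer(names(agg))] + agg
    }
  }
  x
}

db4_filters <- function() {
  h <- rev(db4_dec_lo)                                  # classical ordering
  g <- (-1)^(seq_along(h) - 1) * db4_dec_lo             # quadrature mirror
  list(h = h, g = g)
}

#' Periodized db4 discrete wavelet transform
#'
#' @param x numeric signal, length a multiple of `2^levels`.
#' @param levels decomposition depth.
#' @return list with approximation `a` and details `d` (list, finest first).
#' @export
dwt_db4 <- function(x, levels) {
  f <- db4_filters()
  lo <- f$h
  hi <- f$g
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, lo, hi)
    details[[j]] <- s$d
    a <- s$a
  }
  list(a = a, d = details)
}

#' @rdname dwt_db4
#' @param w a decomposition as returned by `dwt_db4()`.
#' @export
idwt_db4 <- function(w) {
  f <- db4_filters()
  rl <- f$h  # orthonormal: synthesis reuses the analysis pair in this index form
  rh <- f$g
  a <- w$a
  for (j in rev(seq_along(w$d))) {
    a <- idwt_step(a, w$d[[j]], rl, rh)
  }
  a
}

#' Wavelet denoising (db4)
#'
#' Decomposition depth defaults to `floor(log2(rate / 8))`. Two modes:
#' `"threshold"` soft-thresholds all detail coefficients at the universal
#' threshold `sigma * sqrt(2 log n)` (noise scale from the finest band,
#' MAD / 0.6745) — appropriate for signals that are sparse in the wavelet
#' domain (ECG, respiration). `"baseline"` instead subtracts the level-J
#' approximation (slow baseline wander) and leaves the detail bands intact —
#' appropriate for broadband signals such as surface EMG, which
#' universal-threshold shrinkage would destroy.
#'
#' @param x numeric signal.
#' @param rate sampling rate (Hz).
#' @param levels decomposition depth override.
#' @param mode `"threshold"` or `"baseline"`.
#' @return denoised signal, same length.
#' @export
wavelet_denoise <- function(x, rate, levels = NULL,
                            mode = c("threshold", "baseline")) {
  mode <- match.arg(mode)
  if (is.null(levels)) levels <- max(1, floor(log2(rate / 8)))
  n <- length(x)
  block <- 2^levels
  n_pad <- ceiling(n / block) * block
  if (n_pad < 2 * block) n_pad <- 2 * block
  xp <- if (n_pad > n) c(x, rev(x)[seq_len(n_pad - n)]) else x
  w <- dwt_db4(xp, levels)
  if (mode == "threshold") {
    sigma <- median(abs(w$d[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(xp)))
    w$d <- lapply(w$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  } else {
    w$a[] <- 0
  }
  idwt_db4(w)[seq_len(n)]
}
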