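# Independent brute-force oracles: plain-loop definitional implementations,
# deliberately sharing no code with the package internals.

bf_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

bf_pop_sd <- function(x) {
  m <- bf_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / length(x))
}

bf_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

# Pearson r straight from the covariance definition
bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- bf_mean(x)
  my <- bf_mean(y)
  sxy <- 0
  for (i in seq_len(n)) sxy <- sxy + (x[i] - mx) * (y[i] - my)
  (sxy / n) / (bf_pop_sd(x) * bf_pop_sd(y))
}

# Kendall tau-b by exhaustive pair enumeration
bf_kendall_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (sign(dx) == sign(dy)) conc <- conc + 1 else disc <- disc + 1
    }
  }
  denom <- sqrt((conc + disc + tx) * (conc + disc + ty))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# band power by per-bin loop (same rectangular rule, independent code path)
bf_band_power <- function(freq, psd, df, lo, hi) {
  s <- 0
  for (i in seq_along(freq)) {
    if (freq[i] > lo && freq[i] <= hi) s <- s + psd[i] * df
  }
  s
}

bf_median_frequency <- function(freq, psd) {
  p <- psd
  p[1] <- 0
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  half <- total / 2
  cum <- 0
  for (i in seq_along(p)) {
    if (cum + p[i] >= half) {
      f_lo <- if (i > 1) freq[i - 1] else 0
      frac <- if (p[i] > 0) (half - cum) / p[i] else 0
      return(f_lo + frac * (freq[i] - f_lo))
    }
    cum <- cum + p[i]
  }
  freq[length(freq)]
}

bf_mean_power_frequency <- function(freq, psd) {
  p <- psd
  p[1] <- 0
  num <- den <- 0
  for (i in seq_along(p)) {
    num <- num + freq[i] * p[i]
    den <- den + p[i]
  }
  if (den <= 0) NA_real_ else num / den
}

# Algorithm-style weighted vote: per-label confidence sums, ties to the
# lowest label code
bf_weighted_vote <- function(pred_labels, confidences, labels) {
  g <- setNames(rep(0, length(labels)), labels)
  for (i in seq_along(pred_labels)) {
    g[pred_labels[i]] <- g[pred_labels[i]] + confidences[i]
  }
  best <- labels[which(g == max(g))]
  list(label = best[1], g = g)
}

# precision/recall/F1 from a confusion count matrix (true rows x pred cols)
bf_prf <- function(cm) {
  k <- nrow(cm)
  out <- matrix(0, k, 3, dimnames = list(rownames(cm),
                                         c("precision", "recall", "f1")))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    pred <- sum(cm[, i])
    supp <- sum(cm[i, ])
    p <- if (pred > 0) tp / pred else 0
    r <- if (supp > 0) tp / supp else 0
    out[i, ] <- c(p, r, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  out
}
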