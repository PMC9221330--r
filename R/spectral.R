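# Welch power spectral density and the band statistics built on it.

#' Welch PSD estimate
#'
#' Hann-windowed, mean-removed, 50%-overlapping segments, one-sided density
#' scaling (`2 |X|^2 / (fs * sum(w^2))`, ends not doubled).
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param segment_s segment length in seconds (clipped to the signal length).
#' @param overlap fractional overlap between segments.
#' @param nfft FFT length (zero-padded); default next power of two >= segment,
#'   at least `min_nfft`.
#' @param min_nfft lower bound on `nfft` (fine frequency grids for narrow
#'   low-frequency bands).
#' @return list with `freq` (Hz), `psd` (power / Hz) and `df` (bin width).
#' @export
welch_psd <- function(x, fs, segment_s = NULL, overlap = 0.5, nfft = NULL,
                      min_nfft = 256) {
  n <- length(x)
  stopifnot(n >= 8)
  seg_n <- if (is.null(segment_s)) n else min(n, max(8, round(segment_s * fs)))
  if (is.null(nfft)) nfft <- max(min_nfft, 2^ceiling(log2(seg_n)))
  hop <- max(1, round(seg_n * (1 - overlap)))
  starts <- seq(1, n - seg_n + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg_n) - 1) / (seg_n - 1))  # Hann
  scale <- fs * sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_n - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, rep(0, nfft - seg_n)))
    acc <- acc + 2 * Mod(X[seq_len(nfft %/% 2 + 1)])^2 / scale
  }
  psd <- acc / length(starts)
  psd[1] <- psd[1] / 2
  if (nfft %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft, psd = psd,
       df = fs / nfft)
}

#' Integrated power in a frequency band
#'
#' Rectangular-rule integration over bins with `lo < f <= hi`.
#'
#' @param spec a [welch_psd()] result.
#' @param lo,hi band edges, Hz.
#' @return band power.
#' @export
band_power <- function(spec, lo, hi) {
  sel <- spec$freq > lo & spec$freq <= hi
  sum(spec$psd[sel]) * spec$df
}

#' Median frequency of a spectrum
#'
#' The frequency splitting the integrated PSD area in half, with linear
#' interpolation inside the crossing bin.
#'
#' @param spec a [welch_psd()] result.
#' @return frequency in Hz, or `NA` for a zero-power spectrum.
#' @export
median_frequency <- function(spec) {
  p <- spec$psd
  p[1] <- 0  # exclude DC
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  cum <- cumsum(p)
  half <- total / 2
  i <- which(cum >= half)[1]
  prev <- if (i > 1) cum[i - 1] else 0
  frac <- if (p[i] > 0) (half - prev) / p[i] else 0
  f_lo <- if (i > 1) spec$freq[i - 1] else 0
  f_lo + frac * (spec$freq[i] - f_lo)
}

#' Mean power frequency of a spectrum
#'
#' PSD-weighted mean frequency.
#'
#' @param spec a [welch_psd()] result.
#' @return frequency in Hz, or `NA` for a zero-power spectrum.
#' @export
mean_power_frequency <- function(spec) {
  p <- spec$psd
  p[1] <- 0
  total <- sum(p)
  if (total <= 0) return(NA_real_)
  sum(spec$freq * p) / total
}

#' Dominant spectral peak in a band
#'
#' @param spec a [welch_psd()] result.
#' @param lo,hi search band, Hz.
#' @param min_peak_ratio peak must exceed this multiple of the in-band median
#'   PSD to count (noise-floor guard).
#' @return peak frequency in Hz, or `NA` if no peak rises above the floor.
#' @export
dominant_frequency <- function(spec, lo = 0.05, hi = 1.0,
                               min_peak_ratio = 5) {
  sel <- which(spec$freq >= lo & spec$freq <= hi)
  if (length(sel) < 3) return(NA_real_)
  p <- spec$psd[sel]
  i <- which.max(p)
  floor_est <- median(p)
  if (max(p) <= 0 || (floor_est > 0 && p[i] < min_peak_ratio * floor_est)) {
    return(NA_real_)
  }
  if (floor_est == 0 && p[i] == 0) return(NA_real_)
  spec$freq[sel[i]]
}
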