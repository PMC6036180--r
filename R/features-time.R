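# Time-domain feature families: band filtering, Hilbert envelope,
# amplitude statistics, range-EEG and the Higuchi fractal dimension.

# Two-pass Butterworth-magnitude band-pass gain on the folded FFT grid
band_gain <- function(n, fs, lo, hi, order = 4) {
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  butter_bp_mag(f, lo, hi, n = order)
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth-shaped magnitude response (the squared,
#' forward-backward-equivalent magnitude of an order-`order` band-pass) in
#' the frequency domain. The filter is exactly zero-phase and preserves
#' signal length.
#'
#' @param x numeric signal.
#' @param lo,hi band edges in Hz; `hi` must lie below Nyquist.
#' @param fs sampling rate in Hz.
#' @param order effective Butterworth order (default 4).
#' @return filtered signal of the same length.
#' @export
band_filter <- function(x, lo, hi, fs, order = 4) {
  stop_if(hi >= fs / 2, "band upper edge at or above Nyquist")
  stop_if(lo <= 0 || lo >= hi, "band must satisfy 0 < lo < hi")
  g <- band_gain(length(x), fs, lo, hi, order)
  Re(fft(fft(x) * g, inverse = TRUE)) / length(x)
}

#' Squared-magnitude Hilbert envelope
#'
#' The envelope is the squared magnitude of the analytic signal
#' `|x + i H(x)|^2`, with the Hilbert transform computed in the frequency
#' domain (positive frequencies doubled, negative zeroed).
#'
#' @param x finite numeric signal.
#' @return envelope of the same length (nonnegative).
#' @export
envelope <- function(x) {
  stop_if(!all(is.finite(x)), "non-finite samples")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  a <- fft(fft(x) * h, inverse = TRUE) / n
  Mod(a)^2
}

#' @rdname envelope
#' @param X precomputed `fft(x)` (alternative input).
#' @export
envelope_from_fft <- function(X) {
  n <- length(X)
  Mod(fft(X * hilbert_multiplier(n), inverse = TRUE) / n)^2
}

# filtered signal and its envelope from one forward FFT with a
# precomputed gain and analytic-signal multiplier (shared across channels
# and epochs); used by the extractor hot path
band_filter_env <- function(X, gain, h) {
  n <- length(X)
  Y <- X * gain
  list(x = Re(fft(Y, inverse = TRUE)) / n,
       env = Mod(fft(Y * h, inverse = TRUE) / n)^2)
}

hilbert_multiplier <- function(n) {
  h <- numeric(n)
  if (n %% 2L == 0L) { h[c(1L, n / 2 + 1L)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2 }
  h
}

#' Amplitude-domain features of a band-filtered epoch
#'
#' Six statistics of a zero-mean band-filtered segment: total power (mean
#' squared amplitude), standard deviation, skewness, raw kurtosis, and the
#' mean and standard deviation of the squared-magnitude Hilbert envelope.
#' For a constant segment skewness and kurtosis are undefined and are
#' emitted as 0 with a warning.
#'
#' @param x band-filtered epoch.
#' @param env optional precomputed [envelope()] of `x`.
#' @return named numeric vector of 6 features.
#' @export
amplitude_features <- function(x, env = NULL) {
  if (is.null(env)) env <- envelope(x)
  s <- cpp_amp_stats(x, env)
  if (s[7L] > 0)
    warning("constant signal: skewness/kurtosis undefined, emitting 0")
  c(total_power = s[1L], sd = s[2L], skewness = s[3L], kurtosis = s[4L],
    env_mean = s[5L], env_sd = s[6L])
}

#' Range-EEG (peak-to-peak) features
#'
#' Peak-to-peak voltage of short sliding windows (2 s, 50% overlap by
#' default) summarised by mean, median, 5th and 95th percentiles, standard
#' deviation, coefficient of variation (sd/mean) and a quantile-based
#' asymmetry measure `((p95 - median) - (median - p5)) / (p95 - p5)`.
#'
#' @param x band-filtered epoch.
#' @param fs sampling rate in Hz.
#' @param win window length in seconds (default 2).
#' @param overlap fractional window overlap (default 0.5).
#' @return named numeric vector of 7 features.
#' @export
reeg_features <- function(x, fs, win = 2, overlap = 0.5) {
  w <- round(win * fs)
  stop_if(length(x) < w, "epoch shorter than the range window")
  step <- max(1L, round(w * (1 - overlap)))
  r <- cpp_sliding_ptp(x, as.integer(w), as.integer(step))
  m <- mean(r)
  s <- sqrt(mean((r - m)^2))
  qs <- quantile(r, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  cv <- if (abs(m) < .Machine$double.eps) {
    warning("zero mean range; cv emitted as 0"); 0
  } else s / m
  spread <- qs[3L] - qs[1L]
  sym <- if (spread <= 0) 0 else ((qs[3L] - qs[2L]) - (qs[2L] - qs[1L])) / spread
  c(mean = m, median = qs[2L], p5 = qs[1L], p95 = qs[3L],
    sd = s, cv = cv, symmetry = sym)
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi estimator: curve lengths `L(k)` are computed for scales
#' `k = 1..kmax` over all offset subseries and the fractal dimension is the
#' negative slope of an ordinary least-squares fit of `log L(k)` on
#' `log k`. Bounded one-dimensional series have FD between 1 (smooth) and 2
#' (noise-like); estimates outside that range are clipped with a warning,
#' and a constant series returns 1 by convention.
#'
#' @param x numeric epoch (unfiltered broadband signal).
#' @param kmax maximum scale (default 6).
#' @return scalar fractal dimension in `[1, 2]`.
#' @export
higuchi_fd <- function(x, kmax = 6) {
  stop_if(length(x) < 10 * kmax, "series too short for Higuchi estimate")
  L <- cpp_higuchi_lengths(as.numeric(x), as.integer(kmax))
  if (all(L <= 0)) {
    warning("constant series: FD = 1 by convention")
    return(1)
  }
  k <- seq_len(kmax)
  fd <- -unname(coef(lm(log(L) ~ log(k)))[2L])
  if (fd < 1 || fd > 2) {
    warning(sprintf("Higuchi FD %.3f outside [1, 2]; clipped", fd))
    fd <- min(max(fd, 1), 2)
  }
  fd
}

#' Lagged rank cross-correlation of two envelopes
#'
#' Each envelope is rank-transformed once over the whole epoch; the rank
#' series are then correlated (Pearson on ranks, i.e. Spearman-style) at
#' every integer-sample lag in `[-max_lag, +max_lag]`. At positive lags
#' the second (right-hemisphere) signal leads the first. Returns the
#' maximum correlation and the lag (in seconds) at which it occurs.
#'
#' @param e1,e2 envelopes of a homologous left/right channel pair.
#' @param fs sampling rate in Hz.
#' @param max_lag maximum lag in seconds (default 0.2).
#' @return named vector `c(max_corr, lag_at_max)`; `NA`s for a constant
#'   envelope.
#' @export
envelope_xcorr <- function(e1, e2, fs, max_lag = 0.2) {
  L <- as.integer(round(max_lag * fs))
  stop_if(L >= length(e1) - 1L, "max_lag too long for epoch")
  if (var(e1) == 0 || var(e2) == 0) {
    return(c(max_corr = NA_real_, lag_at_max = NA_real_))
  }
  r1 <- cpp_rank_avg(e1)
  r2 <- cpp_rank_avg(e2)
  cc <- cpp_lagged_pearson(r1, r2, L)
  if (all(is.na(cc))) return(c(max_corr = NA_real_, lag_at_max = NA_real_))
  i <- which.max(cc)
  c(max_corr = cc[i], lag_at_max = (i - 1L - L) / fs)
}

#' Median envelope cross-correlation features across hemisphere pairs
#'
#' Applies [envelope_xcorr()] to each hemisphere-paired envelope couple and
#' returns the median of the maximum correlations and the median of the
#' lags at which they occur. Pairs with constant envelopes are skipped.
#'
#' @param env_left,env_right lists of envelopes (aligned pairs).
#' @param fs sampling rate in Hz.
#' @param max_lag maximum lag in seconds.
#' @return named vector `c(xcorr_median, xcorr_lag)`.
#' @export
envelope_xcorr_features <- function(env_left, env_right, fs, max_lag = 0.2) {
  stop_if(length(env_left) != length(env_right) || length(env_left) < 1L,
          "need at least one aligned hemisphere pair")
  res <- mapply(function(a, b) envelope_xcorr(a, b, fs, max_lag),
                env_left, env_right)
  ok <- !is.na(res[1L, ])
  if (!any(ok)) return(c(xcorr_median = 0, xcorr_lag = 0))
  c(xcorr_median = median(res[1L, ok]), xcorr_lag = median(res[2L, ok]))
}
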