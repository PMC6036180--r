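# Welch power spectral density and the spectral feature set.

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is cut into windows of
#' `win` seconds advancing by `win * (1 - overlap)`, each window is
#' demeaned, tapered (Hamming by default) and Fourier transformed; the
#' one-sided periodograms are averaged. Scaling is density-style, so the
#' integral of the PSD over frequency approximates the signal variance
#' (Parseval consistency).
#'
#' @param x numeric signal (one epoch).
#' @param fs sampling rate in Hz.
#' @param win window length in seconds (default 2).
#' @param overlap fractional window overlap (default 0.5).
#' @param window_fn taper function of the window length; defaults to the
#'   Hamming window.
#' @param keep_fft keep the complex windowed FFTs (needed for coherence).
#' @return a `psd_estimate`: `freqs` (Hz), `power` (uV^2/Hz), `df`,
#'   `segments` (per-window one-sided PSD matrix, bins x windows),
#'   `window_len`, `overlap` and optionally `cfft`.
#' @export
welch_psd <- function(x, fs, win = 2, overlap = 0.5,
                      window_fn = hamming_window, keep_fft = FALSE) {
  w <- round(win * fs)
  n <- length(x)
  stop_if(n < w, "epoch shorter than the Welch window")
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, n - w + 1L, by = step)
  taper <- window_fn(w)
  u <- sum(taper^2)

  seg <- matrix(x[outer(0:(w - 1L), starts, `+`)], nrow = w)
  seg <- seg - rep(colMeans(seg), each = w)
  seg <- seg * taper
  X <- stats::mvfft(seg)

  nb <- w %/% 2L + 1L
  X <- X[seq_len(nb), , drop = FALSE]
  pxx <- Mod(X)^2 / (fs * u)
  # one-sided: double interior bins (not DC; not Nyquist when w is even)
  dbl <- seq_len(nb) > 1L & !(w %% 2L == 0L & seq_len(nb) == nb)
  pxx[dbl, ] <- 2 * pxx[dbl, ]

  structure(list(freqs = (seq_len(nb) - 1L) * fs / w,
                 power = rowMeans(pxx), df = fs / w,
                 segments = pxx, window_len = win, overlap = overlap,
                 cfft = if (keep_fft) X else NULL, fft_scale = 1 / (fs * u)),
            class = "psd_estimate")
}

#' Hamming window taper
#' @param n window length in samples.
#' @return numeric taper of length `n`.
#' @export
hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

#' Spectral features of one band
#'
#' From a Welch PSD restricted to a band `[a, b)`:
#' absolute band power (integrated PSD), power relative to the whole band,
#' Wiener entropy (spectral flatness: geometric over arithmetic mean of the
#' in-band PSD), Shannon entropy of the normalised in-band PSD divided by
#' `log(bin count)` so it lies in `[0, 1]`, the spectral edge frequency
#' (smallest frequency accumulating `sef` of in-band power), and the mean
#' squared difference between consecutive short-time amplitude spectra
#' averaged over in-band bins.
#'
#' @param psd a [welch_psd()] estimate.
#' @param band one-row band definition (`lo`, `hi`).
#' @param whole one-row whole-band definition (relative-power denominator).
#' @param sef edge-frequency quantile (default 0.95).
#' @return named numeric vector of 6 features.
#' @export
spectral_features <- function(psd, band, whole, sef = 0.95) {
  inb <- band_mask(psd$freqs, band$lo, band$hi)
  inw <- band_mask(psd$freqs, whole$lo, whole$hi)
  stop_if(!any(inb), "band contains no PSD bins")
  p <- psd$power[inb]
  bp <- sum(p) * psd$df
  wp <- sum(psd$power[inw]) * psd$df
  tot <- sum(p)

  if (tot <= 0) {
    warning("all-zero in-band power; entropies set to 0")
    wiener <- 0; shannon <- 0; edge <- band$lo
  } else {
    wiener <- if (any(p <= 0)) 0 else exp(mean(log(p))) / mean(p)
    q <- p / tot
    nz <- q > 0
    shannon <- if (sum(nz) <= 1L) 0 else
      -sum(q[nz] * log(q[nz])) / log(length(q))
    edge <- psd$freqs[inb][which(cumsum(p) / tot >= sef)[1L]]
  }

  amp <- sqrt(psd$segments[inb, , drop = FALSE])
  k <- ncol(amp)
  sdiff <- if (k < 2L) 0 else
    mean((amp[, -1L, drop = FALSE] - amp[, -k, drop = FALSE])^2)

  c(power = bp, rel_power = if (wp > 0) bp / wp else 0,
    wiener_entropy = wiener, shannon_entropy = shannon,
    edge_freq = edge, spectral_diff = sdiff)
}

#' Brain symmetry index for one band
#'
#' Hemispheric power spectra are averaged across the channels of each
#' hemisphere at every frequency bin; the BSI is the mean over in-band bins
#' of the absolute normalised difference
#' `|(P_left - P_right) / (P_left + P_right)|`, which lies in `[0, 1]`
#' (0 = perfectly symmetric, 1 = all power on one side). Bins where both
#' hemispheres are zero are skipped.
#'
#' @param psd_left,psd_right lists of [welch_psd()] estimates, one per
#'   channel of each hemisphere, on a common frequency grid.
#' @param band one-row band definition.
#' @return scalar BSI in `[0, 1]`.
#' @export
bsi <- function(psd_left, psd_right, band) {
  stop_if(length(psd_left) < 1L || length(psd_right) < 1L,
          "need at least one channel per hemisphere")
  pl <- rowMeans(vapply(psd_left, `[[`, numeric(length(psd_left[[1L]]$power)), "power"))
  pr <- rowMeans(vapply(psd_right, `[[`, numeric(length(psd_right[[1L]]$power)), "power"))
  f <- psd_left[[1L]]$freqs
  inb <- band_mask(f, band$lo, band$hi)
  num <- pl[inb] - pr[inb]
  den <- pl[inb] + pr[inb]
  ok <- den > 0
  if (!any(ok)) return(0)
  mean(abs(num[ok] / den[ok]))
}

#' Magnitude-squared coherence of a channel pair
#'
#' Welch-style coherence from cached windowed FFTs:
#' `C(f) = |<X Y*>|^2 / (<|X|^2> <|Y|^2>)` with `< >` averaging across
#' windows. Restricted to a band, yields the in-band mean coherence and the
#' frequency at which coherence peaks.
#'
#' @param psd_x,psd_y [welch_psd()] estimates computed with
#'   `keep_fft = TRUE` on the two signals.
#' @param band one-row band definition.
#' @return named vector `c(mean_coh, peak_freq)`, or `NA`s if the pair is
#'   degenerate (zero power).
#' @export
coherence_pair <- function(psd_x, psd_y, band) {
  stop_if(is.null(psd_x$cfft) || is.null(psd_y$cfft),
          "welch_psd(..., keep_fft = TRUE) required for coherence")
  sxy <- rowMeans(psd_x$cfft * Conj(psd_y$cfft))
  sxx <- rowMeans(Mod(psd_x$cfft)^2)
  syy <- rowMeans(Mod(psd_y$cfft)^2)
  f <- psd_x$freqs
  inb <- band_mask(f, band$lo, band$hi)
  den <- sxx[inb] * syy[inb]
  if (!any(den > 0)) return(c(mean_coh = NA_real_, peak_freq = NA_real_))
  coh <- ifelse(den > 0, Mod(sxy[inb])^2 / den, 0)
  c(mean_coh = mean(coh[den > 0]),
    peak_freq = f[inb][which.max(coh)])
}
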