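# Filtering, resampling, montage derivation and epoch segmentation.
#
# All filters are applied with zero phase so that relative timing between
# channels is preserved for the connectivity features. Filtering is done in
# the frequency domain with Butterworth-shaped magnitude responses (the
# squared, i.e. forward-backward equivalent, magnitude), which is exactly
# zero-phase and numerically robust even for passband edges that sit at a
# tiny fraction of the Nyquist rate.

#' Preprocessing configuration
#'
#' @param bandpass numeric length-2, band-pass corner frequencies in Hz.
#' @param target_fs target sampling rate in Hz after resampling (250 Hz,
#'   i.e. 4 ms resolution, by default).
#' @param notch_centers centres of band-stop notches in Hz. The default
#'   (`NULL`) notches the 19.5 Hz slice-frequency harmonics up to Nyquist,
#'   the 60 Hz line frequency and a 26 Hz vibration artifact.
#' @param notch_bw notch bandwidth in Hz (1 Hz default).
#' @param montage `"referential"` (leave channels as read) or `"bipolar"`
#'   (derive anode - cathode channels from `bipolar_pairs`).
#' @param bipolar_pairs data frame with columns `anode`, `cathode`;
#'   defaults to the shipped longitudinal 31-pair layout
#'   ([default_bipolar_pairs()]).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(bandpass = c(1, 70), target_fs = 250,
                              notch_centers = NULL, notch_bw = 1,
                              montage = c("referential", "bipolar"),
                              bipolar_pairs = NULL) {
  montage <- match.arg(montage)
  stop_if(length(bandpass) != 2L || bandpass[1L] <= 0 ||
            bandpass[1L] >= bandpass[2L], "bandpass must satisfy 0 < lo < hi")
  stop_if(bandpass[2L] >= target_fs / 2,
          "bandpass upper edge must lie below the post-resampling Nyquist")
  if (is.null(notch_centers)) notch_centers <- default_notch_centers(target_fs / 2)
  if (is.null(bipolar_pairs)) bipolar_pairs <- default_bipolar_pairs()
  structure(list(bandpass = as.numeric(bandpass), target_fs = target_fs,
                 notch_centers = sort(unique(notch_centers)),
                 notch_bw = notch_bw, montage = montage,
                 bipolar_pairs = bipolar_pairs),
            class = "preprocess_config")
}

#' Default notch centres for a given Nyquist frequency
#'
#' Harmonics of the 19.5 Hz fMRI slice-selection frequency up to Nyquist,
#' the 60 Hz AC line frequency and a 26 Hz vibration artifact frequency.
#'
#' @param nyquist Nyquist frequency in Hz.
#' @return sorted numeric vector of notch centres.
#' @export
default_notch_centers <- function(nyquist = 125) {
  harm <- seq(19.5, nyquist, by = 19.5)
  sort(unique(c(harm[harm < nyquist], 26, 60)))
}

# Two-pass (squared) Butterworth band-pass magnitude of effective order n:
# G(f) = 1 / (1 + q^(2n)),  q = (f^2 - lo*hi) / ((hi - lo) * f).
butter_bp_mag <- function(f, lo, hi, n = 10) {
  fp <- pmax(f, .Machine$double.xmin)  # DC maps to q = -Inf, gain 0
  q <- (fp^2 - lo * hi) / ((hi - lo) * fp)
  1 / (1 + q^(2 * n))
}

# Band-stop complement with a narrower prototype (effective order 4).
butter_bs_mag <- function(f, centre, bw, n = 4) {
  lo <- centre - bw / 2; hi <- centre + bw / 2
  1 - butter_bp_mag(f, lo, hi, n)
}

#' Spectral (sinc) resampling
#'
#' Resamples by truncating the Fourier spectrum at the new Nyquist
#' frequency and inverse-transforming at the new length: exact band-limited
#' interpolation with inherent anti-aliasing, zero phase and unit passband
#' gain.
#'
#' @param x numeric signal.
#' @param fs_in,fs_out input and output sampling rates in Hz
#'   (`fs_out <= fs_in`).
#' @return resampled signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  stop_if(fs_out > fs_in, "upsampling is not supported")
  if (abs(fs_in - fs_out) < 1e-9) return(x)
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  X <- fft(x)
  keep <- (n_out - 1L) %/% 2L  # bins strictly below the new Nyquist
  Y <- complex(real = numeric(n_out))
  Y[1L] <- X[1L]
  if (keep >= 1L) {
    Y[2L:(keep + 1L)] <- X[2L:(keep + 1L)]
    Y[(n_out - keep + 1L):n_out] <- X[(n - keep + 1L):n]
  }
  Re(fft(Y, inverse = TRUE)) * (n_out / n) / n_out
}

# Apply a real, symmetric magnitude response G(f) in the frequency domain.
# G is evaluated on the two-sided FFT grid; the result is exactly
# zero-phase.
apply_fft_gain <- function(x, fs, gain_fn) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  Re(fft(fft(x) * gain_fn(f), inverse = TRUE)) / n
}

#' Filter and resample a recording
#'
#' Polyphase resampling to `target_fs`, zero-phase band-pass filtering and
#' zero-phase band-stop notches, channel by channel. Notches at or above
#' the post-resampling Nyquist frequency are skipped with a warning.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return a filtered [raw_recording()] at `cfg$target_fs`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stop_if(!inherits(rec, "raw_recording"), "rec must be a raw_recording")
  stop_if(!inherits(cfg, "preprocess_config"), "cfg must be a preprocess_config")
  data <- rec$data
  fs <- rec$fs

  if (abs(fs - cfg$target_fs) > 1e-9) {
    stop_if(cfg$target_fs > fs, "upsampling is not supported")
    data <- t(apply(data, 1L, resample_fft, fs_in = fs,
                    fs_out = cfg$target_fs))
    fs <- cfg$target_fs
  }
  nyq <- fs / 2

  lo <- cfg$bandpass[1L]; hi <- cfg$bandpass[2L]
  notches <- cfg$notch_centers
  drop <- notches + cfg$notch_bw / 2 >= nyq
  if (any(drop)) {
    warning(sprintf("skipping notch(es) at/above Nyquist (%g Hz): %s",
                    nyq, paste(notches[drop], collapse = ", ")))
    notches <- notches[!drop]
  }
  gain <- function(f) {
    g <- butter_bp_mag(f, lo, hi)
    for (nc in notches) g <- g * butter_bs_mag(f, nc, cfg$notch_bw)
    g
  }
  data <- t(apply(data, 1L, apply_fft_gain, fs = fs, gain_fn = gain))
  out <- raw_recording(data, fs = fs, labels = rec$labels)
  if (cfg$montage == "bipolar") out <- to_bipolar(out, cfg$bipolar_pairs)
  out
}

#' Derive a bipolar montage
#'
#' Each derived channel is the samplewise difference anode - cathode; its
#' label is `"anode-cathode"`.
#'
#' @param rec a [raw_recording()].
#' @param pairs data frame with character columns `anode` and `cathode`,
#'   all referring to labels present in `rec`.
#' @return a [raw_recording()] with `nrow(pairs)` channels.
#' @export
to_bipolar <- function(rec, pairs = default_bipolar_pairs()) {
  stop_if(!inherits(rec, "raw_recording"), "rec must be a raw_recording")
  pairs <- as.data.frame(pairs)
  stop_if(!all(c("anode", "cathode") %in% names(pairs)),
          "pairs needs 'anode' and 'cathode' columns")
  missing <- setdiff(unique(c(pairs$anode, pairs$cathode)), rec$labels)
  stop_if(length(missing) > 0L,
          "montage refers to absent channel(s): ",
          paste(missing, collapse = ", "))
  data <- rec$data[pairs$anode, , drop = FALSE] -
    rec$data[pairs$cathode, , drop = FALSE]
  raw_recording(data, fs = rec$fs,
                labels = paste0(pairs$anode, "-", pairs$cathode))
}

#' Default longitudinal bipolar montage (31 pairs)
#'
#' A double-banana-style longitudinal layout for a 32-electrode 10-20 cap
#' (lateral and parasagittal chains per hemisphere, a midline chain, and
#' the mastoid-adjacent TP9/TP10 electrodes), yielding 31 derived channels.
#'
#' @return data frame with columns `anode`, `cathode`.
#' @export
default_bipolar_pairs <- function() {
  p <- rbind(
    # left lateral / temporal chain
    c("Fp1", "F7"), c("F7", "FC5"), c("FC5", "T7"), c("T7", "CP5"),
    c("CP5", "P7"), c("P7", "O1"),
    # right lateral / temporal chain
    c("Fp2", "F8"), c("F8", "FC6"), c("FC6", "T8"), c("T8", "CP6"),
    c("CP6", "P8"), c("P8", "O2"),
    # left parasagittal chain
    c("Fp1", "F3"), c("F3", "FC1"), c("FC1", "C3"), c("C3", "CP1"),
    c("CP1", "P3"), c("P3", "O1"),
    # right parasagittal chain
    c("Fp2", "F4"), c("F4", "FC2"), c("FC2", "C4"), c("C4", "CP2"),
    c("CP2", "P4"), c("P4", "O2"),
    # midline chain and mastoid-adjacent leads
    c("Fz", "Cz"), c("Cz", "Pz"), c("Pz", "POz"), c("POz", "Oz"),
    c("T7", "TP9"), c("T8", "TP10"), c("O1", "Oz")
  )
  data.frame(anode = p[, 1L], cathode = p[, 2L])
}

#' Monopolar electrode labels of the default 32-channel cap
#' @return character vector of 32 labels.
#' @export
default_cap_labels <- function() {
  pr <- default_bipolar_pairs()
  unique(c(pr$anode, pr$cathode))
}

#' Hemisphere of a channel label
#'
#' Classifies 10-20-style labels (monopolar or bipolar `"A-C"`) by the
#' electrode number: odd = left, even = right, trailing `z` = midline. A
#' bipolar label is classified by its anode, falling back to the cathode
#' for midline anodes.
#'
#' @param labels character vector of channel labels.
#' @return character vector: `"left"`, `"right"` or `"mid"`.
#' @export
channel_hemisphere <- function(labels) {
  one <- function(el) {
    num <- regmatches(el, regexpr("[0-9]+$", el))
    if (length(num) == 0L) return("mid")
    if (as.integer(num) %% 2L == 1L) "left" else "right"
  }
  vapply(labels, function(lb) {
    parts <- strsplit(lb, "-", fixed = TRUE)[[1L]]
    h <- one(parts[1L])
    if (h == "mid" && length(parts) > 1L) h <- one(parts[2L])
    h
  }, "")
}

#' Default homologous hemisphere channel pairs (bipolar montage)
#'
#' Left/right homologous derived channels of the default montage, used for
#' the connectivity features (envelope cross-correlation and coherence) and
#' for the hemisphere averages of the brain symmetry index.
#'
#' @return data frame with character columns `left` and `right`.
#' @export
default_hemi_pairs <- function() {
  data.frame(
    left = c("Fp1-F7", "F7-FC5", "FC5-T7", "T7-CP5", "CP5-P7", "P7-O1",
             "Fp1-F3", "F3-FC1", "FC1-C3", "C3-CP1", "CP1-P3", "P3-O1",
             "T7-TP9"),
    right = c("Fp2-F8", "F8-FC6", "FC6-T8", "T8-CP6", "CP6-P8", "P8-O2",
              "Fp2-F4", "F4-FC2", "FC2-C4", "C4-CP2", "CP2-P4", "P4-O2",
              "T8-TP10"))
}

#' Segment a recording into fixed-length overlapping epochs
#'
#' Epoch starts advance by `epoch_len * (1 - overlap)` seconds; a trailing
#' partial epoch is discarded rather than padded, so that epoch averages
#' are taken over equal-length segments. The epoch count is
#' `floor((duration - epoch_len) / (epoch_len * (1 - overlap))) + 1`.
#'
#' @param rec a [raw_recording()].
#' @param epoch_len epoch length in seconds (default 60).
#' @param overlap fractional overlap between consecutive epochs in
#'   `[0, 1)` (default 0.5).
#' @return an `epoch_set`: list with `data` (channels x samples x epochs
#'   array), `fs`, `labels`, `epoch_len`, `overlap` and `m` (epoch count).
#' @export
segment_epochs <- function(rec, epoch_len = 60, overlap = 0.5) {
  stop_if(!inherits(rec, "raw_recording"), "rec must be a raw_recording")
  stop_if(overlap < 0 || overlap >= 1, "overlap must be in [0, 1)")
  spp <- round(epoch_len * rec$fs)
  nsamp <- ncol(rec$data)
  stop_if(nsamp < spp, "recording shorter than one epoch")
  step <- round(epoch_len * (1 - overlap) * rec$fs)
  stop_if(step < 1, "epoch step must be at least one sample")
  m <- (nsamp - spp) %/% step + 1L
  arr <- array(0, dim = c(nrow(rec$data), spp, m),
               dimnames = list(rec$labels, NULL, NULL))
  for (e in seq_len(m)) {
    arr[, , e] <- rec$data[, ((e - 1L) * step + 1L):((e - 1L) * step + spp)]
  }
  structure(list(data = arr, fs = rec$fs, labels = rec$labels,
                 epoch_len = epoch_len, overlap = overlap, m = m),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d channels, %d epochs of %g s (overlap %g) @ %g Hz\n",
              dim(x$data)[1L], x$m, x$epoch_len, x$overlap, x$fs))
  invisible(x)
}
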