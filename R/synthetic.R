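# Synthetic EEG cohort generator.
#
# Each subject is a sum of band-limited oscillators (one per classical
# band) whose amplitudes and peak frequencies are affine functions of age,
# with subject- and channel-level lognormal scatter, a hemispheric
# amplitude asymmetry, slow amplitude modulation (so envelopes carry
# structure), and 1/f^gamma background noise at a configurable
# signal-to-noise ratio. Ground-truth generative parameters are returned
# alongside every recording, so recovery of planted age structure can be
# tested end to end.

#' Default age-dependent band effects
#'
#' Amplitudes (uV) and peak frequencies (Hz) as affine functions of age in
#' years: alpha amplitude and peak frequency decline with age (the dominant
#' and best replicated resting-state aging effects), theta declines mildly,
#' delta and beta drift slightly upward.
#'
#' @return data frame with columns `band`, `amp0`, `amp_slope`, `freq0`,
#'   `freq_slope` (`amp = amp0 + amp_slope * age`, likewise frequency).
#' @export
default_band_effects <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta"),
    amp0 = c(10, 11, 28, 5),
    amp_slope = c(0.02, -0.04, -0.25, 0.02),
    freq0 = c(2, 5.5, 11, 20),
    freq_slope = c(0, 0, -0.025, 0))
}

#' Band effects with the age signal confined to alpha amplitude
#'
#' All amplitude and frequency slopes are zero except the alpha amplitude,
#' which declines steeply with age. Used for planted-structure recovery
#' experiments where importance should concentrate on alpha-band features.
#'
#' @return data frame in the format of [default_band_effects()].
#' @export
alpha_only_band_effects <- function() {
  be <- default_band_effects()
  be$amp_slope <- c(0, 0, -0.3, 0)
  be$amp0[be$band == "alpha"] <- 30
  be$freq_slope <- 0
  be
}

#' Synthetic cohort specification
#'
#' @param n_subjects cohort size.
#' @param age_range uniform chronological age range in years (18-58).
#' @param n_channels 31 (bipolar-derived labels, extraction-ready) or 32
#'   (monopolar cap labels, for exercising the montage derivation).
#' @param fs sampling rate in Hz (250).
#' @param duration recording length in seconds (480 = 8 min; 120 is the
#'   short mode used throughout the test suite).
#' @param band_effects age-effect table ([default_band_effects()]).
#' @param subject_scatter lognormal sd of the per-subject band amplitude
#'   factor (biological variability not explained by age).
#' @param channel_scatter lognormal sd of the per-channel amplitude factor.
#' @param asymmetry fractional left/right amplitude imbalance (left scaled
#'   by `1 + asymmetry/2`, right by `1 - asymmetry/2`); drives a nonzero
#'   brain symmetry index.
#' @param am_depth,am_freq depth and rate (Hz) of the slow amplitude
#'   modulation applied to each oscillator.
#' @param noise_gamma spectral exponent of the 1/f^gamma background.
#' @param snr cohort-reference oscillator variance (evaluated at the
#'   mid-age amplitudes, without scatter) over in-band noise variance;
#'   the noise level is identical for every subject so that planted age
#'   effects stay confined to the oscillators. `Inf` disables noise.
#' @param seed master seed; the cohort is fully deterministic given it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 100, age_range = c(18, 58),
                        n_channels = 31, fs = 250, duration = 480,
                        band_effects = default_band_effects(),
                        subject_scatter = 0.25, channel_scatter = 0.08,
                        asymmetry = 0.1, am_depth = 0.2, am_freq = 0.1,
                        noise_gamma = 1, snr = 2, seed = 1) {
  stop_if(n_subjects < 1, "need at least one subject")
  stop_if(!n_channels %in% c(31L, 32L), "n_channels must be 31 or 32")
  amin <- pmin(band_effects$amp0 + band_effects$amp_slope * age_range[1L],
               band_effects$amp0 + band_effects$amp_slope * age_range[2L])
  stop_if(any(amin < 0), "negative band amplitude inside age range")
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 n_channels = n_channels, fs = fs, duration = duration,
                 band_effects = band_effects,
                 subject_scatter = subject_scatter,
                 channel_scatter = channel_scatter, asymmetry = asymmetry,
                 am_depth = am_depth, am_freq = am_freq,
                 noise_gamma = noise_gamma, snr = snr, seed = seed),
            class = "cohort_spec")
}

#' Channel labels used by the generator
#' @param n_channels 31 (bipolar-derived) or 32 (monopolar cap).
#' @return character label vector.
#' @export
synthetic_labels <- function(n_channels = 31) {
  if (n_channels == 32L) return(default_cap_labels())
  pr <- default_bipolar_pairs()
  paste0(pr$anode, "-", pr$cathode)
}

# shaped background noise, unit variance, returned with the fraction of
# its power inside [lo, hi)
pink_noise <- function(n, fs, gamma, lo = 0.5, hi = 30) {
  nf <- n %/% 2L
  f <- (1:nf) * fs / n
  mag <- f^(-gamma / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- spec
  full[n:(n - nf + 2L)] <- Conj(spec[1:(nf - 1L)])
  x <- Re(fft(full, inverse = TRUE)) / n
  pow <- mag^2
  frac <- sum(pow[f >= lo & f < hi]) / sum(pow)
  x <- x / sd(x)
  list(x = x, band_fraction = frac)
}

#' Simulate one subject's recording
#'
#' @param spec a [cohort_spec()].
#' @param age chronological age in years.
#' @param seed subject-level seed (deterministic given it).
#' @return list with `recording` (a [raw_recording()]) and `truth` (one-row
#'   data frame of the realised per-band amplitudes and frequencies).
#' @export
simulate_subject <- function(spec, age, seed = 1) {
  stop_if(!inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  set.seed(seed)
  labels <- synthetic_labels(spec$n_channels)
  hemi <- channel_hemisphere(labels)
  hfac <- c(left = 1 + spec$asymmetry / 2, right = 1 - spec$asymmetry / 2,
            mid = 1)[hemi]
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  be <- spec$band_effects
  nb <- nrow(be)

  amp_sub <- pmax(be$amp0 + be$amp_slope * age, 0) *
    exp(rnorm(nb, 0, spec$subject_scatter))
  freq_sub <- pmax(be$freq0 + be$freq_slope * age, 0.5)

  # noise level is fixed across subjects, referenced to the mid-age
  # oscillator variance of the cohort; scaling it to each subject's own
  # oscillators would leak any planted age effect into every band
  ref_amp <- pmax(be$amp0 + be$amp_slope * mean(spec$age_range), 0)
  ref_var <- sum(ref_amp^2 * (1 + spec$am_depth^2 / 2) / 2)

  data <- matrix(0, length(labels), n)
  for (ci in seq_along(labels)) {
    x <- numeric(n)
    for (bi in seq_len(nb)) {
      a <- amp_sub[bi] * exp(rnorm(1, 0, spec$channel_scatter)) * hfac[ci]
      f <- freq_sub[bi] + runif(1, -0.15, 0.15)
      am <- 1 + spec$am_depth * sin(2 * pi * spec$am_freq * t + runif(1, 0, 2 * pi))
      x <- x + a * am * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
    }
    if (is.finite(spec$snr)) {
      pn <- pink_noise(n, spec$fs, spec$noise_gamma)
      target_inband <- ref_var / spec$snr
      x <- x + pn$x * sqrt(target_inband / pn$band_fraction)
    }
    data[ci, ] <- x
  }
  truth <- data.frame(age = age,
                      t(structure(amp_sub, names = paste0("amp_", be$band))),
                      t(structure(freq_sub, names = paste0("freq_", be$band))))
  list(recording = raw_recording(data, fs = spec$fs, labels = labels),
       truth = truth)
}

#' Simulate a full cohort
#'
#' Ages are sampled uniformly over the spec's range; a balanced `sex`
#' label is attached (no generative effect: the generator carries no sex
#' differences by default).
#'
#' @param spec a [cohort_spec()].
#' @param keep_recordings keep the recordings in memory (set `FALSE` for
#'   large cohorts and use [cohort_features()] instead).
#' @return list with `metadata` (subject_id, age, sex), `truth`, and
#'   `recordings` (or `NULL`).
#' @export
simulate_cohort <- function(spec, keep_recordings = TRUE) {
  n <- spec$n_subjects
  set.seed(child_seed(spec$seed, 1))
  ages <- runif(n, spec$age_range[1L], spec$age_range[2L])
  sex <- rep_len(c("F", "M"), n)
  recs <- if (keep_recordings) vector("list", n) else NULL
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- simulate_subject(spec, ages[i], child_seed(spec$seed, 2, i))
    if (keep_recordings) recs[[i]] <- sub$recording
    truth[[i]] <- sub$truth
  }
  list(metadata = data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                             age = ages, sex = sex, stringsAsFactors = FALSE),
       truth = do.call(rbind, truth),
       recordings = recs)
}

#' Simulate a cohort and extract its feature table in one pass
#'
#' Streams subject by subject (simulate, segment into epochs, extract,
#' discard the raw recording), so arbitrarily large cohorts fit in memory.
#'
#' @param spec a [cohort_spec()].
#' @param cfg a [feature_config()].
#' @param epoch_len,overlap epoch segmentation parameters.
#' @param verbose print a progress line every 25 subjects.
#' @return list with `table` (subject_id, age, sex + feature columns) and
#'   `truth`.
#' @export
cohort_features <- function(spec, cfg = feature_config(), epoch_len = 60,
                            overlap = 0.5, verbose = FALSE) {
  n <- spec$n_subjects
  set.seed(child_seed(spec$seed, 1))
  ages <- runif(n, spec$age_range[1L], spec$age_range[2L])
  sex <- rep_len(c("F", "M"), n)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- simulate_subject(spec, ages[i], child_seed(spec$seed, 2, i))
    epochs <- segment_epochs(sub$recording, epoch_len, overlap)
    rows[[i]] <- extract_subject(epochs, cfg)
    truth[[i]] <- sub$truth
    if (verbose && i %% 25L == 0L) message("  extracted ", i, "/", n)
  }
  tab <- cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                          age = ages, sex = sex, stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, rows), optional = TRUE))
  list(table = tab, truth = do.call(rbind, truth))
}
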