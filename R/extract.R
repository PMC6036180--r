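# Per-subject feature extraction: every feature family evaluated per
# channel x band x epoch, then averaged across epochs into one named row.
#
# Feature names are machine-parseable as <domain>.<feature>.<band>.<channel>
# (channel omitted for the across-channel connectivity features; fractal
# dimension uses the pseudo-band "broadband" since it is computed on the
# unfiltered signal). Channel labels never contain dots, so the names can
# be split on "." to group importance scores by any axis.

#' Extract the full feature vector of one subject
#'
#' Computes the five feature domains for every epoch and averages across
#' epochs: amplitude statistics (6 per band and channel), range-EEG
#' (7 per band and channel), spectral measures (6 per band and channel),
#' connectivity (5 per band: brain symmetry index, median and lag of the
#' maximum envelope rank cross-correlation, mean coherence, median
#' peak-coherence frequency) and the Higuchi fractal dimension (1 per
#' channel, unfiltered). With the default four feature bands and N = 31
#' channels this yields 744 + 868 + 744 + 20 + 31 = 2407 features.
#'
#' @param epochs an `epoch_set` from [segment_epochs()].
#' @param cfg a [feature_config()].
#' @return named numeric feature vector.
#' @export
extract_subject <- function(epochs, cfg = feature_config()) {
  stop_if(!inherits(epochs, "epoch_set"), "epochs must be an epoch_set")
  stop_if(epochs$m < 1L, "need at least one epoch per channel")
  fs <- epochs$fs
  labels <- epochs$labels
  fb <- feature_bands(cfg)
  wb <- whole_band(cfg)
  stop_if(max(fb$hi, wb$hi) >= fs / 2, "band above Nyquist")

  pairs <- cfg$hemi_pairs
  pairs <- pairs[pairs$left %in% labels & pairs$right %in% labels, , drop = FALSE]
  stop_if(nrow(pairs) < 1L,
          "no configured hemisphere pair present in the recording")
  pair_chans <- unique(c(pairs$left, pairs$right))

  # per-band filter gains and the analytic-signal multiplier depend only
  # on the epoch length; compute them once for all channels and epochs
  nsamp <- dim(epochs$data)[2L]
  gains <- lapply(seq_len(nrow(fb)), function(bi)
    band_gain(nsamp, fs, fb$lo[bi], fb$hi[bi], cfg$filter_order))
  hmult <- hilbert_multiplier(nsamp)

  acc <- NULL
  for (e in seq_len(epochs$m)) {
    row <- extract_epoch(epochs$data[, , e, drop = FALSE], fs, labels,
                         cfg, fb, wb, pairs, pair_chans, gains, hmult)
    acc <- if (is.null(acc)) row else acc + row
  }
  acc / epochs$m
}

extract_epoch <- function(slab, fs, labels, cfg, fb, wb, pairs, pair_chans,
                          gains, hmult) {
  nch <- length(labels)
  nb <- nrow(fb)
  psds <- vector("list", nch); names(psds) <- labels
  envs <- vector("list", nch); names(envs) <- labels

  amp <- matrix(0, 6L, nch * nb)
  reeg <- matrix(0, 7L, nch * nb)
  spec <- matrix(0, 6L, nch * nb)
  fd <- numeric(nch)
  amp_names <- character(nch * nb)

  col <- 0L
  for (ci in seq_len(nch)) {
    x <- slab[ci, , 1L]
    X <- fft(x)
    psds[[ci]] <- welch_psd(x, fs, win = cfg$psd_win, overlap = cfg$psd_overlap,
                            keep_fft = TRUE)
    fd[ci] <- higuchi_fd(x, cfg$higuchi_kmax)
    keep_env <- labels[ci] %in% pair_chans
    if (keep_env) envs[[ci]] <- vector("list", nb)
    for (bi in seq_len(nb)) {
      col <- col + 1L
      fe <- band_filter_env(X, gains[[bi]], hmult)
      amp[, col] <- amplitude_features(fe$x, fe$env)
      reeg[, col] <- reeg_features(fe$x, fs, cfg$reeg_win, cfg$reeg_overlap)
      spec[, col] <- spectral_features(psds[[ci]], fb[bi, ], wb,
                                       cfg$sef_quantile)
      amp_names[col] <- paste0(fb$name[bi], ".", labels[ci])
      if (keep_env) envs[[ci]][[bi]] <- fe$env
    }
  }

  conn <- matrix(0, 5L, nb)
  for (bi in seq_len(nb)) {
    band <- fb[bi, ]
    conn[1L, bi] <- bsi(psds[pairs$left], psds[pairs$right], band)
    xc <- envelope_xcorr_features(
      lapply(envs[pairs$left], `[[`, bi),
      lapply(envs[pairs$right], `[[`, bi),
      fs, cfg$max_lag)
    conn[2L:3L, bi] <- xc
    coh <- mapply(function(l, r)
      coherence_pair(psds[[l]], psds[[r]], band), pairs$left, pairs$right)
    ok <- !is.na(coh[1L, ])
    conn[4L, bi] <- if (any(ok)) mean(coh[1L, ok]) else 0
    conn[5L, bi] <- if (any(ok)) median(coh[2L, ok]) else 0
  }

  v <- c(
    structure(as.numeric(amp),
              names = paste0("amplitude.",
                             rep(c("total_power", "sd", "skewness", "kurtosis",
                                   "env_mean", "env_sd"), nch * nb), ".",
                             rep(amp_names, each = 6L))),
    structure(as.numeric(reeg),
              names = paste0("reeg.",
                             rep(c("mean", "median", "p5", "p95", "sd", "cv",
                                   "symmetry"), nch * nb), ".",
                             rep(amp_names, each = 7L))),
    structure(as.numeric(spec),
              names = paste0("spectral.",
                             rep(c("power", "rel_power", "wiener_entropy",
                                   "shannon_entropy", "edge_freq",
                                   "spectral_diff"), nch * nb), ".",
                             rep(amp_names, each = 6L))),
    structure(as.numeric(conn),
              names = paste0("connectivity.",
                             rep(c("bsi", "xcorr_median", "xcorr_lag",
                                   "coh_mean", "coh_peak_freq"), nb), ".",
                             rep(fb$name, each = 5L))),
    structure(fd, names = paste0("fd.higuchi.broadband.", labels))
  )
  v
}

#' Tabulate feature counts by domain
#'
#' @param features named feature vector (from [extract_subject()]) or a
#'   character vector of feature names.
#' @return named integer vector of per-domain column counts.
#' @export
feature_counts <- function(features) {
  nm <- if (is.character(features)) features else names(features)
  domain <- sub("\\..*$", "", nm)
  table(factor(domain, levels = c("amplitude", "reeg", "spectral",
                                  "connectivity", "fd")))
}

#' Parse structured feature names
#'
#' Splits `<domain>.<feature>.<band>[.<channel>]` names into a data frame.
#' Unparseable names yield `NA` fields.
#'
#' @param nm character vector of feature names.
#' @return data frame with columns `name`, `domain`, `feature`, `band`,
#'   `channel`.
#' @export
parse_feature_names <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  get <- function(p, i) if (length(p) >= i) p[i] else NA_character_
  data.frame(
    name = nm,
    domain = vapply(parts, get, "", 1L),
    feature = vapply(parts, get, "", 2L),
    band = vapply(parts, get, "", 3L),
    channel = vapply(parts, function(p)
      if (length(p) >= 4L) paste(p[-(1:3)], collapse = ".") else NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Extract a feature table from a list of recordings
#'
#' Segments each recording into epochs and extracts one feature row per
#' subject, returning a data frame with `subject_id`, `age` (if supplied)
#' and one column per feature.
#'
#' @param recordings list of [raw_recording()] objects.
#' @param ages optional numeric chronological ages, one per recording.
#' @param cfg a [feature_config()].
#' @param epoch_len,overlap epoch segmentation parameters (60 s, 0.5).
#' @param subject_ids optional character ids (default `S001`, ...).
#' @return a feature table data frame.
#' @export
extract_table <- function(recordings, ages = NULL, cfg = feature_config(),
                          epoch_len = 60, overlap = 0.5, subject_ids = NULL) {
  n <- length(recordings)
  stop_if(n < 1L, "no recordings")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  rows <- lapply(recordings, function(rec)
    extract_subject(segment_epochs(rec, epoch_len, overlap), cfg))
  mat <- do.call(rbind, rows)
  out <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  if (!is.null(ages)) out$age <- as.numeric(ages)
  cbind(out, as.data.frame(mat, optional = TRUE))
}

#' Names of the non-feature key columns of a feature table
#' @keywords internal
#' @export
meta_columns <- function() c("subject_id", "age", "sex")

feature_matrix <- function(table) {
  cols <- setdiff(names(table), meta_columns())
  as.matrix(table[, cols, drop = FALSE])
}
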