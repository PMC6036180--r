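test_that("band filter keeps in-band tones and rejects out-of-band ones", {
  fs <- 250
  x <- make_sine(10, fs, 8)
  inb <- band_filter(x, 7, 13, fs)
  expect_lt(abs(sqrt(2 * mean(inb^2)) - 1), 0.05)     # alpha passes 10 Hz
  outb <- band_filter(x, 13, 30, fs)
  expect_lt(sqrt(2 * mean(outb^2)), 0.10)             # beta rejects 10 Hz

  set.seed(1)
  noise <- rnorm(fs * 8)
  d <- band_filter(noise, 0.5, 4, fs)
  psd <- welch_psd(d, fs)
  below5 <- sum(psd$power[psd$freqs < 5])
  expect_gt(below5 / sum(psd$power), 0.90)
  expect_error(band_filter(x, 7, 130, fs), "Nyquist")
})

test_that("envelope follows the squared analytic-signal magnitude", {
  fs <- 250
  x <- make_sine(10, fs, 4)
  e <- envelope(x)
  interior <- 100:(length(x) - 100)
  expect_lt(max(abs(e[interior] - 1)), 0.02)          # |analytic|^2 of unit sine
  e3 <- envelope(3 * x)
  expect_lt(max(abs(e3[interior] - 9)), 0.2)          # amplitude a -> a^2

  # AM sine: envelope tracks the squared modulation
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  am <- (1 + 0.5 * cos(2 * pi * 0.5 * t))
  e_am <- envelope(am * sin(2 * pi * 20 * t))
  truth <- am^2
  rel_rmse <- sqrt(mean((e_am[interior] - truth[interior])^2)) /
    sqrt(mean(truth[interior]^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("amplitude features recover known moments", {
  set.seed(2)
  x <- rnorm(200000)
  a <- amplitude_features(x)
  expect_lt(abs(a["total_power"] - 1), 0.02)
  expect_lt(abs(a["sd"] - 1), 0.01)
  expect_lt(abs(a["skewness"]), 0.03)
  expect_lt(abs(a["kurtosis"] - 3), 0.06)             # raw kurtosis

  s <- make_sine(10, 250, 4)
  expect_lt(abs(amplitude_features(s)["total_power"] - 0.5), 0.01)

  expect_warning(z <- amplitude_features(rep(0, 500)), "constant")
  expect_equal(unname(z[c("total_power", "sd", "env_mean")]), c(0, 0, 0))
})

test_that("range-EEG features behave on constant and sinusoidal input", {
  fs <- 250
  expect_warning(z <- reeg_features(rep(0, 4 * fs), fs), "zero mean")
  expect_equal(unname(z["mean"]), 0)
  expect_equal(unname(z["median"]), 0)

  s <- make_sine(10, fs, 8)
  r <- reeg_features(s, fs)
  expect_lt(abs(r["mean"] - 2), 0.01)  # peak-to-peak of unit sine (25 samples/cycle)
  expect_lt(r["sd"], 1e-6)             # every window sees identical extrema
  expect_lt(abs(r["cv"]), 1e-6)
})

test_that("Welch PSD locates peaks and satisfies Parseval", {
  fs <- 250
  s <- make_sine(10, fs, 8)
  psd <- welch_psd(s, fs)
  expect_equal(psd$freqs[which.max(psd$power)], 10, tolerance = 0.51)

  set.seed(3)
  sigma <- 2.5
  noise <- rnorm(fs * 30, sd = sigma)
  psd_n <- welch_psd(noise, fs)
  expect_lt(abs(sum(psd_n$power) * psd_n$df - sigma^2) / sigma^2, 0.1)

  two <- make_sine(6, fs, 8) + make_sine(20, fs, 8, amp = 0.8)
  psd2 <- welch_psd(two, fs)
  top2 <- psd2$freqs[order(psd2$power, decreasing = TRUE)[1:2]]
  expect_setequal(round(sort(top2)), c(6, 20))
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("spectral features hit their analytic limits", {
  freqs <- seq(0, 125, by = 0.5)
  flat <- structure(list(freqs = freqs, power = rep(1, length(freqs)),
                         df = 0.5, segments = matrix(1, length(freqs), 3)),
                    class = "psd_estimate")
  band <- data.frame(name = "alpha", lo = 7, hi = 13)
  whole <- data.frame(name = "whole", lo = 0.5, hi = 30)
  f <- spectral_features(flat, band, whole)
  expect_equal(unname(f["wiener_entropy"]), 1)
  expect_equal(unname(f["shannon_entropy"]), 1)

  single <- flat
  single$power <- numeric(length(freqs))
  single$power[freqs == 10] <- 5
  single$segments <- matrix(single$power, ncol = 1)
  g <- spectral_features(single, band, whole)
  expect_equal(unname(g["wiener_entropy"]), 0)
  expect_equal(unname(g["shannon_entropy"]), 0)
  expect_equal(unname(g["edge_freq"]), 10)

  # relative power over the four bands partitions a band-limited signal
  set.seed(4)
  fs <- 250
  x <- band_filter(rnorm(fs * 20), 0.5, 30, fs)
  psd <- welch_psd(x, fs)
  rels <- vapply(c("delta", "theta", "alpha", "beta"), function(b) {
    bd <- default_bands()[default_bands()$name == b, ]
    spectral_features(psd, bd, whole)["rel_power"]
  }, 0)
  expect_lt(abs(sum(rels) - 1), 0.05)
})

test_that("brain symmetry index matches closed-form cases and is symmetric", {
  fs <- 250
  set.seed(5)
  x <- rnorm(fs * 10)
  p1 <- welch_psd(x, fs)
  band <- data.frame(name = "alpha", lo = 7, hi = 13)

  expect_equal(bsi(list(p1), list(p1), band), 0)

  p0 <- p1; p0$power <- rep(0, length(p1$power))
  expect_equal(bsi(list(p1), list(p0), band), 1)

  p3 <- p1; p3$power <- 3 * p1$power
  expect_equal(bsi(list(p1), list(p3), band), 0.5)    # |1-3|/(1+3)

  p2 <- welch_psd(rnorm(fs * 10), fs)
  expect_equal(bsi(list(p1), list(p2), band), bsi(list(p2), list(p1), band))
  v <- bsi(list(p1), list(p2), band)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("envelope cross-correlation finds identity, delay and independence", {
  fs <- 250
  set.seed(6)
  e <- envelope(band_filter(rnorm(fs * 8), 7, 13, fs))
  same <- envelope_xcorr(e, e, fs)
  expect_equal(unname(same["max_corr"]), 1)
  expect_equal(unname(same["lag_at_max"]), 0)

  # second series delayed by d samples: it lags, so the peak sits at -d/fs
  d <- 12
  e2 <- c(rep(e[1], d), e[1:(length(e) - d)])
  del <- envelope_xcorr(e, e2, fs)
  expect_equal(unname(del["lag_at_max"]), -d / fs)

  ind <- envelope_xcorr(envelope(band_filter(rnorm(fs * 8), 7, 13, fs)),
                        envelope(band_filter(rnorm(fs * 8), 7, 13, fs)), fs)
  expect_lt(abs(ind["max_corr"]), 0.3)

  const <- envelope_xcorr(rep(1, 1000), e[1:1000], fs)
  expect_true(is.na(const["max_corr"]))
})

test_that("coherence is 1 for identical signals and peaks at a shared tone", {
  fs <- 250
  set.seed(7)
  x <- rnorm(fs * 30)
  px <- welch_psd(x, fs, keep_fft = TRUE)
  band <- data.frame(name = "alpha", lo = 7, hi = 13)
  expect_equal(unname(coherence_pair(px, px, band)["mean_coh"]), 1)

  py <- welch_psd(rnorm(fs * 30), fs, keep_fft = TRUE)
  expect_lt(coherence_pair(px, py, band)["mean_coh"], 0.2)

  shared <- make_sine(10, fs, 30, amp = 3)
  pa <- welch_psd(shared + rnorm(fs * 30), fs, keep_fft = TRUE)
  pb <- welch_psd(shared + rnorm(fs * 30), fs, keep_fft = TRUE)
  expect_equal(unname(coherence_pair(pa, pb, band)["peak_freq"]), 10,
               tolerance = 0.51)
})

test_that("Higuchi fractal dimension separates lines, sines and noise", {
  # boundary cases may clip (a line sits exactly at FD = 1)
  expect_lt(abs(suppressWarnings(higuchi_fd(seq(0, 1, length.out = 2000)))
                - 1), 0.05)
  set.seed(8)
  expect_lt(abs(suppressWarnings(higuchi_fd(rnorm(20000))) - 2), 0.1)
  fd_sine <- higuchi_fd(make_sine(10, 250, 8))
  expect_gt(fd_sine, 1); expect_lt(fd_sine, 1.5)
  expect_warning(fd_const <- higuchi_fd(rep(2, 1000)), "constant")
  expect_equal(fd_const, 1)
})

test_that("per-epoch features match the naive oracle implementations", {
  fs <- 250
  set.seed(10)
  bands <- default_bands()
  alpha <- bands[bands$name == "alpha", ]
  whole <- bands[bands$name == "whole", ]
  for (trial in 1:5) {
    x <- as.numeric(band_filter(rnorm(4 * fs, sd = runif(1, 0.5, 20)),
                                0.5, 30, fs))
    xf <- band_filter(x, 7, 13, fs)
    expect_equal(xf, naive_band_filter(x, 7, 13, fs), tolerance = 1e-9)

    env <- envelope(xf)
    expect_equal(env, naive_envelope(xf), tolerance = 1e-9)

    expect_equal(amplitude_features(xf, env), naive_amplitude(xf, env),
                 tolerance = 1e-9)
    expect_equal(reeg_features(xf, fs), naive_reeg(xf, fs), tolerance = 1e-9)

    psd <- welch_psd(x, fs, keep_fft = TRUE)
    np <- naive_welch(x, fs)
    expect_equal(psd$power, np$power, tolerance = 1e-9)
    expect_equal(
      spectral_features(psd, alpha, whole),
      naive_spectral(np, 7, 13, 0.5, 30), tolerance = 1e-9)

    y <- as.numeric(band_filter(rnorm(4 * fs), 0.5, 30, fs))
    psy <- welch_psd(y, fs, keep_fft = TRUE)
    ny <- naive_welch(y, fs)
    expect_equal(bsi(list(psd), list(psy), alpha),
                 naive_bsi(list(np), list(ny), 7, 13), tolerance = 1e-9)
    expect_equal(unname(coherence_pair(psd, psy, alpha)),
                 unname(naive_coherence(np, ny, 7, 13)), tolerance = 1e-9)

    expect_equal(higuchi_fd(x), naive_higuchi(x), tolerance = 1e-9)

    e1 <- envelope(xf); e2 <- envelope(band_filter(y, 7, 13, fs))
    fast <- envelope_xcorr(e1, e2, fs, max_lag = 0.2)
    slow <- naive_lagged_rankcorr(e1, e2, round(0.2 * fs))
    expect_equal(unname(fast["max_corr"]), max(slow), tolerance = 1e-9)
    expect_equal(unname(fast["lag_at_max"]),
                 (which.max(slow) - 1 - round(0.2 * fs)) / fs,
                 tolerance = 1e-12)
  }
})

test_that("extract_subject has the documented column layout", {
  rec <- short_recording(seed = 21, duration = 60)
  fv <- extract_subject(segment_epochs(rec, 60, 0.5))
  counts <- feature_counts(fv)
  expect_equal(unname(counts["amplitude"]), 744L)
  expect_equal(unname(counts["reeg"]), 868L)
  expect_equal(unname(counts["spectral"]), 744L)
  expect_equal(unname(counts["connectivity"]), 20L)
  expect_equal(unname(counts["fd"]), 31L)
  expect_false(anyNA(fv))
  expect_false(anyDuplicated(names(fv)) > 0)
})

test_that("epoch averaging is an identity for m = 1 and order-invariant", {
  rec <- short_recording(seed = 22, duration = 90)
  ep <- segment_epochs(rec, 60, 0.5)          # m = 2
  one <- ep; one$data <- ep$data[, , 1, drop = FALSE]; one$m <- 1L
  two <- ep; two$data <- ep$data[, , 2, drop = FALSE]; two$m <- 1L
  f1 <- extract_subject(one)
  f2 <- extract_subject(two)
  favg <- extract_subject(ep)
  expect_equal(favg, (f1 + f2) / 2, tolerance = 1e-12)

  swapped <- ep; swapped$data <- ep$data[, , c(2, 1)]
  expect_equal(extract_subject(swapped), favg, tolerance = 1e-12)
})

test_that("features scale as expected under amplitude scaling", {
  rec <- short_recording(seed = 23, duration = 60)
  ep <- segment_epochs(rec, 60, 0.5)
  f1 <- extract_subject(ep)
  a <- 3
  ep2 <- ep; ep2$data <- a * ep$data
  f2 <- extract_subject(ep2)

  expect_equal(f2[grep("amplitude.total_power", names(f1))],
               a^2 * f1[grep("amplitude.total_power", names(f1))],
               tolerance = 1e-8)
  expect_equal(f2[grep("reeg.mean", names(f1))],
               a * f1[grep("reeg.mean", names(f1))], tolerance = 1e-8)
  scale_free <- c(grep("reeg.cv", names(f1)), grep("reeg.symmetry", names(f1)),
                  grep("wiener|shannon|edge_freq|rel_power", names(f1)),
                  grep("^fd\\.|bsi|coh_mean|xcorr", names(f1)))
  expect_equal(f2[scale_free], f1[scale_free], tolerance = 1e-6)
})

test_that("extraction is deterministic across repeated calls", {
  rec <- short_recording(seed = 24, duration = 60)
  ep <- segment_epochs(rec, 60, 0.5)
  expect_identical(extract_subject(ep), extract_subject(ep))
})
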