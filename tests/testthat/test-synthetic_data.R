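test_that("simulation is deterministic and correctly dimensioned", {
  spec <- cohort_spec(n_subjects = 3, duration = 10, seed = 1)
  a <- simulate_subject(spec, age = 30, seed = 5)
  b <- simulate_subject(spec, age = 30, seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_equal(dim(a$recording$data), c(31, 2500))
  expect_identical(a$recording$labels, synthetic_labels(31))

  co <- simulate_cohort(spec)
  expect_equal(length(co$recordings), 3)
  expect_equal(nrow(co$metadata), 3)
  expect_equal(nrow(co$truth), 3)
  expect_true(all(co$metadata$age >= 18 & co$metadata$age <= 58))
  expect_setequal(unique(co$metadata$sex), c("F", "M"))
})

test_that("a noise-free single alpha oscillator has relative alpha power near 1", {
  be <- default_band_effects()
  be$amp0 <- c(0, 0, 20, 0)
  be$amp_slope <- 0
  spec <- cohort_spec(n_subjects = 1, duration = 20, snr = Inf,
                      band_effects = be, subject_scatter = 0, seed = 2)
  rec <- simulate_subject(spec, age = 30, seed = 3)$recording
  psd <- welch_psd(rec$data[1, ], rec$fs)
  bands <- default_bands()
  alpha <- bands[bands$name == "alpha", ]
  whole <- bands[bands$name == "whole", ]
  f <- spectral_features(psd, alpha, whole)
  expect_gt(f["rel_power"], 0.95)
})

test_that("younger subjects carry more alpha power than older ones", {
  spec <- cohort_spec(n_subjects = 1, duration = 20, seed = 4)
  bands <- default_bands()
  alpha <- bands[bands$name == "alpha", ]
  diffs <- vapply(1:10, function(s) {
    young <- simulate_subject(spec, age = 20, seed = child_seed(4, s, 1))
    old <- simulate_subject(spec, age = 55, seed = child_seed(4, s, 2))
    py <- welch_psd(young$recording$data[1, ], 250)
    po <- welch_psd(old$recording$data[1, ], 250)
    inb <- py$freqs >= alpha$lo & py$freqs < alpha$hi
    sum(py$power[inb]) - sum(po$power[inb])
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("alpha power correlates negatively with age across a cohort", {
  spec <- cohort_spec(n_subjects = 40, duration = 20, seed = 6)
  co <- simulate_cohort(spec)
  bands <- default_bands()
  alpha <- bands[bands$name == "alpha", ]
  ap <- vapply(co$recordings, function(r) {
    psd <- welch_psd(r$data[1, ], r$fs)
    inb <- psd$freqs >= alpha$lo & psd$freqs < alpha$hi
    log(sum(psd$power[inb]))
  }, 0)
  r <- cor(ap, co$metadata$age)
  expect_lt(r, -0.3)
})

test_that("hemispheric asymmetry drives a positive brain symmetry index", {
  spec <- cohort_spec(n_subjects = 1, duration = 20, asymmetry = 0.4,
                      snr = Inf, seed = 7)
  rec <- simulate_subject(spec, age = 30, seed = 8)$recording
  hemi <- channel_hemisphere(rec$labels)
  psds <- lapply(seq_len(nrow(rec$data)), function(i)
    welch_psd(rec$data[i, ], rec$fs))
  bands <- default_bands()
  alpha <- bands[bands$name == "alpha", ]
  v <- bsi(psds[hemi == "left"], psds[hemi == "right"], alpha)
  expect_gt(v, 0.05)
})

test_that("ground truth aligns with the generative parameters", {
  spec <- cohort_spec(n_subjects = 2, duration = 5, subject_scatter = 0,
                      seed = 9)
  sub <- simulate_subject(spec, age = 40, seed = 10)
  be <- default_band_effects()
  expect_equal(sub$truth$amp_alpha,
               be$amp0[be$band == "alpha"] + 40 * be$amp_slope[be$band == "alpha"])
  expect_equal(sub$truth$freq_alpha,
               be$freq0[be$band == "alpha"] + 40 * be$freq_slope[be$band == "alpha"])
})
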