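# Fixture builders shared across the test files. Everything is generated
# in code at test time; nothing is read from disk except files the tests
# themselves write.

make_sine <- function(freq, fs, dur, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

make_rec <- function(data, fs, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  raw_recording(data, fs = fs, labels = labels)
}

# two-channel pair configuration for small hand-built recordings
pair_cfg <- function(left = "L1", right = "R1", ...) {
  feature_config(hemi_pairs = data.frame(left = left, right = right), ...)
}

# short feature-level synthetic table: age is a linear function of the
# first features plus noise
linear_table <- function(n = 60, p = 20, noise = 1, seed = 1,
                         slopes = c(3, -2)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("spectral.power.alpha.C", seq_len(p))))
  age <- 35 + as.vector(x[, seq_along(slopes), drop = FALSE] %*% slopes) +
    rnorm(n, 0, noise)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)), age = age, x,
             check.names = FALSE)
}

fast_cfg <- function(seed = 1, ...) ncv_config(fast = TRUE, seed = seed, ...)

# small synthetic recording for feature-count and io tests
short_recording <- function(seed = 5, duration = 60, n_channels = 31) {
  spec <- cohort_spec(n_subjects = 1, duration = duration,
                      n_channels = n_channels, seed = seed)
  simulate_subject(spec, age = 35, seed = seed)$recording
}
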