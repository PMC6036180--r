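# Independent naive oracle implementations. Deliberately simple and
# unvectorised (direct DFT matrices, explicit loops); they share no code
# with the package's computation paths and are only run on short signals.

naive_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  s <- if (inverse) 1 else -1
  M <- exp(s * 2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(M %*% x)
}

naive_band_filter <- function(x, lo, hi, fs, order = 4) {
  n <- length(x)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  fp <- pmax(f, 1e-300)
  q <- (fp^2 - lo * hi) / ((hi - lo) * fp)
  g <- 1 / (1 + q^(2 * order))
  Re(naive_dft(naive_dft(x) * g, inverse = TRUE)) / n
}

naive_envelope <- function(x) {
  n <- length(x)
  X <- naive_dft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  a <- naive_dft(X * h, inverse = TRUE) / n
  Mod(a)^2
}

naive_amplitude <- function(x, env = naive_envelope(x)) {
  n <- length(x)
  mx <- sum(x) / n
  m2 <- sum((x - mx)^2) / n
  m3 <- sum((x - mx)^3) / n
  m4 <- sum((x - mx)^4) / n
  me <- sum(env) / length(env)
  c(total_power = sum(x^2) / n,
    sd = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    env_mean = me,
    env_sd = sqrt(sum((env - me)^2) / length(env)))
}

naive_reeg <- function(x, fs, win = 2, overlap = 0.5) {
  w <- round(win * fs)
  step <- round(w * (1 - overlap))
  ranges <- c()
  s <- 1
  while (s + w - 1 <= length(x)) {
    seg <- x[s:(s + w - 1)]
    ranges <- c(ranges, max(seg) - min(seg))
    s <- s + step
  }
  m <- sum(ranges) / length(ranges)
  sdev <- sqrt(sum((ranges - m)^2) / length(ranges))
  q <- quantile(ranges, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  spread <- q[3] - q[1]
  c(mean = m, median = q[2], p5 = q[1], p95 = q[3], sd = sdev,
    cv = if (abs(m) > 0) sdev / m else 0,
    symmetry = if (spread > 0) ((q[3] - q[2]) - (q[2] - q[1])) / spread else 0)
}

naive_welch <- function(x, fs, win = 2, overlap = 0.5) {
  w <- round(win * fs)
  step <- round(w * (1 - overlap))
  taper <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  u <- sum(taper^2)
  nb <- w %/% 2 + 1
  segs <- NULL
  cffts <- NULL
  s <- 1
  while (s + w - 1 <= length(x)) {
    seg <- x[s:(s + w - 1)]
    seg <- (seg - sum(seg) / w) * taper
    X <- naive_dft(seg)[1:nb]
    pxx <- Mod(X)^2 / (fs * u)
    for (k in 2:nb) if (!(w %% 2 == 0 && k == nb)) pxx[k] <- 2 * pxx[k]
    segs <- cbind(segs, pxx)
    cffts <- cbind(cffts, X)
    s <- s + step
  }
  list(freqs = (0:(nb - 1)) * fs / w, power = rowMeans(segs),
       df = fs / w, segments = segs, cfft = cffts)
}

naive_spectral <- function(np, lo, hi, wlo, whi, sef = 0.95) {
  inb <- np$freqs >= lo & np$freqs < hi
  inw <- np$freqs >= wlo & np$freqs < whi
  p <- np$power[inb]
  bp <- sum(p) * np$df
  wp <- sum(np$power[inw]) * np$df
  tot <- sum(p)
  wiener <- if (any(p <= 0)) 0 else exp(sum(log(p)) / length(p)) / (tot / length(p))
  q <- p / tot
  shannon <- -sum(q[q > 0] * log(q[q > 0])) / log(length(q))
  edge <- np$freqs[inb][min(which(cumsum(p) / tot >= sef))]
  amp <- sqrt(np$segments[inb, , drop = FALSE])
  k <- ncol(amp)
  sdiff <- if (k < 2) 0 else {
    acc <- 0
    for (t in 1:(k - 1)) acc <- acc + sum((amp[, t + 1] - amp[, t])^2)
    acc / ((k - 1) * nrow(amp))
  }
  c(power = bp, rel_power = bp / wp, wiener_entropy = wiener,
    shannon_entropy = shannon, edge_freq = edge, spectral_diff = sdiff)
}

naive_bsi <- function(pl_list, pr_list, lo, hi) {
  f <- pl_list[[1]]$freqs
  pl <- Reduce(`+`, lapply(pl_list, `[[`, "power")) / length(pl_list)
  pr <- Reduce(`+`, lapply(pr_list, `[[`, "power")) / length(pr_list)
  inb <- which(f >= lo & f < hi)
  vals <- c()
  for (k in inb) {
    den <- pl[k] + pr[k]
    if (den > 0) vals <- c(vals, abs((pl[k] - pr[k]) / den))
  }
  if (length(vals) == 0) 0 else sum(vals) / length(vals)
}

naive_coherence <- function(nx, ny, lo, hi) {
  f <- nx$freqs
  sxy <- rowMeans(nx$cfft * Conj(ny$cfft))
  sxx <- rowMeans(Mod(nx$cfft)^2)
  syy <- rowMeans(Mod(ny$cfft)^2)
  inb <- f >= lo & f < hi
  coh <- Mod(sxy[inb])^2 / (sxx[inb] * syy[inb])
  c(mean_coh = mean(coh), peak_freq = f[inb][which.max(coh)])
}

naive_higuchi <- function(x, kmax = 6) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in 1:kmax) {
    Lm <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      nd <- length(idx) - 1
      if (nd < 1) next
      s <- 0
      for (i in 2:length(idx)) s <- s + abs(x[idx[i]] - x[idx[i - 1]])
      Lm <- c(Lm, s * (n - 1) / (nd * k) / k)
    }
    L[k] <- mean(Lm)
  }
  -unname(coef(lm(log(L) ~ log(1:kmax)))[2])
}

# Pearson correlation of globally rank-transformed envelopes over the
# overlap at each lag; positive lag means the second series leads
naive_lagged_rankcorr <- function(e1, e2, max_lag_samples) {
  r1 <- rank(e1, ties.method = "average")
  r2 <- rank(e2, ties.method = "average")
  n <- length(r1)
  lags <- -max_lag_samples:max_lag_samples
  out <- numeric(length(lags))
  for (i in seq_along(lags)) {
    L <- lags[i]
    if (L >= 0) out[i] <- cor(r1[(L + 1):n], r2[1:(n - L)])
    else out[i] <- cor(r1[1:(n + L)], r2[(1 - L):n])
  }
  out
}
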