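fit_small_ncv <- function(noise = 0.5, seed = 1, n = 60, p = 10) {
  tab <- linear_table(n = n, p = p, noise = noise, seed = seed,
                      slopes = c(4))
  res <- run_ncv(tab, fast_cfg(seed = seed))
  list(tab = tab, res = res)
}

test_that("importance sums to 100 per fold and finds the dominant feature", {
  f <- fit_small_ncv(noise = 0.2, seed = 2)
  imp <- importance(f$res, f$tab)
  sums <- colSums(imp[grep("^fold", names(imp))])
  expect_equal(unname(sums), rep(100, f$res$cfg$K_O), tolerance = 1e-9)
  expect_equal(imp$feature[1], "spectral.power.alpha.C1")
  # the driver tops every fold
  fold_cols <- grep("^fold", names(imp))
  for (k in fold_cols) {
    expect_equal(imp$feature[which.max(imp[[k]])], "spectral.power.alpha.C1")
  }
  # correlation annotation matches a direct computation
  expect_equal(imp$cor_age[imp$feature == "spectral.power.alpha.C1"],
               cor(f$tab$age, f$tab[["spectral.power.alpha.C1"]]))
})

test_that("pure-noise features get near-uniform importance", {
  set.seed(3)
  n <- 60; p <- 12
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("reeg.mean.beta.C", 1:p)))
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n), age = runif(n, 18, 58),
                    x, check.names = FALSE)
  res <- run_ncv(tab, fast_cfg(seed = 3, methods = c("enet", "rf", "xgb")))
  imp <- importance(res, tab)
  expect_lt(max(imp$mean_importance), 5 * median(imp$mean_importance))
})

test_that("partial dependence recovers linear structure and flatness", {
  f <- fit_small_ncv(noise = 0.2, seed = 4)
  pd <- pdp(f$res, f$tab, "spectral.power.alpha.C1", grid_size = 15)
  # near-linear increasing relation with slope close to the true 4
  for (l in unique(pd$fold)) {
    cc <- pd[pd$fold == l, ]
    expect_gt(cor(cc$value, cc$yhat), 0.99)
    slope <- coef(lm(yhat ~ value, cc))[2]
    expect_gt(slope, 2); expect_lt(slope, 5)
  }
  # an ignored feature yields a flat curve relative to the signal one
  pd0 <- pdp(f$res, f$tab, "spectral.power.alpha.C9", grid_size = 15)
  range_sig <- diff(range(pd$yhat))
  range_null <- diff(range(pd0$yhat))
  expect_lt(range_null, 0.2 * range_sig)
})

test_that("pdp consistency statistic hits its analytic limits", {
  g <- seq(0, 1, length.out = 20)
  curves <- rbind(
    data.frame(feature = "f", fold = 1, value = g, yhat = 2 * g),
    data.frame(feature = "f", fold = 2, value = g, yhat = 2 * g + 1))
  expect_equal(pdp_consistency(curves), 1)
  flipped <- curves
  flipped$yhat[flipped$fold == 2] <- -2 * g
  expect_equal(pdp_consistency(flipped), -1)

  f <- fit_small_ncv(noise = 0.2, seed = 5)
  pd <- pdp(f$res, f$tab, "spectral.power.alpha.C1", grid_size = 15)
  expect_gt(pdp_consistency(pd), 0.8)
})

test_that("spatial aggregation parses names and normalises shares", {
  imp <- data.frame(
    feature = c("spectral.power.alpha.C1", "spectral.power.alpha.C2",
                "reeg.mean.beta.C1", "fd.higuchi.broadband.C1",
                "connectivity.bsi.alpha"),
    mean_importance = c(50, 20, 20, 5, 5))
  class(imp) <- c("importance_table", "data.frame")
  sp <- spatial_importance(imp)
  expect_equal(sum(sp$domain_share), 100)
  expect_equal(unname(sp$domain_share["spectral"]), 70)
  expect_equal(sum(sp$band_share), 100)
  # importance concentrated on one channel dominates its grid
  expect_equal(colnames(sp$grids$spectral)[which.max(sp$grids$spectral)], "C1")

  # uniform importance over equal feature counts gives a flat grid
  uni <- data.frame(
    feature = as.vector(outer(paste0("amplitude.sd."), paste0(
      rep(c("alpha", "beta"), each = 3), ".C", 1:3), paste0)),
    mean_importance = rep(10, 6))
  class(uni) <- c("importance_table", "data.frame")
  g <- spatial_importance(uni)$grids$amplitude
  expect_lt(max(g) / min(g), 1.5)
})
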