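test_that("fold assignment is balanced, exhaustive and reproducible", {
  f <- make_folds(100, 10, seed = 1)
  expect_equal(as.numeric(table(f)), rep(10, 10))
  expect_identical(f, make_folds(100, 10, seed = 1))
  expect_false(identical(f, make_folds(100, 10, seed = 2)))

  f2 <- make_folds(468, 10, seed = 3)
  expect_true(all(table(f2) %in% c(46, 47)))
  expect_equal(length(f2), 468)
  expect_error(make_folds(5, 10, 1), "fewer")
})

test_that("the one-standard-error rule selects the simplest adequate point", {
  # point 2 is best; point 1 (simpler) is within one SE -> chosen
  expect_equal(select_one_se(c(5.0, 4.8), c(0.3, 0.3), 1:2), 1)
  # dominating point more than one SE better stays selected
  expect_equal(select_one_se(c(5.0, 3.0), c(0.3, 0.3), 1:2), 2)
  # parsimony order is respected among qualifying points
  expect_equal(select_one_se(c(4.9, 5.0, 4.8), c(0.3, 0.3, 0.3), c(2, 1, 3)), 2)
  # failed grid points (Inf) are never selected
  expect_equal(select_one_se(c(Inf, 4), c(Inf, 0.1), 1:2), 2)
})

test_that("single-point grids are returned unchanged by tuning", {
  set.seed(1)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, 1] + rnorm(60, sd = 0.1)
  reg <- method_registry()
  folds <- list(make_folds(60, 5, 7))
  tuned <- tune_inner(x, y, reg$enet, data.frame(alpha = 0.5, lambda = 0.1),
                      folds, seed = 3)
  expect_equal(tuned$params$lambda, 0.1)
  expect_equal(dim(tuned$inner_pred), NULL)  # single repeat -> vector
  expect_equal(length(tuned$inner_pred), 60)
  expect_true(all(is.finite(tuned$inner_pred)))
})

test_that("pure-noise response makes one-SE pick the most regularised point", {
  reg <- method_registry()
  grid <- expand.grid(alpha = 0.5, lambda = c(0.01, 0.1, 1, 10))
  picks <- vapply(1:5, function(s) {
    set.seed(s)
    x <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(NULL, paste0("f", 1:10)))
    y <- rnorm(80)
    folds <- list(make_folds(80, 5, child_seed(s, 1)))
    tune_inner(x, y, reg$enet, grid, folds, seed = s)$params$lambda
  }, 0)
  expect_gte(median(picks), 10)  # heaviest shrinkage wins on noise
})

test_that("stack weights identify a perfect base model", {
  set.seed(2)
  n <- 200
  age <- runif(n, 18, 58)
  preds <- cbind(good = age, bad1 = rnorm(n, mean(age), 10),
                 bad2 = rnorm(n, mean(age), 10))
  st <- fit_stack(preds, age, K_Ens = 5, seed = 1)
  expect_lt(abs(st$coef[2] - 1), 0.05)
  expect_lt(max(abs(st$coef[3:4])), 0.05)
  expect_lt(st$cv_rmse, 1)

  # identical (perfectly collinear) base predictions: weights still
  # combine to ~1 and the stacked prediction tracks the common signal
  same <- cbind(a = age + rnorm(n, 0, 0.5), b = 0, c = 0)
  same[, 2] <- same[, 1]; same[, 3] <- same[, 1]
  st2 <- fit_stack(same, age, 5, 1)
  expect_lt(abs(sum(st2$coef[-1]) - 1), 0.1)
  ph <- cbind(1, same) %*% st2$coef
  expect_lt(sqrt(mean((ph - age)^2)), 1)

  # uninformative base predictions collapse to a calibrated intercept
  st3 <- fit_stack(cbind(a = rnorm(n, 35, 5), b = rnorm(n, 35, 5)),
                   age, 5, 1)
  expect_lt(sum(abs(st3$coef[-1])), 0.3)
  expect_lt(abs(st3$coef[1] + sum(st3$coef[-1]) * 35 - mean(age)), 3)
})

test_that("noiseless linear cohorts are recovered near-perfectly", {
  tab <- linear_table(n = 70, p = 10, noise = 1e-6, seed = 5)
  res <- run_ncv(tab, fast_cfg(seed = 2))
  expect_gt(res$metrics$pooled$r2, 0.95)
  expect_equal(nrow(res$predictions), 70)
  expect_equal(sort(unique(res$predictions$outer_fold)), 1:5)
  # every subject predicted exactly once
  expect_false(anyNA(res$predictions$predicted_age))
})

test_that("permuted responses produce no leakage", {
  r2s <- vapply(1:4, function(s) {
    set.seed(s + 100)
    tab <- linear_table(n = 60, p = 15, noise = 1, seed = s)
    tab$age <- sample(tab$age)
    cfg <- fast_cfg(seed = s, methods = c("enet", "rf"))
    run_ncv(tab, cfg)$metrics$pooled$r2
  }, 0)
  expect_lt(mean(r2s), 0.05)
  expect_gt(mean(r2s), -0.30)
})

test_that("identical configuration and seed reproduce the result exactly", {
  tab <- linear_table(n = 50, p = 8, noise = 2, seed = 9)
  cfg <- fast_cfg(seed = 11)
  r1 <- run_ncv(tab, cfg)
  r2 <- run_ncv(tab, cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("metrics follow their closed forms", {
  age <- c(20, 30, 40, 50)
  m <- compute_metrics(age, age)
  expect_equal(m$r2, 1); expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0); expect_equal(m$r, 1)

  m0 <- compute_metrics(rep(mean(age), 4), age)
  expect_equal(m0$r2, 0)

  mc <- compute_metrics(age + 2, age)
  expect_equal(mc$mae, 2); expect_equal(mc$rmse, 2)
  expect_equal(mc$r, 1); expect_lt(mc$r2, 1)

  expect_error(compute_metrics(age, rep(30, 4)), "zero variance")
})

test_that("brain age gap is prediction minus age", {
  age <- c(25, 35, 45)
  expect_equal(brain_age_gap(age, age), c(0, 0, 0))
  expect_equal(brain_age_gap(age + 2, age), c(2, 2, 2))
})

test_that("full-size grids are well-formed and tunable", {
  grids <- default_grids(fast = FALSE)
  reg <- method_registry()
  expect_setequal(names(grids), names(reg))
  for (m in names(grids)) {
    ord <- reg[[m]]$parsimony(grids[[m]])
    expect_setequal(ord, seq_len(nrow(grids[[m]])))  # valid permutation
  }
  # a multi-point tree-method grid runs through the tuner
  set.seed(7)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1] * 2 + rnorm(40, sd = 0.5)
  folds <- list(make_folds(40, 3, 5))
  tuned <- tune_inner(x, y, reg$rf, grids$rf, folds, seed = 8)
  expect_true(tuned$params$mtry_rule %in% c("sqrt", "third"))
  expect_true(all(is.finite(tuned$grid_mean)))
})

test_that("learning curve at full size matches a direct run", {
  tab <- linear_table(n = 40, p = 6, noise = 1, seed = 3)
  cfg <- fast_cfg(seed = 4, methods = c("enet", "gpr"))
  lc <- learning_curve(tab, cfg, sizes = 40, n_seeds = 1)
  direct <- run_ncv(tab, cfg)
  expect_equal(lc$r2, direct$metrics$pooled$r2)
  expect_warning(learning_curve(tab, cfg, sizes = c(5), n_seeds = 1),
                 "skipped")
})
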