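# Nested cross-validation with stack ensembling.
#
# The outer loop estimates generalisation; the inner loop (K_I folds,
# R repeats) tunes each base regressor's hyperparameters by grid search
# with the one-standard-error rule. Base models refit on the outer training
# fold are combined by a general linear model whose weights are learned on
# the pooled inner-resample held-out predictions, so the meta-model never
# sees the outer test subjects. Concatenating the outer test predictions
# yields exactly one prediction per subject, from which the brain age gap
# (BrainAGE = predicted age - chronological age) is derived.

#' Nested cross-validation configuration
#'
#' @param K_O,K_I outer and inner fold counts (10 each by default).
#' @param R inner repeat count (default 5).
#' @param K_Ens fold count for the stack-ensemble cross-validated RMSE.
#' @param methods base-regressor names among `"enet"`, `"svr"`, `"rf"`,
#'   `"xgb"`, `"gpr"`.
#' @param grids named list of hyperparameter grids ([default_grids()]).
#' @param seed master seed; all fold assignments and fits derive child
#'   seeds from it deterministically.
#' @param fast logical: use the reduced preset (5 outer/inner folds, one
#'   repeat, small grids) sized for desk-scale cohorts.
#' @return an `ncv_config` list.
#' @export
ncv_config <- function(K_O = 10, K_I = 10, R = 5, K_Ens = 10,
                       methods = c("enet", "svr", "rf", "xgb", "gpr"),
                       grids = NULL, seed = 1, fast = FALSE) {
  if (fast) {
    K_O <- 5; K_I <- 5; R <- 1; K_Ens <- 5
    if (is.null(grids)) grids <- default_grids(fast = TRUE)
  }
  if (is.null(grids)) grids <- default_grids(fast = FALSE)
  stop_if(K_O < 2 || K_I < 2 || K_Ens < 2, "fold counts must be at least 2")
  stop_if(R < 1, "R must be at least 1")
  reg <- method_registry()
  stop_if(!all(methods %in% names(reg)), "unknown method name")
  stop_if(!all(methods %in% names(grids)), "missing grid for a method")
  stop_if(any(vapply(grids[methods], nrow, 0L) < 1L), "empty grid")
  structure(list(K_O = K_O, K_I = K_I, R = R, K_Ens = K_Ens,
                 methods = methods, grids = grids, seed = seed),
            class = "ncv_config")
}

#' Balanced random fold assignment
#'
#' Disjoint, exhaustive folds whose sizes differ by at most one,
#' reproducible from the seed.
#'
#' @param n number of subjects.
#' @param K number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..K`, length `n`.
#' @export
make_folds <- function(n, K, seed) {
  stop_if(n < K, "fewer subjects than folds")
  set.seed(seed)
  sample(rep(seq_len(K), length.out = n))
}

#' One-standard-error grid-point selection
#'
#' Given per-grid-point mean tuning losses and their standard errors,
#' selects the most parsimonious point whose mean loss does not exceed the
#' minimum mean loss plus its standard error.
#'
#' @param mean_loss numeric vector of mean losses per grid point.
#' @param se_loss standard errors, same length.
#' @param parsimony_order integer permutation ordering grid points from
#'   simplest to most complex.
#' @return the selected grid-point index.
#' @export
select_one_se <- function(mean_loss, se_loss, parsimony_order) {
  stop_if(length(mean_loss) != length(se_loss), "length mismatch")
  finite <- is.finite(mean_loss)
  stop_if(!any(finite), "no grid point produced a finite loss")
  best <- which(finite)[which.min(mean_loss[finite])]
  thr <- mean_loss[best] + se_loss[best]
  for (i in parsimony_order) {
    if (is.finite(mean_loss[i]) && mean_loss[i] <= thr) return(i)
  }
  best
}

#' Tune one method by inner cross-validation
#'
#' Fits every grid point on each inner resample, scores held-out RMSE, and
#' applies the one-standard-error rule over the method's parsimony
#' ordering. The held-out predictions at the selected point, pooled across
#' the `K_I x R` resamples, are returned for stack training. Grid points
#' whose fit fails are scored as `+Inf` with a warning.
#'
#' @param x training feature matrix (already standardised if the method
#'   expects it).
#' @param y training response.
#' @param method method entry from the registry.
#' @param grid hyperparameter grid (data frame).
#' @param inner_folds list of `R` fold-assignment vectors over the rows of
#'   `x`.
#' @param seed seed for per-fit child seeds.
#' @return list with `params` (selected row), `index`, `mean_rmse`,
#'   `se_rmse`, `grid_mean`, `inner_pred` (rows x R matrix of held-out
#'   predictions at the selected point).
#' @export
tune_inner <- function(x, y, method, grid, inner_folds, seed) {
  G <- nrow(grid)
  R <- length(inner_folds)
  K <- max(inner_folds[[1L]])
  n <- nrow(x)
  rmse <- array(NA_real_, dim = c(G, K, R))
  preds <- array(NA_real_, dim = c(n, R, G))

  for (r in seq_len(R)) {
    folds <- inner_folds[[r]]
    for (k in seq_len(K)) {
      tr <- folds != k
      for (g in seq_len(G)) {
        p <- grid[g, , drop = FALSE]
        fitted <- tryCatch(
          method$fit(x[tr, , drop = FALSE], y[tr], p,
                     child_seed(seed, r, k, g)),
          error = function(e) {
            warning("grid-point fit failed (scored +Inf): ",
                    conditionMessage(e))
            NULL
          })
        if (is.null(fitted)) { rmse[g, k, r] <- Inf; next }
        ph <- tryCatch(method$predict(fitted, x[!tr, , drop = FALSE], p),
                       error = function(e) NULL)
        if (is.null(ph) || !all(is.finite(ph))) { rmse[g, k, r] <- Inf; next }
        rmse[g, k, r] <- sqrt(mean((y[!tr] - ph)^2))
        preds[!tr, r, g] <- ph
      }
    }
  }

  flat <- matrix(rmse, nrow = G)  # G x (K*R)
  mean_rmse <- rowMeans(flat)
  se_rmse <- apply(flat, 1L, function(v)
    if (all(is.finite(v))) sd(v) / sqrt(length(v)) else Inf)
  sel <- select_one_se(mean_rmse, se_rmse, method$parsimony(grid))
  list(params = grid[sel, , drop = FALSE], index = sel,
       mean_rmse = mean_rmse[sel], se_rmse = se_rmse[sel],
       grid_mean = mean_rmse,
       inner_pred = preds[, , sel, drop = TRUE])
}

#' Fit the stack-ensemble general linear model
#'
#' A general linear model of the observed ages on the base methods'
#' held-out inner predictions (intercept plus one coefficient per method),
#' fit under `K_Ens`-fold cross-validation: the weights carry a ridge
#' penalty whose size is chosen to minimise the cross-validated RMSE over
#' the regularisation path. With informative base predictions the selected
#' penalty is at the light end of the path and the fit is essentially
#' ordinary least squares; with uninformative (or collinear) predictions
#' the cross-validation drives the weights toward zero, leaving a
#' calibrated intercept-only model instead of an overfit combination.
#'
#' @param inner_predictions matrix, one column per base method, of pooled
#'   held-out inner-resample predictions.
#' @param ages response aligned with the rows of `inner_predictions`.
#' @param K_Ens fold count for the stack cross-validation.
#' @param seed RNG seed for the stack folds.
#' @return list with `coef` (intercept first), `cv_rmse` at the selected
#'   penalty, and `lambda` (the selected penalty).
#' @export
fit_stack <- function(inner_predictions, ages, K_Ens = 10, seed = 1) {
  P <- as.matrix(inner_predictions)
  stop_if(ncol(P) < 2L, "need predictions from at least two methods")
  stop_if(nrow(P) != length(ages), "prediction/response length mismatch")
  ok <- stats::complete.cases(P) & is.finite(ages)
  P <- P[ok, , drop = FALSE]; ages <- ages[ok]

  # extend glmnet's default ridge path toward zero so the light end of
  # the grid is effectively ordinary least squares
  lam0 <- glmnet::glmnet(P, ages, alpha = 0, nlambda = 30)$lambda
  lam <- unique(c(lam0, min(lam0) * 10^seq(-1, -6)))
  full <- glmnet::glmnet(P, ages, alpha = 0, lambda = lam)
  folds <- make_folds(nrow(P), min(K_Ens, nrow(P)), seed)
  sse <- numeric(length(lam))
  for (k in seq_len(max(folds))) {
    tr <- folds != k
    fit_k <- glmnet::glmnet(P[tr, , drop = FALSE], ages[tr], alpha = 0,
                            lambda = lam)
    ph <- predict(fit_k, P[!tr, , drop = FALSE], s = lam)
    sse <- sse + colSums((ages[!tr] - ph)^2)
  }
  cv_rmse <- sqrt(sse / nrow(P))
  best <- which.min(cv_rmse)
  list(coef = as.numeric(coef(full, s = lam[best])),
       cv_rmse = cv_rmse[best], lambda = lam[best])
}

stack_predict <- function(coefs, base_preds) {
  as.numeric(cbind(1, as.matrix(base_preds)) %*% coefs)
}

#' Regression metrics
#'
#' `R^2 = 1 - SS_resid / SS_total` computed from the predictions (not from
#' a refitted line), mean absolute error, root mean squared error, and the
#' Pearson correlation between prediction and observation.
#'
#' @param pred predicted values.
#' @param obs observed values (must have nonzero variance).
#' @return named list with `r2`, `mae`, `rmse`, `r`.
#' @export
compute_metrics <- function(pred, obs) {
  stop_if(length(pred) != length(obs), "length mismatch")
  stop_if(!all(is.finite(pred)) || !all(is.finite(obs)), "non-finite values")
  sst <- sum((obs - mean(obs))^2)
  stop_if(sst <= 0, "zero variance in observations")
  ssr <- sum((obs - pred)^2)
  list(r2 = 1 - ssr / sst,
       mae = mean(abs(obs - pred)),
       rmse = sqrt(mean((obs - pred)^2)),
       r = if (sd(pred) > 0) cor(pred, obs) else NA_real_)
}

#' Brain age gap
#'
#' BrainAGE per subject: predicted age minus chronological age. Only
#' unbiased (outer-fold) predictions should be used.
#'
#' @param pred predicted ages.
#' @param age chronological ages.
#' @return numeric vector of gaps in years.
#' @export
brain_age_gap <- function(pred, age) {
  stop_if(length(pred) != length(age), "length mismatch")
  as.numeric(pred) - as.numeric(age)
}

#' Run the nested cross-validation pipeline
#'
#' For each outer fold: standardise features on the training portion, tune
#' every base method by inner cross-validation with the
#' one-standard-error rule, refit the tuned base models, learn GLM stack
#' weights on the pooled inner held-out predictions, and predict the
#' held-out outer test subjects. Tree methods receive raw features; the
#' penalised and kernel methods receive the standardised ones.
#'
#' @param table feature table with an `age` column and no missing values.
#' @param cfg an [ncv_config()].
#' @return an `ncv_result`: `predictions` (subject, age, predicted age,
#'   BrainAGE, outer fold), `metrics` (pooled plus per-fold mean and sd),
#'   `base_outer` / `base_inner_rmse` per-method diagnostics, and the
#'   per-fold models needed for interpretation.
#' @export
run_ncv <- function(table, cfg = ncv_config()) {
  stop_if(!"age" %in% names(table), "feature table needs an 'age' column")
  x_all <- feature_matrix(table)
  stop_if(anyNA(x_all), "feature table contains missing values")
  y <- as.numeric(table$age)
  n <- nrow(x_all)
  reg <- method_registry()[cfg$methods]
  M <- length(reg)
  seed <- cfg$seed

  outer <- make_folds(n, cfg$K_O, child_seed(seed, 11))
  pred <- rep(NA_real_, n)
  base_pred <- matrix(NA_real_, n, M, dimnames = list(NULL, cfg$methods))
  folds_out <- vector("list", cfg$K_O)
  fold_metrics <- vector("list", cfg$K_O)
  inner_rmse <- matrix(NA_real_, cfg$K_O, M, dimnames = list(NULL, cfg$methods))

  for (l in seq_len(cfg$K_O)) {
    tr <- outer != l
    stop_if(sum(!tr) < 2L, "outer fold with fewer than two subjects")
    x_tr <- x_all[tr, , drop = FALSE]
    y_tr <- y[tr]
    ctr <- colMeans(x_tr)
    scl <- apply(x_tr, 2L, sd); scl[scl == 0] <- 1
    xs_tr <- scale(x_tr, ctr, scl)
    xs_ts <- scale(x_all[!tr, , drop = FALSE], ctr, scl)

    inner_folds <- lapply(seq_len(cfg$R), function(r)
      make_folds(nrow(x_tr), cfg$K_I, child_seed(seed, 20, l, r)))

    tuned <- vector("list", M); names(tuned) <- cfg$methods
    models <- vector("list", M); names(models) <- cfg$methods
    inner_P <- matrix(NA_real_, nrow(x_tr) * cfg$R, M,
                      dimnames = list(NULL, cfg$methods))
    for (mi in seq_len(M)) {
      meth <- reg[[mi]]
      xin <- if (meth$scale) xs_tr else x_tr
      tuned[[mi]] <- tune_inner(xin, y_tr, meth, cfg$grids[[cfg$methods[mi]]],
                                inner_folds, child_seed(seed, 30, l, mi))
      inner_rmse[l, mi] <- tuned[[mi]]$mean_rmse
      ip <- tuned[[mi]]$inner_pred
      inner_P[, mi] <- as.numeric(ip)
      models[[mi]] <- meth$fit(xin, y_tr, tuned[[mi]]$params,
                               child_seed(seed, 40, l, mi))
    }

    stack <- fit_stack(inner_P, rep(y_tr, cfg$R), cfg$K_Ens,
                       child_seed(seed, 60, l))

    bp <- vapply(seq_len(M), function(mi) {
      meth <- reg[[mi]]
      xts <- if (meth$scale) xs_ts else x_all[!tr, , drop = FALSE]
      meth$predict(models[[mi]], xts, tuned[[mi]]$params)
    }, numeric(sum(!tr)))
    bp <- matrix(bp, ncol = M)
    base_pred[!tr, ] <- bp
    pred[!tr] <- stack_predict(stack$coef, bp)

    fold_metrics[[l]] <- compute_metrics(pred[!tr], y[!tr])
    folds_out[[l]] <- list(fold = l, models = models,
                           params = lapply(tuned, `[[`, "params"),
                           stack = stack, center = ctr, scale = scl,
                           tr_idx = which(tr), ts_idx = which(!tr))
  }

  fm <- do.call(rbind, lapply(fold_metrics, function(m)
    data.frame(r2 = m$r2, mae = m$mae, rmse = m$rmse, r = m$r)))
  base_outer <- lapply(seq_len(M), function(mi)
    compute_metrics(base_pred[, mi], y))
  names(base_outer) <- cfg$methods

  structure(list(
    predictions = data.frame(
      subject_id = table$subject_id %||% sprintf("S%03d", seq_len(n)),
      age = y, predicted_age = pred,
      brainage = brain_age_gap(pred, y), outer_fold = outer,
      stringsAsFactors = FALSE),
    metrics = list(pooled = compute_metrics(pred, y),
                   folds = fm,
                   fold_mean = colMeans(fm),
                   fold_sd = apply(fm, 2L, sd)),
    base_outer = base_outer,
    base_outer_pred = base_pred,
    base_inner_rmse = inner_rmse,
    folds = folds_out,
    feature_names = colnames(x_all),
    methods = cfg$methods,
    cfg = cfg), class = "ncv_result")
}

#' @export
print.ncv_result <- function(x, ...) {
  p <- x$metrics$pooled
  cat(sprintf("<ncv_result> n = %d, K_O = %d, methods: %s\n",
              nrow(x$predictions), x$cfg$K_O,
              paste(x$methods, collapse = ", ")))
  cat(sprintf("  pooled R2 = %.3f, MAE = %.2f y, RMSE = %.2f y, r = %.3f\n",
              p$r2, p$mae, p$rmse, p$r))
  cat(sprintf("  per-fold R2 = %.3f (%.3f)\n",
              x$metrics$fold_mean["r2"], x$metrics$fold_sd["r2"]))
  invisible(x)
}

#' Learning curve over sample size
#'
#' Subsamples the cohort without replacement at each requested size, reruns
#' the nested cross-validation, and records the pooled R-squared. Sizes
#' below `2 * K_O` are skipped with a warning.
#'
#' @param table feature table with `age`.
#' @param cfg an [ncv_config()].
#' @param sizes subsample sizes.
#' @param n_seeds number of subsampling repetitions per size.
#' @return data frame with columns `size`, `seed`, `r2`.
#' @export
learning_curve <- function(table, cfg, sizes, n_seeds = 3) {
  n <- nrow(table)
  out <- list()
  for (sz in sizes) {
    if (sz < 2 * cfg$K_O) {
      warning("size ", sz, " below 2 * K_O; skipped")
      next
    }
    stop_if(sz > n, "size exceeds cohort")
    for (s in seq_len(n_seeds)) {
      if (sz == n) {
        idx <- seq_len(n)
      } else {
        set.seed(child_seed(cfg$seed, 70, sz, s))
        idx <- sample(n, sz)
      }
      sub_cfg <- cfg
      sub_cfg$seed <- child_seed(cfg$seed, 71, sz, s)
      if (sz == n) sub_cfg$seed <- cfg$seed
      res <- run_ncv(table[idx, , drop = FALSE], sub_cfg)
      out[[length(out) + 1L]] <- data.frame(size = sz, seed = s,
                                            r2 = res$metrics$pooled$r2)
    }
  }
  do.call(rbind, out)
}
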