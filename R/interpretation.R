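# Interpretation of a fitted nested-cross-validation result: fold-wise
# feature importance normalised to sum 100, partial-dependence curves of
# the stack model, their across-fold consistency, and channel x band
# aggregation of importance.

# permutation importance for models without a native extractor: increase
# in mean squared error on a (deterministic) subsample of the training
# fold when one feature is permuted
permutation_importance <- function(predict_fn, x, y, seed, max_rows = 32L) {
  n <- nrow(x); p <- ncol(x)
  idx <- unique(round(seq(1L, n, length.out = min(max_rows, n))))
  xs <- x[idx, , drop = FALSE]
  ys <- y[idx]
  base <- predict_fn(xs)
  mse0 <- mean((ys - base)^2)
  set.seed(seed)
  perm <- sample(length(idx))
  # one big batched prediction over all single-feature permutations
  big <- xs[rep(seq_along(idx), p), , drop = FALSE]
  for (j in seq_len(p)) {
    rows <- (j - 1L) * length(idx) + seq_along(idx)
    big[rows, j] <- xs[perm, j]
  }
  ph <- predict_fn(big)
  vapply(seq_len(p), function(j) {
    rows <- (j - 1L) * length(idx) + seq_along(idx)
    max(mean((ys - ph[rows])^2) - mse0, 0)
  }, 0)
}

fold_importance <- function(ncv, fold, x_all, y_all) {
  reg <- method_registry()[ncv$methods]
  fnames <- ncv$feature_names
  p <- length(fnames)
  M <- length(reg)
  imp <- matrix(0, p, M)
  for (mi in seq_len(M)) {
    meth <- reg[[mi]]
    model <- fold$models[[mi]]
    params <- fold$params[[mi]]
    raw <- NULL
    if (!is.null(meth$importance)) {
      raw <- meth$importance(model, params)
      if (!is.null(raw) && !is.null(names(raw))) {
        v <- numeric(p); names(v) <- fnames
        common <- intersect(names(raw), fnames)
        v[common] <- raw[common]
        raw <- v
      }
    }
    if (is.null(raw)) {
      xtr <- x_all[fold$tr_idx, , drop = FALSE]
      if (meth$scale) xtr <- scale(xtr, fold$center, fold$scale)
      raw <- permutation_importance(
        function(z) meth$predict(model, z, params),
        xtr, y_all[fold$tr_idx],
        seed = child_seed(ncv$cfg$seed, 80, fold$fold, mi))
    }
    tot <- sum(raw)
    imp[, mi] <- if (tot > 0) raw / tot else rep(1 / p, p)
  }
  w <- abs(fold$stack$coef[-1L])
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / M, M)
  combined <- as.numeric(imp %*% w)
  100 * combined / sum(combined)
}

#' Fold-averaged stack-ensemble feature importance
#'
#' Per outer fold, each base model's importance (elastic-net coefficient
#' magnitudes, tree impurity/gain, permutation importance for the kernel
#' methods) is normalised to sum 1 and the models are combined using the
#' normalised absolute stack weights; the combination is rescaled so the
#' fold's importances sum to exactly 100, then averaged across folds. Each
#' feature is annotated with its marginal Pearson correlation with age.
#'
#' @param ncv an `ncv_result` from [run_ncv()].
#' @param table the feature table the result was fit on.
#' @return an `importance_table` data frame: `feature`, `mean_importance`,
#'   one `fold<l>` column per outer fold, `cor_age`; sorted by decreasing
#'   mean importance.
#' @export
importance <- function(ncv, table) {
  stop_if(!inherits(ncv, "ncv_result"), "ncv must be an ncv_result")
  stop_if(length(ncv$folds) < 1L || is.null(ncv$folds[[1L]]$models),
          "fold models unavailable")
  x_all <- feature_matrix(table)
  stop_if(!identical(colnames(x_all), ncv$feature_names),
          "feature table does not match the fitted result")
  y <- as.numeric(table$age)
  per_fold <- vapply(ncv$folds, fold_importance, numeric(ncol(x_all)),
                     ncv = ncv, x_all = x_all, y_all = y)
  colnames(per_fold) <- paste0("fold", seq_along(ncv$folds))
  out <- data.frame(feature = ncv$feature_names,
                    mean_importance = rowMeans(per_fold),
                    per_fold,
                    cor_age = as.numeric(cor(x_all, y)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

stack_predict_fold <- function(ncv, fold, x) {
  reg <- method_registry()[ncv$methods]
  xs <- scale(x, fold$center, fold$scale)
  bp <- vapply(seq_along(reg), function(mi) {
    meth <- reg[[mi]]
    meth$predict(fold$models[[mi]], if (meth$scale) xs else x,
                 fold$params[[mi]])
  }, numeric(nrow(x)))
  stack_predict(fold$stack$coef, matrix(bp, ncol = length(reg)))
}

#' Partial-dependence curve of the stack model for one feature
#'
#' For each of `grid_size` quantile-spaced values spanning the fold's
#' observed feature range, the feature is set to that value for every
#' training row of the fold and the stack predictions are averaged. One
#' curve per outer fold.
#'
#' @param ncv an `ncv_result`.
#' @param table the feature table the result was fit on.
#' @param feature feature name.
#' @param grid_size number of grid points (default 25).
#' @param folds which outer folds to evaluate (default all).
#' @return data frame with columns `feature`, `fold`, `value`, `yhat`.
#' @export
pdp <- function(ncv, table, feature, grid_size = 25, folds = NULL) {
  x_all <- feature_matrix(table)
  stop_if(!feature %in% colnames(x_all), "unknown feature: ", feature)
  if (is.null(folds)) folds <- seq_along(ncv$folds)
  out <- list()
  for (l in folds) {
    fold <- ncv$folds[[l]]
    xtr <- x_all[fold$tr_idx, , drop = FALSE]
    v <- xtr[, feature]
    stop_if(sd(v) == 0, "constant feature in fold ", l, ": ", feature)
    grid <- unique(quantile(v, probs = seq(0, 1, length.out = grid_size),
                            names = FALSE, type = 7))
    yhat <- vapply(grid, function(g) {
      xg <- xtr
      xg[, feature] <- g
      mean(stack_predict_fold(ncv, fold, xg))
    }, 0)
    out[[length(out) + 1L]] <- data.frame(feature = feature, fold = l,
                                          value = grid, yhat = yhat)
  }
  do.call(rbind, out)
}

#' Across-fold consistency of partial-dependence curves
#'
#' Each fold's curve is interpolated onto a common grid spanning the
#' intersection of the folds' ranges; the statistic is the mean pairwise
#' Pearson correlation between fold curves, in `[-1, 1]`. Pairs involving a
#' flat curve are skipped.
#'
#' @param curves data frame from [pdp()] (one feature, several folds).
#' @param grid_size interpolation grid size.
#' @return scalar mean pairwise correlation.
#' @export
pdp_consistency <- function(curves, grid_size = 25) {
  folds <- unique(curves$fold)
  stop_if(length(folds) < 2L, "need curves from at least two folds")
  lo <- max(tapply(curves$value, curves$fold, min))
  hi <- min(tapply(curves$value, curves$fold, max))
  stop_if(lo >= hi, "fold grids do not overlap")
  g <- seq(lo, hi, length.out = grid_size)
  mat <- vapply(folds, function(l) {
    cc <- curves[curves$fold == l, ]
    approx(cc$value, cc$yhat, xout = g, rule = 2, ties = mean)$y
  }, numeric(grid_size))
  cors <- c()
  for (i in seq_along(folds)[-length(folds)]) {
    for (j in (i + 1L):length(folds)) {
      if (sd(mat[, i]) == 0 || sd(mat[, j]) == 0) next
      cors <- c(cors, cor(mat[, i], mat[, j]))
    }
  }
  if (length(cors) == 0L) return(NA_real_)
  mean(cors)
}

#' Channel-by-band and domain aggregation of feature importance
#'
#' Parses the structured feature names and aggregates mean importance into
#' per-domain channel x band grids (mean importance per cell), plus the
#' percentage share of total importance carried by each feature domain and
#' each frequency band. Unparseable names are excluded with a warning.
#'
#' @param imp an `importance_table` from [importance()].
#' @return list with `grids` (per domain: band x channel matrix of mean
#'   importance), `domain_share` and `band_share` (percent, each summing to
#'   100).
#' @export
spatial_importance <- function(imp) {
  meta <- parse_feature_names(imp$feature)
  bad <- is.na(meta$domain) | is.na(meta$feature) | is.na(meta$band)
  if (any(bad)) {
    warning("excluding ", sum(bad), " unparseable feature name(s)")
    imp <- imp[!bad, , drop = FALSE]
    meta <- meta[!bad, , drop = FALSE]
  }
  v <- imp$mean_importance
  domain_share <- 100 * tapply(v, meta$domain, sum) / sum(v)

  band_rows <- !is.na(meta$band) & meta$band != "broadband"
  band_share <- 100 * tapply(v[band_rows], meta$band[band_rows], sum) /
    sum(v[band_rows])

  grids <- lapply(split(seq_len(nrow(meta)), meta$domain), function(idx) {
    ch <- meta$channel[idx]
    if (all(is.na(ch))) ch <- rep("(all)", length(idx))
    tapply(v[idx], list(band = meta$band[idx], channel = ch), mean)
  })
  list(grids = grids, domain_share = domain_share, band_share = band_share)
}
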