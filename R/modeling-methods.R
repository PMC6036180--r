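# Base-regressor registry for the nested cross-validation ensemble.
#
# Each method supplies: whether it expects standardised features, a default
# hyperparameter grid, a parsimony ordering over that grid (used by the
# one-standard-error rule: simplest settings first), a deterministic fit
# function and a predict function. Linear and tree methods also expose a
# native importance extractor; kernel methods fall back to permutation
# importance in the interpretation module.

rbf_sigma <- function(x) {
  # deterministic median heuristic: median squared distance between up to
  # 100 evenly spaced training rows
  n <- nrow(x)
  idx <- unique(round(seq(1L, n, length.out = min(100L, n))))
  d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

#' Default hyperparameter grids for the base regressors
#'
#' The `fast` grids are deliberately small (mostly single points) for
#' desk-scale cohorts and simulation studies; the full grids cover the
#' conventional ranges for each family. All grids can be overridden via
#' [ncv_config()].
#'
#' @param fast logical; return the reduced grids.
#' @return named list of data-frame grids.
#' @export
default_grids <- function(fast = FALSE) {
  if (fast) {
    list(
      enet = expand.grid(alpha = 0.5, lambda = c(1, 0.1)),
      svr = data.frame(C = 1),
      rf = data.frame(mtry_rule = "sqrt", num_trees = 100),
      xgb = data.frame(max_depth = 3, eta = 0.1, nrounds = 50),
      gpr = data.frame(degree = 1)
    )
  } else {
    list(
      enet = expand.grid(alpha = c(0.1, 0.55, 1),
                         lambda = 10^seq(-2, 1, length.out = 4)),
      svr = data.frame(C = c(0.25, 1, 4)),
      rf = data.frame(mtry_rule = c("sqrt", "third"), num_trees = 300),
      xgb = expand.grid(max_depth = c(2, 4, 6), eta = c(0.05, 0.1, 0.3),
                        nrounds = c(100, 300)),
      gpr = data.frame(degree = c(1, 2, 3))
    )
  }
}

method_registry <- function() {
  list(
    enet = list(
      label = "elastic net",
      scale = TRUE,
      parsimony = function(g) order(-g$lambda, -g$alpha),
      fit = function(x, y, p, seed) {
        glmnet::glmnet(x, y, alpha = p$alpha)
      },
      predict = function(m, x, p) as.numeric(predict(m, x, s = p$lambda)),
      importance = function(m, p) {
        b <- as.numeric(coef(m, s = p$lambda))[-1L]
        abs(b)
      }
    ),
    svr = list(
      label = "support-vector regression (radial)",
      scale = TRUE,
      parsimony = function(g) order(g$C),
      fit = function(x, y, p, seed) {
        set.seed(seed)
        kernlab::ksvm(x, y, type = "eps-svr", kernel = "rbfdot",
                      kpar = list(sigma = rbf_sigma(x)), C = p$C,
                      scaled = FALSE)
      },
      predict = function(m, x, p) as.numeric(kernlab::predict(m, x)),
      importance = NULL
    ),
    rf = list(
      label = "random forest",
      scale = FALSE,
      parsimony = function(g) {
        sz <- ifelse(as.character(g$mtry_rule) == "sqrt", 1L, 2L)
        order(sz, g$num_trees)
      },
      fit = function(x, y, p, seed) {
        mtry <- switch(as.character(p$mtry_rule),
                       sqrt = max(1L, floor(sqrt(ncol(x)))),
                       third = max(1L, floor(ncol(x) / 3)))
        ranger::ranger(x = x, y = y, num.trees = p$num_trees, mtry = mtry,
                       min.node.size = 5, seed = seed, num.threads = 1L,
                       importance = "impurity")
      },
      predict = function(m, x, p) predict(m, data = x, num.threads = 1L)$predictions,
      importance = function(m, p) {
        imp <- m$variable.importance
        pmax(imp, 0)
      }
    ),
    xgb = list(
      label = "gradient-boosted trees",
      scale = FALSE,
      parsimony = function(g) order(g$max_depth, g$nrounds, -g$eta),
      fit = function(x, y, p, seed) {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror",
                        max_depth = p$max_depth, eta = p$eta,
                        tree_method = "hist", max_bin = 64L,
                        nthread = 1L, seed = seed),
          data = dtrain, nrounds = p$nrounds, verbose = 0)
      },
      predict = function(m, x, p) predict(m, xgboost::xgb.DMatrix(data = x)),
      importance = function(m, p) {
        tab <- tryCatch(xgboost::xgb.importance(model = m),
                        error = function(e) NULL)
        if (is.null(tab) || nrow(tab) == 0L) return(NULL)
        structure(tab$Gain, names = tab$Feature)
      }
    ),
    gpr = list(
      label = "Gaussian process regression (polynomial kernel)",
      scale = TRUE,
      parsimony = function(g) order(g$degree),
      fit = function(x, y, p, seed) {
        set.seed(seed)
        kernlab::gausspr(x, y,
                         kernel = "polydot",
                         kpar = list(degree = p$degree, scale = 1 / ncol(x),
                                     offset = 1),
                         var = 0.1, scaled = FALSE)
      },
      predict = function(m, x, p) as.numeric(kernlab::predict(m, x)),
      importance = NULL
    )
  )
}
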