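#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of `y`.
#'
#' @param y Observed response.
#' @param yhat Predictions.
#' @return R-squared.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero variance in y")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Breusch-Pagan test for heteroscedasticity
#'
#' Studentized (Koenker) form: regress the squared residuals on the model
#' covariates and report `LM = n * R2_aux` against a chi-square with
#' `rank(X) - 1` degrees of freedom.
#'
#' @param residuals OLS residuals.
#' @param X Design matrix including the intercept column.
#' @return List with `statistic` and `p_value`.
#' @export
breusch_pagan <- function(residuals, X) {
  stopifnot(length(residuals) == nrow(X))
  u <- residuals^2
  if (var(u) == 0) return(list(statistic = 0, p_value = 1))
  aux <- stats::lm.fit(X, u)
  r2_aux <- 1 - sum(aux$residuals^2) / sum((u - mean(u))^2)
  stat <- length(u) * r2_aux
  df <- aux$rank - 1L
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Fit the OLS risk-adjustment model
#'
#' Ordinary least squares of log10 PMPM on the one-hot covariates. Exactly
#' collinear columns (beyond the dropped reference levels) are removed via the
#' pivoted QR solve and reported; approximate collinearity is deliberately
#' retained. Diagnostics include R-squared, the overall F-test and the
#' Breusch-Pagan heteroscedasticity test.
#'
#' @param design A [build_design_matrix()] object.
#' @return Object of class `"linear_fit"`: `beta` (named coefficients),
#'   `fitted`, `residuals`, `r_squared`, `f_statistic`, `f_test_p`,
#'   `bp_statistic`, `bp_p`, `n`, `rank`, `dropped`, `member_id`, `year`.
#' @export
fit_linear <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X; y <- design$y
  if (nrow(X) <= ncol(X)) stop("need more rows than columns for OLS")
  fit <- stats::lm.fit(X, y)
  dropped <- character(0)
  if (fit$rank < ncol(X)) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    warning("rank-deficient design; dropping exactly collinear columns: ",
            paste(bad, collapse = ", "))
    dropped <- bad
    X <- X[, !is.na(fit$coefficients), drop = FALSE]
    fit <- stats::lm.fit(X, y)
  }
  fitted <- as.numeric(X %*% fit$coefficients)
  res <- y - fitted
  # constant response: define R^2 = 0 (the model explains nothing)
  r2 <- if (var(y) == 0) 0 else r_squared(y, fitted)
  n <- length(y); p <- fit$rank
  f_stat <- if (r2 < 1) (r2 / (p - 1)) / ((1 - r2) / (n - p)) else Inf
  f_p <- pf(f_stat, p - 1, n - p, lower.tail = FALSE)
  bp <- breusch_pagan(res, X)
  structure(list(beta = fit$coefficients, fitted = fitted, residuals = res,
                 r_squared = r2, f_statistic = f_stat, f_test_p = f_p,
                 bp_statistic = bp$statistic, bp_p = bp$p_value,
                 n = n, rank = p, dropped = dropped,
                 member_id = design$member_id, year = design$year),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("OLS risk-adjustment fit: n =", x$n, ", p =", x$rank, "\n")
  cat(sprintf("  R-squared %.4f, F-test p %.3g, Breusch-Pagan p %.3g\n",
              x$r_squared, x$f_test_p, x$bp_p))
  invisible(x)
}

#' Gradient-boosted model hyperparameters
#'
#' Defaults follow a regularized squared-error boosted-tree setup: 1000 trees,
#' a conservative learning rate, and a cross-validated grid over maximum tree
#' depth and minimum leaf sample weight.
#'
#' @param nrounds Number of boosting rounds (trees).
#' @param eta Learning rate.
#' @param gamma Leaf-count penalty.
#' @param lambda L2 penalty on leaf weights.
#' @param depth_grid,min_child_grid Cross-validation grids for `max_depth`
#'   and `min_child_weight`.
#' @param nfold Cross-validation folds.
#' @param train_fraction Fraction of rows used for training; the rest is the
#'   held-out test split.
#' @return List of class `"gbm_params"`.
#' @export
gbm_params <- function(nrounds = 1000, eta = 0.05, gamma = 0, lambda = 1,
                       depth_grid = c(3, 5, 7),
                       min_child_grid = c(10, 50, 200),
                       nfold = 5, train_fraction = 0.6) {
  structure(list(nrounds = nrounds, eta = eta, gamma = gamma, lambda = lambda,
                 depth_grid = depth_grid, min_child_grid = min_child_grid,
                 nfold = nfold, train_fraction = train_fraction),
            class = "gbm_params")
}

#' Fit the gradient-boosted tree risk-adjustment model
#'
#' Trains a regularized additive tree ensemble on log10 PMPM with squared
#' error loss. The rows are split 60/40 into train/test by `split_seed`;
#' `max_depth` and `min_child_weight` are selected on the training split by
#' k-fold cross-validation minimizing mean squared error; the final ensemble
#' is trained on the training split and scored on train, test and all rows.
#' Residuals are computed for every row (the test-split residuals are honest
#' out-of-sample residuals; the overall R-squared scores the train-split
#' model on all rows).
#'
#' @param design A [build_design_matrix()] object.
#' @param params A [gbm_params()] object.
#' @param split_seed Integer seed controlling the split, the CV folds and the
#'   tree construction; the fit is deterministic given the seed.
#' @return Object of class `"gbm_fit"`: `residuals` (all rows, `y - yhat`),
#'   `fitted`, `r_squared_train`, `r_squared_test`, `r_squared_overall`,
#'   `best_params`, `cv_results`, `train_idx`, `model`, `member_id`, `year`.
#' @export
fit_gbm <- function(design, params = gbm_params(), split_seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X[, colnames(design$X) != "intercept", drop = FALSE]
  y <- design$y
  n <- length(y)
  if (n < 5 * params$nfold) stop("too few rows for the train/test split and CV folds")
  if (!all(is.finite(y))) stop("non-finite response")

  set.seed(split_seed)
  train_idx <- sort(sample.int(n, size = round(params$train_fraction * n)))
  dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                 label = y[train_idx], nthread = 1)

  grid <- expand.grid(max_depth = params$depth_grid,
                      min_child_weight = params$min_child_grid)
  cv_mse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    set.seed(split_seed + g)
    cv <- xgboost::xgb.cv(
      params = list(objective = "reg:squarederror", eta = params$eta,
                    gamma = params$gamma, lambda = params$lambda,
                    max_depth = grid$max_depth[g],
                    min_child_weight = grid$min_child_weight[g],
                    nthread = 1, tree_method = "hist"),
      data = dtrain, nrounds = params$nrounds, nfold = params$nfold,
      verbose = 0)
    cv_mse[g] <- tail(cv$evaluation_log$test_rmse_mean, 1)^2
  }
  best <- which.min(cv_mse)

  set.seed(split_seed)
  model <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  gamma = params$gamma, lambda = params$lambda,
                  max_depth = grid$max_depth[best],
                  min_child_weight = grid$min_child_weight[best],
                  nthread = 1, tree_method = "hist"),
    data = dtrain, nrounds = params$nrounds, verbose = 0)

  yhat <- predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
  test_idx <- setdiff(seq_len(n), train_idx)
  structure(list(
    residuals = y - yhat, fitted = yhat,
    r_squared_train = r_squared(y[train_idx], yhat[train_idx]),
    r_squared_test = r_squared(y[test_idx], yhat[test_idx]),
    r_squared_overall = r_squared(y, yhat),
    best_params = as.list(grid[best, ]),
    cv_results = cbind(grid, cv_mse = cv_mse),
    train_idx = train_idx, model = model,
    member_id = design$member_id, year = design$year),
    class = "gbm_fit")
}

#' @export
print.gbm_fit <- function(x, ...) {
  cat("Gradient-boosted risk-adjustment fit\n")
  cat(sprintf("  selected max_depth %d, min_child_weight %d\n",
              x$best_params$max_depth, x$best_params$min_child_weight))
  cat(sprintf("  R-squared: train %.4f, test %.4f, overall %.4f\n",
              x$r_squared_train, x$r_squared_test, x$r_squared_overall))
  invisible(x)
}

#' Normal Q-Q data for residuals
#'
#' Standardizes the residuals (mean 0, SD 1), sorts them, and pairs each
#' order statistic with the theoretical normal quantile at plotting position
#' `(i - 0.5) / n`. The centering and scaling constants are kept as
#' attributes so thresholds detected on the standardized scale can be mapped
#' back to raw residuals.
#'
#' @param residuals Numeric vector, length >= 10.
#' @return Tibble with `theoretical` and `observed` (standardized, sorted),
#'   with attributes `center`, `scale`, `n`.
#' @export
qq_data <- function(residuals) {
  n <- length(residuals)
  if (n < 10) stop("need at least 10 residuals")
  s <- sd(residuals)
  if (s == 0) stop("zero residual variance")
  m <- mean(residuals)
  out <- tibble(theoretical = qnorm((seq_len(n) - 0.5) / n),
                observed = sort((residuals - m) / s))
  attr(out, "center") <- m
  attr(out, "scale") <- s
  attr(out, "n") <- n
  out
}
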