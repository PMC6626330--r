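test_that("OLS recovers exact linear structure and handles a constant response", {
  set.seed(4)
  X <- cbind(intercept = 1, a = rnorm(40), b = rbinom(40, 1, 0.5))
  y <- as.numeric(X %*% c(1, 2, -0.5))
  fit <- fit_linear(raw_design(y, X))
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$r_squared, 1)

  yc <- rep(2, 40)
  fitc <- fit_linear(raw_design(yc, X))
  expect_equal(fitc$r_squared, 0)
  expect_equal(unname(fitc$beta[c("a", "b")]), c(0, 0), tolerance = 1e-12)
})

test_that("OLS coefficients match the normal-equations oracle", {
  X <- cbind(intercept = 1,
             x1 = c(0.2, 1.4, -0.7, 2.2, 0.9, -1.1),
             x2 = c(1, 0, 1, 0, 1, 1))
  y <- c(1.0, 2.5, -0.3, 4.1, 1.7, 0.2)
  fit <- fit_linear(raw_design(y, X))
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$beta), as.numeric(oracle), tolerance = 1e-10)
  expect_lt(abs(mean(fit$residuals)), 1e-10)
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8)
})

test_that("r_squared equals the two-pass formula", {
  y <- c(2.0, 3.5, 1.1, 4.2, 2.8)
  yhat <- c(2.2, 3.1, 1.5, 4.0, 2.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  oracle <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(r_squared(y, yhat), oracle, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), yhat), "zero variance")
})

test_that("Breusch-Pagan agrees with the studentized reference implementation", {
  skip_if_not_installed("lmtest")
  set.seed(8)
  n <- 300
  x <- runif(n)
  y <- 1 + 2 * x + rnorm(n, sd = 0.5 + x)
  X <- cbind(intercept = 1, x = x)
  fit <- fit_linear(raw_design(y, X))
  bp <- breusch_pagan(fit$residuals, X)
  ref <- lmtest::bptest(lm(y ~ x))
  expect_equal(bp$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(bp$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(breusch_pagan(rep(0.3, n), X)$statistic, 0)
})

test_that("Breusch-Pagan keeps its nominal size and detects real heteroscedasticity", {
  set.seed(15)
  n <- 200
  rej <- replicate(1000, {
    X <- cbind(intercept = 1, x1 = rnorm(n), x2 = runif(n))
    y <- as.numeric(X %*% c(1, 0.5, -0.5)) + rnorm(n)
    fit <- fit_linear(raw_design(y, X))
    breusch_pagan(fit$residuals, X)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)

  set.seed(16)
  pow <- replicate(200, {
    x <- runif(5000, 0.5, 1.5)
    y <- 1 + x + rnorm(5000, sd = x)
    X <- cbind(intercept = 1, x = x)
    fit <- fit_linear(raw_design(y, X))
    breusch_pagan(fit$residuals, X)$p_value < 0.05
  })
  expect_gte(mean(pow), 0.95)
})

test_that("Q-Q data standardizes, sorts and tracks theoretical quantiles", {
  n <- 10000
  q <- qnorm((seq_len(n) - 0.5) / n)
  qq <- qq_data(5 + 2 * q)
  expect_identical(nrow(qq), as.integer(n))
  # the only discrepancy is the O(1/n) bias of the sample SD of the
  # plotting-position quantiles, so agreement is tight but not exact
  expect_lt(max(abs(qq$observed - qq$theoretical)), 2e-3)
  expect_error(qq_data(rep(1, 20)), "zero residual variance")
  expect_error(qq_data(rnorm(5)), "at least 10")

  # max |observed - theoretical| for a true normal sample stays below the
  # 99.9% Monte-Carlo band (1.02, estimated from 300 replicates at n = 1e5)
  set.seed(21)
  qq2 <- qq_data(rnorm(100000))
  expect_lt(max(abs(qq2$observed - qq2$theoretical)), 1.05)
})

test_that("GBM fits are deterministic given the seed", {
  set.seed(31)
  n <- 600
  X <- cbind(intercept = 1, a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3),
             z = rnorm(n))
  y <- 0.5 * X[, "a"] + 0.3 * X[, "z"] + rnorm(n, sd = 0.4)
  d <- raw_design(y, X)
  p <- gbm_params(nrounds = 60, depth_grid = 3, min_child_grid = 20)
  g1 <- fit_gbm(d, p, split_seed = 5)
  g2 <- fit_gbm(d, p, split_seed = 5)
  expect_identical(g1$residuals, g2$residuals)
  expect_identical(g1$best_params, g2$best_params)
})

test_that("GBM captures planted interactions that OLS cannot", {
  set.seed(32)
  n <- 4000
  a <- rbinom(n, 1, 0.4); b <- rbinom(n, 1, 0.4)
  y <- 0.2 * a + 0.2 * b + 0.6 * a * b + rnorm(n, sd = 0.3)
  d <- raw_design(y, cbind(intercept = 1, a = a, b = b))
  lin <- fit_linear(d)
  g <- fit_gbm(d, gbm_params(nrounds = 300, depth_grid = c(2, 3),
                             min_child_grid = c(10, 50)), split_seed = 9)
  expect_gt(g$r_squared_overall, lin$r_squared)
})

test_that("linear and GBM residuals stay highly correlated under modest interactions", {
  cfg <- generator_config(n_members = 6000, years = 2011, seed = 35,
                          interactions = list(list(a = "MEN", b = "SUD",
                                                   beta = 0.15)))
  sim <- simulate_claims(cfg)
  f <- fit_year(sim, 2011)
  g <- fit_gbm(f$design, gbm_params(nrounds = 300, depth_grid = c(3, 5),
                                    min_child_grid = c(50, 200)),
               split_seed = 3)
  expect_gt(cor(f$fit$residuals, g$residuals), 0.8)
})

test_that("GBM does not leak fit into the held-out split under pure noise", {
  set.seed(33)
  n <- 20000
  X <- cbind(intercept = 1,
             matrix(rbinom(n * 5, 1, 0.3), n,
                    dimnames = list(NULL, paste0("c", 1:5))))
  y <- rnorm(n)
  g <- fit_gbm(raw_design(y, X),
               gbm_params(nrounds = 300, depth_grid = 3, min_child_grid = 50),
               split_seed = 12)
  expect_lte(g$r_squared_test, 0.05)
})

test_that("OLS residuals are orthogonal to the design", {
  fy <- cached_fit("small2_2011",
                   cached_sim("small2", generator_config(n_members = 2000,
                                                         years = 2011:2012,
                                                         seed = 23)), 2011)
  Xs <- scale(fy$design$X[, -1])
  expect_lt(max(abs(t(Xs) %*% fy$fit$residuals)) / nrow(Xs), 1e-8)
})
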