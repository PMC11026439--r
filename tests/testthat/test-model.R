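test_that("posterior means agree with the closed-form OLS oracle under flat priors", {
  set.seed(99)
  n <- 100
  X <- scale(matrix(rnorm(3 * n), n, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  y <- -0.3 * X[, 1] + 0.1 * X[, 2] + 0.2 * X[, 3] + rnorm(n, 0, 0.05)
  ds <- mk_dataset(y, X)
  fit <- fit_period_model(ds, fast_mcmc(seed = 3),
                          prior_scale_multiplier = 100)
  # independent oracle: normal-equation least squares
  Z <- cbind(1, X)
  beta_ols <- solve(crossprod(Z), crossprod(Z, y))
  expect_equal(unname(colMeans(fit$draws[, 1:4])), drop(beta_ols),
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("parameters are recovered at low noise", {
  set.seed(12)
  n <- 200
  X <- scale(matrix(rnorm(3 * n), n, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  truth <- c(0, -0.3, 0.1, 0.2)
  y <- drop(cbind(1, X) %*% truth) + rnorm(n, 0, 0.05)
  fit <- fit_period_model(mk_dataset(y, X), fast_mcmc(seed = 4))
  med <- apply(fit$draws[, 1:4], 2, median)
  expect_true(all(abs(med - truth) < 0.05))
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(fit$rhat < 1.05))
})

test_that("a degenerate response is an error; small datasets are refused", {
  X <- scale(matrix(rnorm(60), 20, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  expect_error(fit_period_model(mk_dataset(rep(0.1, 20), X), fast_mcmc()),
               "degenerate response")
  expect_error(fit_period_model(mk_dataset(rnorm(10), X[1:10, ]),
                                fast_mcmc()), "need >= 15")
})

test_that("rescaling the response rescales (a, sigma) and preserves slope ratios", {
  set.seed(8)
  n <- 30
  X <- scale(matrix(rnorm(3 * n), n, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  y <- -0.2 * X[, 1] + rnorm(n, 0, 0.1)
  f1 <- fit_period_model(mk_dataset(y, X), fast_mcmc(seed = 5))
  f2 <- fit_period_model(mk_dataset(2 * y, X), fast_mcmc(seed = 5))
  # the model is scale-equivariant and the sampler couples draw-for-draw
  expect_equal(f2$draws[, c("a", "b", "c", "d", "sigma")],
               2 * f1$draws[, c("a", "b", "c", "d", "sigma")],
               tolerance = 1e-8)
})

test_that("retained draw count follows the chains/warmup/thin accounting", {
  expect_equal(mcmc_config()$retained_per_chain, 500)
  expect_error(mcmc_config(n_iterations = 1000, thin = 10), ">= 100")
  set.seed(14)
  X <- scale(matrix(rnorm(60), 20, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  y <- rnorm(20, 0, 0.1)
  fit <- fit_period_model(mk_dataset(y, X), reduced_mcmc(seed = 2))
  expect_equal(nrow(fit$draws), 4 * 100)
  expect_equal(tabulate(fit$chain), rep(100L, 4))
})

test_that("identical seeds give identical fits", {
  set.seed(40)
  X <- scale(matrix(rnorm(60), 20, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  y <- -0.1 * X[, 1] + rnorm(20, 0, 0.1)
  f1 <- fit_period_model(mk_dataset(y, X), fast_mcmc(seed = 6))
  f2 <- fit_period_model(mk_dataset(y, X), fast_mcmc(seed = 6))
  expect_identical(f1$draws, f2$draws)
})

test_that("split R-hat is near 1 for iid chains and large for divergent ones", {
  set.seed(33)
  chains <- lapply(1:4, function(i) matrix(rnorm(1000), ncol = 1,
                                           dimnames = list(NULL, "b")))
  r <- compute_rhat(chains)
  expect_gte(r, 0.99)
  expect_lte(r, 1.01)

  # independent implementation of the same split formula
  split_rhat_oracle <- function(chs) {
    halves <- list()
    half <- nrow(chs[[1]]) %/% 2
    for (ch in chs) {
      halves <- c(halves, list(ch[1:half, 1], ch[(half + 1):(2 * half), 1]))
    }
    W <- mean(sapply(halves, var))
    B <- half * var(sapply(halves, mean))
    sqrt(((half - 1) / half * W + B / half) / W)
  }
  expect_equal(unname(r), split_rhat_oracle(chains), tolerance = 1e-12)

  # constant chains at different levels: within variance 0, R-hat infinite
  c0 <- matrix(0, 100, 1); c1 <- matrix(1, 100, 1)
  expect_identical(unname(compute_rhat(list(c0, c1))), Inf)
  # fully identical constants: undefined, reported NaN
  expect_true(is.nan(compute_rhat(list(c0, c0))))
  # offset but non-constant chains mix badly
  off <- lapply(1:4, function(i) matrix(rnorm(1000, mean = 3 * i, sd = 0.1),
                                        ncol = 1))
  expect_gt(compute_rhat(off), 1.1)
})

test_that("compute_rhat validates its inputs", {
  expect_error(compute_rhat(list(matrix(rnorm(10)))), "at least 2")
  expect_error(compute_rhat(list(matrix(rnorm(10)), matrix(rnorm(8)))),
               "equal lengths")
})

test_that("bayesian R2 follows its defining arithmetic", {
  n <- 50
  set.seed(21)
  X <- scale(matrix(rnorm(3 * n), n, 3))
  colnames(X) <- c("zF", "zST", "zRec")
  ds <- mk_dataset(rnorm(n), X)
  # single draw (a=0, b=1, c=d=0, sigma=1): V = var(zF) = 1 so R2 = 0.5
  dr <- matrix(c(0, 1, 0, 0, 1), 1, dimnames = list(NULL,
               c("a", "b", "c", "d", "sigma")))
  fit <- mk_fit(dr)
  fit$n_obs <- n
  expect_equal(bayes_r2(fit, ds), 0.5, tolerance = 1e-12)
  # intercept-only draws: predictor variance 0 so R2 = 0
  dr0 <- matrix(c(0.3, 0, 0, 0, 1), 1, dimnames = list(NULL,
                c("a", "b", "c", "d", "sigma")))
  fit0 <- mk_fit(dr0); fit0$n_obs <- n
  expect_equal(bayes_r2(fit0, ds), 0)
  # sigma -> 0 with a nonconstant predictor: R2 -> 1
  dr1 <- matrix(c(0, 1, 0, 0, 1e-9), 1, dimnames = list(NULL,
                c("a", "b", "c", "d", "sigma")))
  fit1 <- mk_fit(dr1); fit1$n_obs <- n
  expect_gt(bayes_r2(fit1, ds), 1 - 1e-12)
})

test_that("the retention filter applies both R2 and convergence rules", {
  dr <- matrix(rnorm(500), 100, 5,
               dimnames = list(NULL, c("a", "b", "c", "d", "sigma")))
  ok <- function(r2) mk_fit(dr, r2 = r2)
  bad_rhat <- mk_fit(dr, r2 = 0.5,
                     rhat = c(a = 1, b = 1.05, c = 1, d = 1, sigma = 1))
  fits <- list(
    keep = list(before = ok(0.25), after = ok(0.21)),
    drop_r2 = list(before = ok(0.25), after = ok(0.19)),
    drop_conv = list(before = ok(0.5), after = bad_rhat))
  out <- filter_stocks(fits)
  expect_identical(out$retained, "keep")
  expect_match(out$log$reasons[out$log$stock_id == "drop_r2"], "R2_AFTER")
  expect_match(out$log$reasons[out$log$stock_id == "drop_conv"], "CONVERGENCE")
  expect_error(filter_stocks(list(x = list(before = ok(0.5)))),
               "missing a period fit")
})
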