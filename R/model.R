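#' MCMC sampling configuration
#'
#' Defaults mirror the reference analysis protocol: four chains of 10,000
#' iterations, the first half discarded as warmup, thinning by 10 (so 500
#' retained draws per chain, 2,000 total). `target_accept` is recorded for
#' interface fidelity with HMC backends; the default Gibbs backend draws
#' from exact conditionals and does not use it.
#'
#' @param n_chains Number of chains (>= 2 for the convergence diagnostic).
#' @param n_iterations Iterations per chain.
#' @param warmup_frac Fraction of each chain discarded as warmup.
#' @param thin Thinning factor (>= 1).
#' @param target_accept Target average acceptance probability (HMC notion).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iterations = 10000L,
                        warmup_frac = 0.5, thin = 10L,
                        target_accept = 0.995, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iterations <- as.integer(n_iterations)
  thin <- as.integer(thin)
  if (thin < 1L) stop("thin must be >= 1")
  retained <- floor(n_iterations * (1 - warmup_frac) / thin)
  if (retained < 100L)
    stop("configuration retains ", retained,
         " draws per chain; need >= 100")
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 warmup_frac = warmup_frac, thin = thin,
                 target_accept = target_accept, seed = as.integer(seed),
                 retained_per_chain = retained),
            class = "mcmc_config")
}

# slice sampler (Neal 2003, stepping out) on a log-density; returns new point
slice_sample1 <- function(x0, logf, w = 0.5, m = 50L) {
  fx0 <- logf(x0)
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1, 0, w)
  L <- x0 - u
  R <- L + w
  j <- floor(stats::runif(1) * m)
  k <- (m - 1) - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Fit the per-period Bayesian linear regression
#'
#' Samples the posterior of the Gaussian linear model
#' \eqn{y \sim N(a + X\beta, \sigma)} under weakly informative priors on the
#' scale of the data (the convention of applied-regression defaults):
#' intercept \eqn{a \sim N(\bar y,\; 2.5\,s_y)}, each slope
#' \eqn{\beta_j \sim N(0,\; 2.5\, s_y / s_{x_j})} (with \eqn{s_{x_j} = 1}
#' after z-scoring), and \eqn{\sigma \sim} Exponential(rate \eqn{1/s_y}).
#' The default backend is a Gibbs sampler: the coefficient vector is drawn
#' from its exact multivariate-normal conditional and \eqn{\log\sigma} by
#' slice sampling, so every draw targets the stated posterior exactly.
#' Deterministic under `config$seed`.
#'
#' @param dataset A `model_dataset` with at least 15 rows.
#' @param config An [mcmc_config()].
#' @param prior_scale_multiplier Multiplies all prior standard deviations
#'   (and the sigma-prior mean); large values give effectively flat priors
#'   for oracle comparisons.
#' @param min_obs Minimum rows accepted (default 15, the design minimum of
#'   the study windows).
#' @return An object of class `posterior_fit`: list with `draws` (matrix,
#'   columns `a`, `b`, `c`, `d`, `sigma`; `b` = fishing, `c` = temperature,
#'   `d` = recruitment), `chain` (chain index per row), `rhat` (named,
#'   per parameter), `r2_median`, `n_obs`, `period`, `stock_id`, `prior`.
#' @export
fit_period_model <- function(dataset, config = mcmc_config(),
                             prior_scale_multiplier = 1, min_obs = 15L) {
  stopifnot(inherits(dataset, "model_dataset"), inherits(config, "mcmc_config"))
  y <- dataset$y
  X <- dataset$X
  n <- length(y)
  if (n < min_obs) stop("dataset has ", n, " rows; need >= ", min_obs)
  s_y <- stats::sd(y)
  if (s_y == 0) stop("degenerate response: sd(y) = 0")

  p <- ncol(X) + 1L
  Z <- cbind(1, X)
  mult <- prior_scale_multiplier
  prior_mean <- c(mean(y), rep(0, ncol(X)))
  prior_sd <- c(2.5 * s_y, 2.5 * s_y / apply(X, 2, stats::sd)) * mult
  lambda <- 1 / (s_y * mult)   # exponential rate for sigma

  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  Dinv <- diag(1 / prior_sd^2, p)
  Dinv_m <- Dinv %*% prior_mean

  keep_iters <- seq.int(floor(config$n_iterations * config$warmup_frac) +
                          config$thin,
                        config$n_iterations, by = config$thin)
  S <- length(keep_iters)
  draws <- matrix(NA_real_, S * config$n_chains, p + 1L)
  chain_id <- integer(S * config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    sigma <- s_y
    u <- log(sigma)
    row0 <- (ch - 1L) * S
    k <- 0L
    keep_ptr <- 1L
    for (it in seq_len(config$n_iterations)) {
      # gamma | sigma: exact MVN conditional
      A <- ZtZ / sigma^2 + Dinv
      b <- Zty / sigma^2 + Dinv_m
      U <- chol(A)
      mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
      gamma <- mu + backsolve(U, stats::rnorm(p))
      ssr <- sum((y - Z %*% gamma)^2)
      # log sigma | gamma: slice sample; log-density includes the Jacobian
      logf <- function(uu) -(n - 1) * uu - ssr * exp(-2 * uu) / 2 -
        lambda * exp(uu)
      u <- slice_sample1(u, logf)
      sigma <- exp(u)
      if (keep_ptr <= S && it == keep_iters[keep_ptr]) {
        k <- k + 1L
        draws[row0 + k, ] <- c(gamma, sigma)
        keep_ptr <- keep_ptr + 1L
      }
    }
    chain_id[row0 + seq_len(S)] <- ch
  }
  colnames(draws) <- c("a", "b", "c", "d", "sigma")[seq_len(p + 1L)]

  by_chain <- lapply(seq_len(config$n_chains),
                     function(ch) draws[chain_id == ch, , drop = FALSE])
  rhat <- compute_rhat(by_chain)
  fit <- structure(list(draws = draws, chain = chain_id, rhat = rhat,
                        n_obs = n, period = dataset$period,
                        stock_id = dataset$stock_id,
                        prior = list(mean = prior_mean, sd = prior_sd,
                                     sigma_rate = lambda),
                        config = config),
                   class = "posterior_fit")
  fit$r2_median <- bayes_r2(fit, dataset)
  fit
}

#' @export
print.posterior_fit <- function(x, ...) {
  med <- apply(x$draws, 2, stats::median)
  cat(sprintf("<posterior_fit> %s/%s: n=%d, %d draws\n",
              x$stock_id, x$period, x$n_obs, nrow(x$draws)))
  cat("  medians:", paste(sprintf("%s=%.3f", names(med), med), collapse = " "),
      "\n")
  cat(sprintf("  max Rhat %.4f, median R2 %.3f\n", max(x$rhat), x$r2_median))
  invisible(x)
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Each chain is halved; with W the mean within-half variance and B the
#' between-half variance of the half means times the draws per half,
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with n the draws per
#' half. Chains that have not mixed give values above 1; i.i.d.-like draws
#' give values near 1. W = 0 with between-half spread yields `Inf`
#' (reported, not an error); fully constant identical chains give `NaN`.
#'
#' @param chains List (length >= 2) of equal-size draw matrices (iterations
#'   x parameters) or numeric vectors.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
compute_rhat <- function(chains) {
  if (length(chains) < 2L) stop("need at least 2 chains")
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1, dimnames = list(NULL, "par"))
    else ch
  })
  lens <- vapply(chains, nrow, 0L)
  if (length(unique(lens)) != 1L) stop("chains must have equal lengths")
  if (lens[1] < 4L) stop("chains too short to split")
  half <- lens[1] %/% 2L
  p <- ncol(chains[[1]])
  out <- vapply(seq_len(p), function(j) {
    halves <- unlist(lapply(chains, function(ch) {
      v <- ch[seq_len(2L * half), j]
      list(v[seq_len(half)], v[half + seq_len(half)])
    }), recursive = FALSE)
    W <- mean(vapply(halves, stats::var, 0))
    mns <- vapply(halves, mean, 0)
    B <- half * stats::var(mns)
    var_plus <- (half - 1) / half * W + B / half
    if (W == 0) {
      if (B == 0) NaN else Inf
    } else sqrt(var_plus / W)
  }, 0)
  names(out) <- colnames(chains[[1]])
  out
}

#' Bayesian R-squared (median over draws)
#'
#' Per posterior draw s, \eqn{R^2_s = V_s / (V_s + \sigma_s^2)} where
#' \eqn{V_s} is the sample variance over rows of the linear predictor
#' \eqn{a_s + X\beta_s}. Returns the median over draws.
#'
#' @param fit A `posterior_fit`.
#' @param dataset The `model_dataset` the fit was computed on.
#' @return Median Bayesian R-squared (scalar in `[0, 1]`).
#' @export
bayes_r2 <- function(fit, dataset) {
  stopifnot(inherits(fit, "posterior_fit"), inherits(dataset, "model_dataset"))
  Z <- cbind(1, dataset$X)
  coef_cols <- seq_len(ncol(Z))
  if (nrow(dataset$X) != fit$n_obs) stop("fit and dataset dimensions disagree")
  lp <- Z %*% t(fit$draws[, coef_cols, drop = FALSE])   # n x S
  n <- nrow(lp)
  v <- colSums(lp^2) / (n - 1) - colSums(lp)^2 / (n * (n - 1))
  v <- pmax(v, 0)
  sig2 <- fit$draws[, "sigma"]^2
  stats::median(v / (v + sig2))
}

#' Retention filter on fitted stocks
#'
#' A stock is retained when both period models have median Bayesian
#' R-squared at or above `r2_threshold` and every parameter's R-hat at or
#' below `rhat_threshold` in both fits. Exclusion reasons are named
#' `R2_BEFORE`, `R2_AFTER` and `CONVERGENCE`.
#'
#' @param fits Named list: per stock, a list with elements `before` and
#'   `after`, each a `posterior_fit`.
#' @param r2_threshold Median-R2 retention threshold (default 0.2).
#' @param rhat_threshold Convergence threshold (default 1.01).
#' @return List with `retained` (character vector of stock ids) and `log`
#'   (data frame: stock_id, retained, reasons).
#' @export
filter_stocks <- function(fits, r2_threshold = 0.2, rhat_threshold = 1.01) {
  rows <- lapply(names(fits), function(id) {
    pr <- fits[[id]]
    if (is.null(pr$before) || is.null(pr$after))
      stop("stock ", id, " is missing a period fit")
    reasons <- character(0)
    if (!all(is.finite(pr$before$rhat)) ||
        any(pr$before$rhat > rhat_threshold) ||
        !all(is.finite(pr$after$rhat)) ||
        any(pr$after$rhat > rhat_threshold))
      reasons <- c(reasons, "CONVERGENCE")
    if (pr$before$r2_median < r2_threshold) reasons <- c(reasons, "R2_BEFORE")
    if (pr$after$r2_median < r2_threshold) reasons <- c(reasons, "R2_AFTER")
    data.frame(stock_id = id, retained = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, rows)
  list(retained = log$stock_id[log$retained], log = log)
}
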