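# fixture builders shared across test files

# stock with arbitrary covariates; biomass supplied explicitly
mk_series <- function(biomass, years = seq_along(biomass) + 1969L,
                      f = NULL, rec = NULL, sst = NULL, stock_id = "fix") {
  n <- length(biomass)
  stock_series(stock_id, data.frame(
    year = years,
    biomass_mt = biomass,
    f_per_yr = if (is.null(f)) seq(0.1, 0.6, length.out = n) else f,
    recruitment_n = if (is.null(rec)) 1e6 * exp(sin(seq_len(n))) else rec,
    sst_c = if (is.null(sst)) 10 + cos(seq_len(n)) else sst),
    habitat = "demersal",
    life_history = list(K = 0.3, common_length = 60, longevity = 15))
}

# the canonical qualifying V: decline 100 -> 5 over years 1..21, recovery
# 5 -> 60 over years 21..41
mk_qualifying_v <- function() {
  bm <- c(seq(100, 5, length.out = 21), seq(5, 60, length.out = 21)[-1])
  mk_series(bm, stock_id = "v41")
}

# minimal model_dataset around given y and X
mk_dataset <- function(y, X, period = "before", stock_id = "T") {
  structure(list(period = period, stock_id = stock_id,
                 years = seq_along(y), y = y, X = X,
                 raw_stats = data.frame()),
            class = "model_dataset")
}

# minimal posterior_fit wrapper around a draw matrix
mk_fit <- function(draws, stock_id = "T", period = "before",
                   rhat = NULL, r2 = NA_real_) {
  if (is.null(rhat)) rhat <- stats::setNames(rep(1, ncol(draws)),
                                             colnames(draws))
  structure(list(draws = draws, chain = rep(1L, nrow(draws)), rhat = rhat,
                 r2_median = r2, n_obs = NA_integer_, period = period,
                 stock_id = stock_id),
            class = "posterior_fit")
}

# fast MCMC profile for unit tests (Gibbs draws are nearly independent, so
# thinning is unnecessary there)
fast_mcmc <- function(seed = 1L) {
  mcmc_config(n_chains = 4L, n_iterations = 400L, warmup_frac = 0.5,
              thin = 1L, seed = seed)
}

# reduced profile stated for the larger experiments
reduced_mcmc <- function(seed = 1L) {
  mcmc_config(n_chains = 4L, n_iterations = 2000L, warmup_frac = 0.5,
              thin = 10L, seed = seed)
}

# simulate one stock with given slopes/sigma on the default 41-year scenario
mk_sim_stock <- function(seed, b = c(-0.3, -0.1), c_ = c(0.1, 0.05),
                         d = c(0.2, 0.15), sigma = 0.1,
                         a = c(-0.115, 0.11), stock_id = "sim") {
  pset <- driver_params_set(
    driver_params(a[1], b[1], c_[1], d[1], sigma),
    driver_params(a[2], b[2], c_[2], d[2], sigma))
  simulate_stock(scenario_config(stock_id = stock_id, seed = seed), pset)
}
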