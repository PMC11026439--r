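#' Simulate one stock with the model's exact generative structure
#'
#' Generates covariate series (fishing mortality from a ramp-then-managed
#' trajectory, sea temperature as an AR(1) process, recruitment i.i.d.
#' lognormal), then builds the biomass trajectory by the same linear model
#' the analysis fits: for each transition year t,
#' \deqn{\ln B_t = \ln B_{t-1} + a + b\,zF_{t-1} + c\,zST_{t-1} + d\,zRec_t + \epsilon_t,}
#' with \eqn{\epsilon_t \sim N(0, \sigma)} using the period's parameters.
#' The z-scores are computed within each period's modelling window (up to 20
#' transitions adjacent to the collapse year, matching how the analysis
#' standardizes), so the true coefficients live on the estimation scale and
#' parameter recovery is well defined. Years outside the two windows reuse
#' the adjacent window's standardization statistics.
#'
#' @param config A [scenario_config()].
#' @param params A [driver_params_set()] with both periods.
#' @return A [stock_series()] whose `truth` block stores the parameters, the
#'   noise draws, the linear predictor, per-period standardization stats and
#'   the period windows. Same `config$seed` gives bit-identical output.
#' @export
simulate_stock <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(params, "driver_params_set"))
  n <- config$n_years
  cy <- config$collapse_year
  set.seed(config$seed)

  # fishing mortality: linear ramp f0 -> f_peak ending at the collapse year,
  # then a step down to the managed level; multiplicative lognormal jitter
  ft <- config$f_trajectory
  shape <- c(seq(ft$f0, ft$f_peak, length.out = cy),
             rep(ft$f_managed, n - cy))
  f <- shape * exp(stats::rnorm(n, 0, ft$jitter))

  # sea temperature: stationary AR(1) around the mean
  ar <- config$sst_ar1
  sst <- numeric(n)
  marg_sd <- if (ar$rho < 1 && ar$sd > 0) ar$sd / sqrt(1 - ar$rho^2) else 0
  sst[1] <- ar$mean + stats::rnorm(1, 0, marg_sd)
  for (t in 2:n)
    sst[t] <- ar$mean + ar$rho * (sst[t - 1] - ar$mean) + stats::rnorm(1, 0, ar$sd)

  # recruitment: i.i.d. lognormal; the optional SST coupling ties log
  # recruitment to the previous year's temperature (the alignment the model
  # rows use), inducing controllable collinearity for VIF checks
  rc <- config$recruitment
  z_iid <- stats::rnorm(n)
  if (rc$sst_rho != 0) {
    zs <- zscore0(c(sst[1], sst[-n]))
    zr <- rc$sst_rho * zs + sqrt(1 - rc$sst_rho^2) * z_iid
  } else zr <- z_iid
  rec <- exp(rc$meanlog + rc$sdlog * zr)

  win <- transition_windows(cy, n)
  # per-period standardization statistics on the aligned covariate values
  stats_for <- function(tt) {
    list(f  = c(mean = mean(f[tt - 1L]),  sd = stats::sd(f[tt - 1L])),
         st = c(mean = mean(sst[tt - 1L]), sd = stats::sd(sst[tt - 1L])),
         rec = c(mean = mean(rec[tt]),     sd = stats::sd(rec[tt])))
  }
  zs_before <- stats_for(win$before)
  zs_after <- stats_for(win$after)

  zval <- function(x, st) {
    if (!is.finite(st["sd"]) || st["sd"] == 0) return(rep(0, length(x)))
    (x - st["mean"]) / st["sd"]
  }

  eps <- numeric(n - 1L)   # aligned to transitions t = 2..n
  linpred <- numeric(n - 1L)
  lnb <- numeric(n)
  lnb[1] <- log(config$initial_biomass)
  for (t in 2:n) {
    if (t <= cy) { p <- params$before; zs <- zs_before }
    else { p <- params$after; zs <- zs_after }
    lp <- p$a +
      p$b * zval(f[t - 1L], zs$f) +
      p$c * zval(sst[t - 1L], zs$st) +
      p$d * zval(rec[t], zs$rec)
    e <- if (p$sigma > 0) stats::rnorm(1, 0, p$sigma) else 0
    linpred[t - 1L] <- lp
    eps[t - 1L] <- e
    lnb[t] <- lnb[t - 1L] + lp + e
  }

  years <- config$start_year + seq_len(n) - 1L
  truth <- list(params = params,
                eps = eps, linpred = linpred,
                collapse_year = years[cy],
                windows = list(before = years[win$before],
                               after = years[win$after]),
                zstats = list(before = zs_before, after = zs_after),
                config = config)
  stock_series(config$stock_id,
               data.frame(year = years, biomass_mt = exp(lnb), f_per_yr = f,
                          recruitment_n = rec, sst_c = sst),
               habitat = config$habitat, life_history = config$life_history,
               bbox = config$bbox, truth = truth)
}

# modelling windows as transition indices (t such that the transition
# t-1 -> t is modelled): up to `wmax` most recent before the trough, up to
# `wmax` earliest after it
transition_windows <- function(collapse_idx, n, wmax = 20L) {
  list(before = seq.int(max(2L, collapse_idx - wmax + 1L), collapse_idx),
       after = if (collapse_idx < n)
         seq.int(collapse_idx + 1L, min(n, collapse_idx + wmax))
       else integer(0))
}

# archetype blueprints: intercept drifts that shape the V (or its intended
# violation); slopes are supplied by the truth sampler. a_after = NA means
# "derive from the skeleton" (see a_after_skeleton); slope_shrink damps the
# sampled slopes where covariate partial sums would spoil the intended
# violation.
archetype_blueprint <- function(archetype) {
  switch(archetype,
    qualifying = list(n_years = 41L, collapse_year = 21L,
                      a_before = -0.115, a_after = NA_real_,
                      slope_shrink = 1,
                      intended = character(0)),
    too_short = list(n_years = 25L, collapse_year = 13L,
                     a_before = -0.18, a_after = NA_real_,
                     slope_shrink = 1,
                     intended = "LENGTH"),
    no_recovery_after = list(n_years = 41L, collapse_year = 21L,
                             a_before = -0.115, a_after = 0.015,
                             slope_shrink = 1,
                             intended = "RECOVERY_AFTER"),
    no_high_before = list(n_years = 51L, collapse_year = 31L,
                          a_before = -0.11, a_after = NA_real_,
                          slope_shrink = 0.2,
                          intended = "RECOVERY_BEFORE"),
    stop("unknown archetype: ", archetype)
  )
}

# after-period intercept from the deterministic skeleton: because the fishing
# effect acts on a monotone z-scored ramp, the pre-collapse path bulges above
# its start by an amount that depends on the sampled b, so the recovery rate
# needed to clear 30% of the realized maximum is slope-dependent. Using the
# noise-free skeleton (ramp F only, c = d = 0), pick the rate that reaches
# 45% of the skeleton maximum by the 15-year recovery screen while capping
# the series end at 90% of that maximum (keeping the maximum in the
# pre-collapse period for typical draws).
a_after_skeleton <- function(bp, b_before, ft) {
  n <- bp$n_years
  cy <- bp$collapse_year
  shape <- c(seq(ft$f0, ft$f_peak, length.out = cy), rep(ft$f_managed, n - cy))
  win <- transition_windows(cy, n)
  flag <- shape[win$before - 1L]
  zf <- (shape[(2:cy) - 1L] - mean(flag)) / stats::sd(flag)
  cum <- cumsum(c(0, bp$a_before + b_before * zf))   # log scale, years 1..cy
  depth <- max(cum) - cum[cy]
  n_after <- length(win$after)
  k <- min(15L, n_after)
  min((depth + log(0.45)) / k, (depth + log(0.9)) / n_after)
}

# allowed failure sets per archetype: the intended criterion must fail and
# nothing outside the allowed set may fail (a 25-year series cannot satisfy
# the 15-years-each-side rule either, so SIDES is tolerated there)
archetype_allowed_failures <- function(archetype) {
  switch(archetype,
    qualifying = character(0),
    too_short = c("LENGTH", "SIDES"),
    no_recovery_after = "RECOVERY_AFTER",
    no_high_before = "RECOVERY_BEFORE")
}

default_slope_sampler <- function() {
  # field-typical effect sizes: fishing negative and dominant before the
  # collapse, weakening after; temperature small either sign; recruitment
  # modestly positive
  list(before = list(b = stats::runif(1, -0.35, -0.15),
                     c = stats::runif(1, -0.15, 0.15),
                     d = stats::runif(1, 0.05, 0.25)),
       after = list(b = stats::runif(1, -0.2, 0.1),
                    c = stats::runif(1, -0.15, 0.15),
                    d = stats::runif(1, 0.0, 0.2)))
}

#' Simulate a cohort of stocks with a known truth table
#'
#' Builds `n_stocks` synthetic stocks of which a fixed fraction qualify under
#' the collapse-selection criteria; the rest cycle through three
#' non-qualifying archetypes (series too short; no recovery after the
#' minimum; no high biomass in the window before the minimum). Because the
#' process noise (sigma = 0.15 by default) makes any single realized
#' trajectory uncertain, each stock's noise seed is redrawn (bounded number
#' of attempts) until the realized path matches its intended verdict — the
#' cohort is conditioned on its truth table, which is what makes the truth
#' table true.
#'
#' @param n_stocks Number of stocks (>= 1).
#' @param qualifying_fraction Fraction in `[0, 1]` of stocks that must
#'   qualify; the count is `round(n_stocks * qualifying_fraction)`.
#' @param seed Integer master seed.
#' @param sigma Process noise standard deviation used for every stock.
#' @param slope_sampler Function returning per-period lists with slopes
#'   `b`, `c`, `d`; called once per stock under the cohort RNG stream.
#' @param max_attempts Redraw budget per stock before erroring.
#' @return List with `stocks` (list of [stock_series()]) and `truth` (data
#'   frame: stock_id, archetype, qualifies, intended_failure, per-period
#'   true parameters, habitat and life-history traits, seed used).
#' @export
simulate_cohort <- function(n_stocks, qualifying_fraction = 0.5, seed = 1L,
                            sigma = 0.15,
                            slope_sampler = default_slope_sampler,
                            max_attempts = 500L) {
  stopifnot(n_stocks >= 1, qualifying_fraction >= 0, qualifying_fraction <= 1)
  n_qual <- round(n_stocks * qualifying_fraction)
  arch_cycle <- c("too_short", "no_recovery_after", "no_high_before")
  archetypes <- c(rep("qualifying", n_qual),
                  arch_cycle[(seq_len(n_stocks - n_qual) - 1L) %% 3L + 1L])

  set.seed(seed)
  stock_seeds <- sample.int(.Machine$integer.max - 1000L, n_stocks)
  stocks <- vector("list", n_stocks)
  rows <- vector("list", n_stocks)

  for (i in seq_len(n_stocks)) {
    arch <- archetypes[i]
    bp <- archetype_blueprint(arch)
    sl <- slope_sampler()
    sl <- lapply(sl, function(per) lapply(per, `*`, bp$slope_shrink))
    a_after <- bp$a_after
    if (is.na(a_after))
      a_after <- a_after_skeleton(bp, sl$before$b,
                                  list(f0 = 0.1, f_peak = 0.8,
                                       f_managed = 0.2))
    pset <- driver_params_set(
      driver_params(a = bp$a_before, b = sl$before$b, c = sl$before$c,
                    d = sl$before$d, sigma = sigma),
      driver_params(a = a_after, b = sl$after$b, c = sl$after$c,
                    d = sl$after$d, sigma = sigma))
    habitat <- sample(HABITATS, 1)
    lh <- list(K = stats::runif(1, 0.1, 0.6),
               common_length = stats::runif(1, 20, 120),
               longevity = stats::runif(1, 3, 40))
    lat0 <- stats::runif(1, -60, 60)
    lon0 <- stats::runif(1, -170, 160)
    bbox <- c(lat_min = lat0, lat_max = lat0 + 10,
              lon_min = lon0, lon_max = lon0 + 10)

    allowed <- archetype_allowed_failures(arch)
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      sub_seed <- (stock_seeds[i] + 99991L * (attempt - 1L)) %%
        (.Machine$integer.max - 1L) + 1L
      cfg <- scenario_config(n_years = bp$n_years,
                             collapse_year = bp$collapse_year,
                             initial_biomass = 1,
                             habitat = habitat, life_history = lh, bbox = bbox,
                             stock_id = sprintf("S%03d", i), seed = sub_seed)
      st <- simulate_stock(cfg, pset)
      cw <- check_collapse(st)
      ok <- if (arch == "qualifying") cw$qualifies else
        (bp$intended %in% cw$failure_reasons &&
           all(cw$failure_reasons %in% allowed))
      if (ok) break
    }
    if (!ok) stop("could not realize archetype '", arch, "' for stock ", i,
                  " within ", max_attempts, " attempts")
    stocks[[i]] <- st
    rows[[i]] <- data.frame(
      stock_id = st$stock_id, archetype = arch,
      qualifies = arch == "qualifying",
      intended_failure = if (length(bp$intended)) bp$intended else NA_character_,
      a_before = pset$before$a, b_before = pset$before$b,
      c_before = pset$before$c, d_before = pset$before$d,
      a_after = pset$after$a, b_after = pset$after$b,
      c_after = pset$after$c, d_after = pset$after$d,
      sigma = sigma, habitat = habitat, K = lh$K,
      common_length = lh$common_length, longevity = lh$longevity,
      seed = sub_seed, attempts = attempt,
      stringsAsFactors = FALSE)
  }
  list(stocks = stocks, truth = do.call(rbind, rows))
}

#' Simulate a gridded monthly sea-temperature field
#'
#' Produces a monthly temperature field on a regular lat/lon grid over
#' `bbox`, whose spatial mean follows a stationary AR(1) process on annual
#' means. By default every cell and month within a year carries the same
#' value (the annual mean), so the field's yearly regional average is the
#' AR(1) series itself; `annual_means` overrides the AR(1) draw with a given
#' series (useful to embed a stock's exact regional temperature).
#'
#' @param bbox Named vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param years Integer vector of consecutive years (non-empty).
#' @param ar1 List with `mean`, `rho`, `sd` (see [scenario_config()]).
#' @param seed Integer seed.
#' @param nlat,nlon Grid resolution inside the box.
#' @param annual_means Optional numeric vector (one value per year)
#'   overriding the AR(1) annual means.
#' @return An object of class `sst_field`: list with `temp` (array
#'   `[12 * n_years, nlat, nlon]`), `years`, `months` (1..12 recycled),
#'   `lat`, `lon` (cell-center coordinates).
#' @export
simulate_sst_field <- function(bbox, years, ar1 = list(mean = 10, rho = 0.6,
                                                       sd = 0.5),
                               seed = 1L, nlat = 4L, nlon = 4L,
                               annual_means = NULL) {
  if (length(years) == 0L) stop("empty year range")
  if (bbox["lat_min"] >= bbox["lat_max"] || bbox["lon_min"] >= bbox["lon_max"])
    stop("degenerate bbox")
  ny <- length(years)
  set.seed(seed)
  if (is.null(annual_means)) {
    a <- numeric(ny)
    marg_sd <- if (ar1$rho < 1 && ar1$sd > 0) ar1$sd / sqrt(1 - ar1$rho^2) else 0
    a[1] <- ar1$mean + stats::rnorm(1, 0, marg_sd)
    if (ny > 1) for (t in 2:ny)
      a[t] <- ar1$mean + ar1$rho * (a[t - 1] - ar1$mean) +
        stats::rnorm(1, 0, ar1$sd)
  } else {
    stopifnot(length(annual_means) == ny)
    a <- annual_means
  }
  lat <- bbox["lat_min"] + (seq_len(nlat) - 0.5) *
    (bbox["lat_max"] - bbox["lat_min"]) / nlat
  lon <- bbox["lon_min"] + (seq_len(nlon) - 0.5) *
    (bbox["lon_max"] - bbox["lon_min"]) / nlon
  temp <- array(rep(a, each = 12L), dim = c(12L * ny, nlat, nlon))
  structure(list(temp = temp, years = as.integer(years),
                 months = rep(1:12, ny),
                 lat = unname(lat), lon = unname(lon)),
            class = "sst_field")
}
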