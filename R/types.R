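#' Driver-effect parameters for one period
#'
#' Bundles the coefficients of the annual log-biomass-change model for a
#' single period (before or after the collapse): the intercept `a` (per-year
#' drift of \eqn{\Delta\ln B}), the fishing effect `b`, the sea-temperature
#' effect `c` and the recruitment effect `d` (all per standardized unit of
#' the driver), and the standard deviation `sigma` of the Gaussian error.
#'
#' @param a Intercept, in log-biomass-change units per year.
#' @param b Effect of standardized lagged fishing mortality.
#' @param c Effect of standardized lagged sea temperature.
#' @param d Effect of standardized same-year recruitment.
#' @param sigma Standard deviation of the Gaussian noise term; must be >= 0
#'   (0 is allowed for noise-free simulation, the fitted model requires > 0).
#' @return An object of class `driver_params`.
#' @export
driver_params <- function(a = 0, b = 0, c = 0, d = 0, sigma = 0.15) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(a = a, b = b, c = c, d = d, sigma = sigma),
            class = "driver_params")
}

#' Pair of before/after driver parameter sets
#'
#' @param before,after `driver_params` objects for the pre- and post-collapse
#'   periods.
#' @return An object of class `driver_params_set`.
#' @export
driver_params_set <- function(before, after) {
  stopifnot(inherits(before, "driver_params"), inherits(after, "driver_params"))
  structure(list(before = before, after = after), class = "driver_params_set")
}

HABITATS <- c("demersal", "pelagic", "benthopelagic", "bathydemersal",
              "bathypelagic", "reef-associated")

#' Scenario configuration for a simulated stock
#'
#' Describes one synthetic stock: series length and placement of the biomass
#' minimum, the shape of the fishing-mortality trajectory, the AR(1) process
#' driving regional sea temperature, the lognormal recruitment distribution,
#' and stock metadata (habitat category and life-history traits).
#'
#' @param n_years Number of years in the series (>= 25; a qualifying stock
#'   needs >= 31 so that 15 transitions fit on each side of the minimum).
#' @param collapse_year Index (1-based within the series) where the collapse
#'   trough is placed.
#' @param f_trajectory List with `f0` (initial F, 1/year), `f_peak` (F at the
#'   collapse year), `f_managed` (post-collapse managed level) and `jitter`
#'   (lognormal sd of multiplicative noise on the deterministic shape).
#' @param sst_ar1 List with `mean` (deg C), `rho` (lag-1 autocorrelation in
#'   `[0, 1)`) and `sd` (innovation standard deviation, deg C).
#' @param recruitment List with `meanlog` and `sdlog` of the lognormal
#'   recruitment distribution, and optionally `sst_rho`, a correlation
#'   between log-recruitment and same-year temperature used to induce
#'   collinearity for VIF checks (default 0).
#' @param initial_biomass Starting total biomass in Mt (> 0).
#' @param habitat One of the six habitat categories
#'   (`"demersal"`, `"pelagic"`, `"benthopelagic"`, `"bathydemersal"`,
#'   `"bathypelagic"`, `"reef-associated"`).
#' @param life_history List with `K` (von Bertalanffy growth rate, 1/year),
#'   `common_length` (cm) and `longevity` (years).
#' @param bbox Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`
#'   giving the stock's nominal distribution square.
#' @param start_year First calendar year of the series.
#' @param stock_id Identifier string.
#' @param seed Integer seed; the whole stock is reproducible from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 41L,
                            collapse_year = 21L,
                            f_trajectory = list(f0 = 0.1, f_peak = 0.8,
                                                f_managed = 0.2, jitter = 0.1),
                            sst_ar1 = list(mean = 10, rho = 0.6, sd = 0.5),
                            recruitment = list(meanlog = log(1e6), sdlog = 0.5,
                                               sst_rho = 0),
                            initial_biomass = 1,
                            habitat = "demersal",
                            life_history = list(K = 0.3, common_length = 60,
                                                longevity = 15),
                            bbox = c(lat_min = 50, lat_max = 60,
                                     lon_min = -10, lon_max = 0),
                            start_year = 1960L,
                            stock_id = "stock_1",
                            seed = 1L) {
  n_years <- as.integer(n_years)
  collapse_year <- as.integer(collapse_year)
  if (n_years < 3L) stop("n_years too small to define a trajectory")
  if (initial_biomass <= 0) stop("initial_biomass must be > 0")
  if (collapse_year < 2L || collapse_year > n_years - 1L)
    stop("collapse_year must be interior to the series")
  if (!habitat %in% HABITATS)
    stop("habitat must be one of: ", paste(HABITATS, collapse = ", "))
  if (!is.null(sst_ar1$rho) && (sst_ar1$rho < 0 || sst_ar1$rho >= 1))
    stop("sst_ar1$rho must be in [0, 1)")
  if (is.null(recruitment$sst_rho)) recruitment$sst_rho <- 0
  if (is.null(f_trajectory$jitter)) f_trajectory$jitter <- 0.1
  structure(list(n_years = n_years, collapse_year = collapse_year,
                 f_trajectory = f_trajectory, sst_ar1 = sst_ar1,
                 recruitment = recruitment, initial_biomass = initial_biomass,
                 habitat = habitat, life_history = life_history, bbox = bbox,
                 start_year = as.integer(start_year), stock_id = stock_id,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Construct a stock series object
#'
#' A `stock_series` holds one stock's aligned annual time series (total
#' biomass in Mt, fishing mortality in 1/year, recruitment in numbers,
#' regional annual sea temperature in deg C) plus metadata, and optionally a
#' `truth` block recorded by the simulator (true parameters, noise draws,
#' standardization statistics and period windows).
#'
#' @param stock_id Identifier.
#' @param data Data frame with columns `year`, `biomass_mt`, `f_per_yr`,
#'   `recruitment_n`, `sst_c`. Years must be consecutive integers and
#'   biomass strictly positive wherever present.
#' @param habitat,life_history,bbox Stock metadata (see [scenario_config()]).
#' @param truth Optional list recorded by the simulator.
#' @return An object of class `stock_series`.
#' @export
stock_series <- function(stock_id, data, habitat = NA_character_,
                         life_history = NULL, bbox = NULL, truth = NULL) {
  req <- c("year", "biomass_mt", "f_per_yr", "recruitment_n", "sst_c")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  data <- as.data.frame(data)[req]
  if (nrow(data) == 0L) stop("empty series")
  if (any(diff(data$year) != 1L))
    stop("years must be strictly increasing with no gaps")
  bm <- data$biomass_mt
  if (any(!is.na(bm) & bm <= 0))
    stop("biomass must be strictly positive (log is taken downstream)")
  structure(list(stock_id = stock_id, data = data, habitat = habitat,
                 life_history = life_history, bbox = bbox, truth = truth),
            class = "stock_series")
}

#' @export
print.stock_series <- function(x, ...) {
  yr <- range(x$data$year)
  cat(sprintf("<stock_series> %s: %d years (%d-%d), habitat %s\n",
              x$stock_id, nrow(x$data), yr[1], yr[2], x$habitat))
  invisible(x)
}

#' @export
print.driver_params <- function(x, ...) {
  cat(sprintf("<driver_params> a=%.3f b=%.3f c=%.3f d=%.3f sigma=%.3f\n",
              x$a, x$b, x$c, x$d, x$sigma))
  invisible(x)
}

# internal: z-scores with sample sd (n-1); sd==0 maps to all-zero scores
# (generator-side tolerance; the analysis-side builder errors instead)
zscore0 <- function(u) {
  s <- stats::sd(u)
  if (!is.finite(s) || s == 0) return(rep(0, length(u)))
  (u - mean(u)) / s
}
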