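#' Regional yearly average sea temperature
#'
#' For each requested year, averages the 12 monthly spatial means of the
#' grid cells whose centers fall inside `bbox` (unweighted: the source grid
#' is coarse relative to the stock squares, so area weighting is not
#' attempted).
#'
#' @param field An `sst_field` (see [simulate_sst_field()] /
#'   [read_sst_field()]).
#' @param bbox Named vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param years Years to average; must all be covered by the field.
#' @return Named numeric vector of annual temperatures (deg C), one per year.
#' @export
regional_yearly_sst <- function(field, bbox, years) {
  stopifnot(inherits(field, "sst_field"))
  li <- which(field$lat >= bbox["lat_min"] & field$lat <= bbox["lat_max"])
  lj <- which(field$lon >= bbox["lon_min"] & field$lon <= bbox["lon_max"])
  if (length(li) == 0L || length(lj) == 0L)
    stop("bbox contains no grid-cell centers")
  if (!all(years %in% field$years))
    stop("years not covered by the field: ",
         paste(setdiff(years, field$years), collapse = ", "))
  out <- vapply(years, function(y) {
    yi <- match(y, field$years)
    rows <- (yi - 1L) * 12L + 1:12
    monthly <- vapply(rows, function(r) mean(field$temp[r, li, lj]), 0)
    if (anyNA(monthly)) stop("missing months for year ", y)
    mean(monthly)
  }, 0)
  names(out) <- years
  out
}

#' Build one period's regression dataset
#'
#' Assembles the response and design matrix the per-period model is fit to:
#' response \eqn{y_t = \ln B_t - \ln B_{t-1}} for each transition year t in
#' the slice, and covariates fishing mortality and sea temperature lagged
#' one year (\eqn{F_{t-1}}, \eqn{ST_{t-1}}) with same-year recruitment
#' (\eqn{Rec_t}), each standardized to z-scores within this dataset using
#' the sample standard deviation (denominator n-1). The raw means and sds
#' used are recorded so the standardization is reproducible.
#'
#' @param slice A `period_slice` from [split_periods()] /
#'   [split_periods_at()].
#' @param sst_series Optional named annual temperature vector (names =
#'   years), e.g. from [regional_yearly_sst()]; defaults to the slice's own
#'   `sst_c` column.
#' @param log_recruitment If `TRUE`, recruitment enters on the log scale
#'   before standardization (default `FALSE`: raw numbers).
#' @return An object of class `model_dataset`: list with `period`, `years`
#'   (transition labels), `y`, `X` (matrix with columns `zF`, `zST`, `zRec`),
#'   and `raw_stats` (per-covariate mean and sd).
#' @export
build_dataset <- function(slice, sst_series = NULL, log_recruitment = FALSE) {
  stopifnot(inherits(slice, "period_slice"))
  d <- slice$data
  if (any(diff(d$year) != 1L)) stop("slice years must be consecutive")
  if (any(is.na(d$biomass_mt)) || any(d$biomass_mt <= 0))
    stop("biomass must be present and strictly positive over the slice")
  tt <- slice$years
  lag_years <- tt - 1L
  val <- function(col, yrs) d[[col]][match(yrs, d$year)]

  y <- log(val("biomass_mt", tt)) - log(val("biomass_mt", lag_years))
  f_raw <- val("f_per_yr", lag_years)
  st_raw <- if (is.null(sst_series)) val("sst_c", lag_years) else {
    if (!all(lag_years %in% names(sst_series)))
      stop("sst_series does not cover the lagged years")
    unname(sst_series[as.character(lag_years)])
  }
  rec_raw <- val("recruitment_n", tt)
  if (log_recruitment) rec_raw <- log(rec_raw)
  if (anyNA(f_raw) || anyNA(st_raw) || anyNA(rec_raw))
    stop("missing covariate values in the slice")

  zcol <- function(u, nm) {
    s <- stats::sd(u)
    if (s == 0) stop("covariate ", nm, " is constant within the window; ",
                     "z-score undefined")
    (u - mean(u)) / s
  }
  X <- cbind(zF = zcol(f_raw, "F"), zST = zcol(st_raw, "ST"),
             zRec = zcol(rec_raw, "Rec"))
  raw_stats <- data.frame(
    covariate = c("F", "ST", "Rec"),
    mean = c(mean(f_raw), mean(st_raw), mean(rec_raw)),
    sd = c(stats::sd(f_raw), stats::sd(st_raw), stats::sd(rec_raw)),
    row.names = NULL)
  structure(list(period = slice$period, stock_id = slice$stock_id,
                 years = tt, y = y, X = X, raw_stats = raw_stats,
                 log_recruitment = log_recruitment),
            class = "model_dataset")
}

#' Variance inflation factors of the design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of column j on the remaining columns (with intercept).
#'
#' @param dataset A `model_dataset`.
#' @return Named numeric vector of VIFs, one per design column.
#' @export
vif <- function(dataset) {
  stopifnot(inherits(dataset, "model_dataset"))
  X <- dataset$X
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 1L) stop("need at least ", p + 1L, " rows")
  if (qr(cbind(1, X))$rank < p + 1L)
    stop("rank-deficient design: VIF undefined")
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  out
}
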