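#' Year of the global biomass minimum
#'
#' Ties are broken by the earliest year, so the verdict is deterministic.
#'
#' @param series A [stock_series()].
#' @return The year (integer) of the minimum recorded biomass.
#' @export
find_minimum <- function(series) {
  stopifnot(inherits(series, "stock_series"))
  bm <- series$data$biomass_mt
  idx <- which(bm == min(bm, na.rm = TRUE))[1]
  series$data$year[idx]
}

#' Collapse-qualification check for one stock
#'
#' A stock qualifies as a collapse-and-recovery case when its biomass series
#' describes a V shape centred on the minimum: the series must be long
#' enough, leave at least 15 years of data on each side of the minimum, and
#' show at least one biomass value of at least `recovery_frac` (30%) of the
#' whole-series maximum within the `recovery_window` years on each side of
#' the minimum (high biomass before the trough, recovery after it). The
#' covariates (fishing mortality, recruitment, temperature) must be present
#' on all modelled years.
#'
#' Named criteria, evaluated in order and all reported:
#' \describe{
#'   \item{LENGTH}{at least `min_length` (30) years of biomass data;}
#'   \item{COVARIATES}{F, SST and recruitment present (non-missing) on every
#'     year required by the minimal 15-transition windows;}
#'   \item{SIDES}{at least `min_side` (15) years of data strictly before and
#'     strictly after the minimum year;}
#'   \item{RECOVERY_BEFORE}{some biomass within the `recovery_window` (15)
#'     years before the minimum is >= threshold;}
#'   \item{RECOVERY_AFTER}{likewise within the 15 years after the minimum.}
#' }
#'
#' @param series A [stock_series()].
#' @param min_length Minimum series length in years (default 30).
#' @param min_side Minimum years strictly on each side of the minimum
#'   (default 15).
#' @param recovery_frac Fraction of the series maximum that counts as
#'   "recovered" (default 0.30).
#' @param recovery_window Width in years of the window on each side of the
#'   minimum inside which the 30% screen is applied (default 15).
#' @return An object of class `collapse_window`: list with `stock_id`,
#'   `min_year`, `max_biomass`, `threshold` (= `recovery_frac * max_biomass`),
#'   `before_years` and `after_years` (year ranges of the up-to-20-transition
#'   modelling windows, ending/starting at `min_year`), `qualifies`,
#'   `failure_reasons`.
#' @export
check_collapse <- function(series, min_length = 30L, min_side = 15L,
                           recovery_frac = 0.30, recovery_window = 15L) {
  stopifnot(inherits(series, "stock_series"))
  d <- series$data
  if (any(!is.na(d$biomass_mt) & d$biomass_mt <= 0))
    stop("non-positive biomass: log-change undefined downstream")

  fails <- character(0)
  min_year <- find_minimum(series)
  min_idx <- match(min_year, d$year)
  n <- sum(!is.na(d$biomass_mt))

  if (n < min_length) fails <- c(fails, "LENGTH")

  # minimal modelled years: transitions (min-14..min) and (min+1..min+15)
  # need biomass on min-15..min+15, F and SST on min-15..min+14,
  # recruitment on min-14..min+15 -- only checked where those years exist
  need <- function(col, yrs) {
    yrs <- yrs[yrs >= d$year[1] & yrs <= d$year[nrow(d)]]
    v <- d[[col]][match(yrs, d$year)]
    any(is.na(v))
  }
  cov_missing <-
    need("biomass_mt", (min_year - min_side):(min_year + min_side)) ||
    need("f_per_yr", (min_year - min_side):(min_year + min_side - 1L)) ||
    need("sst_c", (min_year - min_side):(min_year + min_side - 1L)) ||
    need("recruitment_n", (min_year - min_side + 1L):(min_year + min_side))
  if (cov_missing) fails <- c(fails, "COVARIATES")

  n_before <- sum(!is.na(d$biomass_mt) & d$year < min_year)
  n_after <- sum(!is.na(d$biomass_mt) & d$year > min_year)
  if (n_before < min_side || n_after < min_side) fails <- c(fails, "SIDES")

  max_bm <- max(d$biomass_mt, na.rm = TRUE)
  threshold <- recovery_frac * max_bm
  in_win <- function(lo, hi) {
    v <- d$biomass_mt[d$year >= lo & d$year <= hi]
    any(!is.na(v) & v >= threshold)
  }
  if (!in_win(min_year - recovery_window, min_year - 1L))
    fails <- c(fails, "RECOVERY_BEFORE")
  if (!in_win(min_year + 1L, min_year + recovery_window))
    fails <- c(fails, "RECOVERY_AFTER")

  win <- transition_windows(min_idx, nrow(d))
  structure(list(stock_id = series$stock_id,
                 min_year = min_year,
                 max_biomass = max_bm,
                 threshold = threshold,
                 before_years = c(d$year[min(win$before)] - 1L, min_year),
                 after_years = c(min_year,
                                 if (length(win$after)) d$year[max(win$after)]
                                 else min_year),
                 qualifies = length(fails) == 0L,
                 failure_reasons = fails),
            class = "collapse_window")
}

#' @export
print.collapse_window <- function(x, ...) {
  cat(sprintf("<collapse_window> %s: min %d, max %.3g Mt, threshold %.3g Mt, %s\n",
              x$stock_id, x$min_year, x$max_biomass, x$threshold,
              if (x$qualifies) "QUALIFIES"
              else paste("fails:", paste(x$failure_reasons, collapse = ","))))
  invisible(x)
}

#' Split a qualifying stock into before/after modelling slices
#'
#' The minimum year anchors both windows: the transition into the minimum
#' year belongs to "before", transitions out of it to "after", so the two
#' slices are disjoint in transitions while using all data. Each slice takes
#' as many transitions as available up to `wmax` (20), requiring at least
#' `wmin` (15).
#'
#' @param series A [stock_series()].
#' @param window A qualifying `collapse_window` from [check_collapse()].
#' @param wmin,wmax Minimum/maximum transitions per slice.
#' @return List with `before` and `after` period slices (see
#'   [split_periods_at()]).
#' @export
split_periods <- function(series, window, wmin = 15L, wmax = 20L) {
  stopifnot(inherits(window, "collapse_window"))
  if (!window$qualifies)
    stop("split_periods called on a non-qualifying window (",
         paste(window$failure_reasons, collapse = ","), ")")
  split_periods_at(series, window$min_year, wmin = wmin, wmax = wmax)
}

#' Split a stock at a given anchor year
#'
#' Lower-level worker behind [split_periods()]; also used to build modelling
#' slices directly from a simulated stock's true collapse year without going
#' through qualification.
#'
#' @param series A [stock_series()].
#' @param min_year Anchor year (the biomass trough).
#' @param wmin,wmax Minimum/maximum transitions per slice.
#' @return List of two period slices, each of class `period_slice`: list with
#'   `stock_id`, `period` ("before"/"after"), `years` (transition labels t),
#'   and `data` (rows for the transition years plus the leading lag year).
#' @export
split_periods_at <- function(series, min_year, wmin = 15L, wmax = 20L) {
  d <- series$data
  min_idx <- match(min_year, d$year)
  if (is.na(min_idx)) stop("min_year not in series")
  win <- transition_windows(min_idx, nrow(d), wmax = wmax)
  if (length(win$before) < wmin || length(win$after) < wmin)
    stop("fewer than ", wmin, " transitions on one side of the minimum")
  mk <- function(tt, period) {
    rows <- c(min(tt) - 1L, tt)
    structure(list(stock_id = series$stock_id, period = period,
                   years = d$year[tt], data = d[rows, , drop = FALSE]),
              class = "period_slice")
  }
  list(before = mk(win$before, "before"), after = mk(win$after, "after"))
}
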