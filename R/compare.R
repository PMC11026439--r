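#' Posterior-resampling comparison of before/after effects
#'
#' For each parameter, draws `n_resamples` values with replacement
#' independently from the before-fit's and the after-fit's retained draws
#' and reports the proportion of pairs where the after draw is strictly
#' greater than the before draw (ties count as "not greater"). Credibility
#' flags mark stocks where at least 80% / 90% of the resampled mass lies on
#' one side (`p >= 0.8` or `p <= 0.2`; likewise 0.9/0.1), so `flag90`
#' implies `flag80`.
#'
#' @param before,after `posterior_fit` objects for the two periods.
#' @param n_resamples Number of resampled pairs (default 10,000).
#' @param seed Integer seed.
#' @param params Parameters to compare (default `b`, `c`, `d`; add `"a"`
#'   for the intercept).
#' @return An object of class `effect_comparison`: data frame with columns
#'   `stock_id`, `parameter`, `p_after_gt_before`, `flag80`, `flag90`,
#'   plus attributes `n_resamples` and `seed`.
#' @export
compare_posteriors <- function(before, after, n_resamples = 10000L, seed = 1L,
                               params = c("b", "c", "d")) {
  stopifnot(inherits(before, "posterior_fit"), inherits(after, "posterior_fit"))
  if (nrow(before$draws) == 0L || nrow(after$draws) == 0L)
    stop("empty draw sets")
  set.seed(seed)
  rows <- lapply(params, function(pp) {
    db <- before$draws[, pp]
    da <- after$draws[, pp]
    ib <- sample.int(length(db), n_resamples, replace = TRUE)
    ia <- sample.int(length(da), n_resamples, replace = TRUE)
    p <- mean(da[ia] > db[ib])
    data.frame(stock_id = before$stock_id, parameter = pp,
               p_after_gt_before = p,
               flag80 = p >= 0.8 || p <= 0.2,
               flag90 = p >= 0.9 || p <= 0.1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_resamples") <- n_resamples
  attr(out, "seed") <- seed
  class(out) <- c("effect_comparison", class(out))
  out
}

EFFECT_CLASSES <- c("POS_STRONGER", "POS_WEAKER", "NEG_STRONGER",
                    "NEG_WEAKER", "POS_TO_NEG", "NEG_TO_POS")

#' Six-area classification of an effect change
#'
#' Partitions the (before-effect, after-effect) plane off the axes and
#' diagonal into six areas: a positive effect becoming stronger
#' (`0 < before < after`) or weaker but staying positive
#' (`0 < after < before`); a negative effect becoming stronger
#' (`after < before < 0`) or weaker but staying negative
#' (`before < after < 0`); a positive effect turning negative
#' (`before > 0 > after`); and a negative effect turning positive
#' (`before < 0 < after`). Exact zeros or exact ties — measure-zero for
#' continuous posteriors — are resolved by nudging toward the sign of
#' `before + after` so every point receives a category; such boundary
#' cases are flagged via the `"boundary"` attribute.
#'
#' @param before_est,after_est Point estimates (posterior medians by
#'   default upstream) of the effect in the two periods.
#' @return A length-1 character category (one of the six) with attribute
#'   `boundary` (logical).
#' @export
classify_change <- function(before_est, after_est) {
  stopifnot(is.finite(before_est), is.finite(after_est))
  b <- before_est
  a <- after_est
  boundary <- (b == 0 || a == 0 || a == b)
  if (boundary) {
    s <- sign(b + a)
    if (s == 0) s <- 1
    nudge <- max(abs(b), abs(a), 1) * 1e-12
    if (b == 0) b <- s * nudge
    if (a == 0) a <- s * nudge
    if (a == b) a <- a + s * nudge
  }
  cat_out <-
    if (b > 0 && a > 0) { if (a > b) "POS_STRONGER" else "POS_WEAKER" }
    else if (b < 0 && a < 0) { if (a < b) "NEG_STRONGER" else "NEG_WEAKER" }
    else if (b > 0 && a < 0) "POS_TO_NEG"
    else "NEG_TO_POS"
  structure(cat_out, boundary = boundary)
}

#' Sign-ratio table of posterior-median effects
#'
#' Counts, per parameter and period, how many retained stocks have a
#' negative vs. a positive posterior-median effect (an exactly zero median,
#' measure-zero in practice, is counted as positive). Negative + positive
#' equals the retained stock count in every cell.
#'
#' @param medians Data frame with columns `stock_id`, `parameter`, `period`,
#'   `estimate` (one row per stock x parameter x period).
#' @return Data frame with columns `parameter`, `period`, `negative`,
#'   `positive`, `ratio` (formatted "neg/pos").
#' @export
tabulate_sign_ratios <- function(medians) {
  req <- c("stock_id", "parameter", "period", "estimate")
  stopifnot(all(req %in% names(medians)))
  agg <- expand.grid(parameter = unique(medians$parameter),
                     period = unique(medians$period),
                     stringsAsFactors = FALSE)
  agg$negative <- NA_integer_
  agg$positive <- NA_integer_
  for (i in seq_len(nrow(agg))) {
    v <- medians$estimate[medians$parameter == agg$parameter[i] &
                            medians$period == agg$period[i]]
    agg$negative[i] <- sum(v < 0)
    agg$positive[i] <- sum(v >= 0)
  }
  agg$ratio <- sprintf("%d/%d", agg$negative, agg$positive)
  agg
}
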