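#' Change of effect between periods
#'
#' The per-stock, per-parameter quantity summarized in the habitat and
#' life-history figures: `after - before` on the standardized-effect scale.
#' Positive values mean the effect moved toward a more positive effect.
#'
#' @param before_est,after_est Point estimates of the effect in the two
#'   periods.
#' @return `after_est - before_est`.
#' @export
change_of_effect <- function(before_est, after_est) {
  stopifnot(all(is.finite(before_est)), all(is.finite(after_est)))
  after_est - before_est
}

#' Tertile binning of a life-history trait
#'
#' @param x Numeric trait values over the retained stocks.
#' @return Factor with levels `low`, `mid`, `high`; bin edges (the 1/3 and
#'   2/3 quantiles, linear interpolation) as attribute `edges`.
#' @export
bin_tertiles <- function(x) {
  edges <- stats::quantile(x, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  # direct comparison instead of cut(): robust to tied edges (tiny groups)
  f <- factor(ifelse(x <= edges[1], "low",
                     ifelse(x <= edges[2], "mid", "high")),
              levels = c("low", "mid", "high"))
  attr(f, "edges") <- edges
  f
}

#' Grouped summary of effect changes
#'
#' Summarizes per-stock changes of effect (`after - before`) by group:
#' habitat category, or tertile bins over a life-history trait (`K`,
#' `common_length`, `longevity`). Per group and parameter it reports the
#' count, median, first and third quartiles, and the 5th and 95th
#' percentiles — the box-and-whisker summary convention. Quantiles use the
#' linear-interpolation convention (R type 7).
#'
#' @param deltas Data frame with columns `stock_id`, `parameter`, `delta`.
#' @param metadata Data frame with columns `stock_id`, `habitat`, `K`,
#'   `common_length`, `longevity` (one row per stock).
#' @param by Grouping variable: `"habitat"` or one of the trait names.
#' @return Data frame with columns `group`, `parameter`, `n`, `median`,
#'   `q1`, `q3`, `p5`, `p95`; empty groups keep `n = 0` with `NA`
#'   statistics. For trait groupings the bin edges are attached as
#'   attribute `edges`.
#' @export
group_summary <- function(deltas, metadata, by = "habitat") {
  stopifnot(all(c("stock_id", "parameter", "delta") %in% names(deltas)),
            "stock_id" %in% names(metadata))
  if (!all(deltas$stock_id %in% metadata$stock_id))
    stop("metadata missing for some stocks")
  edges <- NULL
  if (by == "habitat") {
    grp <- factor(metadata$habitat, levels = HABITATS)
  } else {
    if (!by %in% names(metadata)) stop("unknown grouping variable: ", by)
    grp <- bin_tertiles(metadata[[by]])
    edges <- attr(grp, "edges")
  }
  names(grp) <- metadata$stock_id
  gvals <- levels(grp)
  params <- unique(deltas$parameter)
  rows <- list()
  for (g in gvals) for (pp in params) {
    ids <- names(grp)[!is.na(grp) & grp == g]
    v <- deltas$delta[deltas$parameter == pp & deltas$stock_id %in% ids]
    if (length(v) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = pp, n = 0L, median = NA_real_, q1 = NA_real_,
        q3 = NA_real_, p5 = NA_real_, p95 = NA_real_, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                           names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = pp, n = length(v), median = q[3], q1 = q[2],
        q3 = q[4], p5 = q[1], p95 = q[5], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(edges)) attr(out, "edges") <- edges
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one object: selection window
#' sizes and recovery fraction, retention thresholds, MCMC settings,
#' resampling count and seeds.
#'
#' @param window_min,window_max Minimum/maximum transitions per period
#'   (15/20).
#' @param recovery_frac Recovery threshold as a fraction of the series
#'   maximum (0.30).
#' @param min_length Minimum series length in years (30).
#' @param r2_threshold Median Bayesian R2 retention threshold (0.2).
#' @param rhat_threshold Convergence threshold (1.01).
#' @param mcmc An [mcmc_config()].
#' @param n_resamples Posterior-comparison resamples (10,000).
#' @param seed Master seed for per-stock derived seeds.
#' @param point_estimate `"median"` (default) or `"mean"` for the six-area
#'   classification.
#' @param log_recruitment Passed to [build_dataset()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_min = 15L, window_max = 20L,
                            recovery_frac = 0.30, min_length = 30L,
                            r2_threshold = 0.2, rhat_threshold = 1.01,
                            mcmc = mcmc_config(), n_resamples = 10000L,
                            seed = 1L, point_estimate = "median",
                            log_recruitment = FALSE) {
  stopifnot(point_estimate %in% c("median", "mean"))
  structure(list(window_min = as.integer(window_min),
                 window_max = as.integer(window_max),
                 recovery_frac = recovery_frac,
                 min_length = as.integer(min_length),
                 r2_threshold = r2_threshold,
                 rhat_threshold = rhat_threshold, mcmc = mcmc,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), point_estimate = point_estimate,
                 log_recruitment = log_recruitment),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes selection, dataset construction, per-period Bayesian fits, the
#' R2/convergence retention filter, posterior comparison, six-area
#' classification and grouped summaries, with stock-level error isolation
#' (one failing stock is logged, not fatal). All randomness derives from
#' `config$seed`, so reruns with the same inputs are byte-identical after
#' [write_run_report()].
#'
#' @param cohort List with `stocks` (list of [stock_series()]); an optional
#'   `truth` element is echoed into the report for downstream checks.
#' @param sst_field Optional `sst_field`; when given, each stock's annual
#'   temperature series is extracted over its bbox with
#'   [regional_yearly_sst()] instead of using the stock's own `sst_c`
#'   column.
#' @param config A [pipeline_config()].
#' @return An object of class `run_report`: nested list with stage counts,
#'   the selector verdicts, fit summaries, retention log, per-parameter
#'   sign-ratio tables, six-area classification counts, the per-stock
#'   comparison table and group summaries.
#' @export
run_pipeline <- function(cohort, sst_field = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stocks <- cohort$stocks
  n_in <- length(stocks)
  errors <- list()

  # --- selection -----------------------------------------------------------
  verdicts <- list()
  windows <- list()
  for (st in stocks) {
    cw <- tryCatch(check_collapse(st, min_length = config$min_length,
                                  min_side = config$window_min,
                                  recovery_frac = config$recovery_frac),
                   error = function(e) e)
    if (inherits(cw, "error")) {
      errors[[st$stock_id]] <- paste("select:", conditionMessage(cw))
      next
    }
    windows[[st$stock_id]] <- cw
    verdicts[[st$stock_id]] <- data.frame(
      stock_id = st$stock_id, qualifies = cw$qualifies,
      min_year = cw$min_year,
      before_start = cw$before_years[1], after_end = cw$after_years[2],
      failure_reasons = paste(cw$failure_reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  verdict_tbl <- do.call(rbind, unname(verdicts))
  selected <- verdict_tbl$stock_id[verdict_tbl$qualifies]

  # --- datasets and fits ---------------------------------------------------
  fits <- list()
  stock_by_id <- stats::setNames(stocks, vapply(stocks, `[[`, "", "stock_id"))
  for (i in seq_along(selected)) {
    id <- selected[i]
    st <- stock_by_id[[id]]
    res <- tryCatch({
      sl <- split_periods(st, windows[[id]], wmin = config$window_min,
                          wmax = config$window_max)
      sst_series <- NULL
      if (!is.null(sst_field)) {
        yrs <- (min(sl$before$data$year)):(max(sl$after$data$year))
        sst_series <- regional_yearly_sst(sst_field, st$bbox, yrs)
      }
      ds_b <- build_dataset(sl$before, sst_series,
                            log_recruitment = config$log_recruitment)
      ds_a <- build_dataset(sl$after, sst_series,
                            log_recruitment = config$log_recruitment)
      mk_cfg <- function(off) {
        cfg <- config$mcmc
        cfg$seed <- (config$seed + 7919L * i + off) %% 2000000000L
        cfg
      }
      list(before = fit_period_model(ds_b, mk_cfg(0L)),
           after = fit_period_model(ds_a, mk_cfg(1000L)),
           datasets = list(before = ds_b, after = ds_a))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- paste("fit:", conditionMessage(res))
    } else fits[[id]] <- res
  }

  # --- retention filter ----------------------------------------------------
  flt <- filter_stocks(lapply(fits, function(x) x[c("before", "after")]),
                       r2_threshold = config$r2_threshold,
                       rhat_threshold = config$rhat_threshold)
  retained <- flt$retained

  # --- comparison and classification ---------------------------------------
  point_fun <- if (config$point_estimate == "median") stats::median else mean
  comp_rows <- list()
  med_rows <- list()
  for (i in seq_along(retained)) {
    id <- retained[i]
    fb <- fits[[id]]$before
    fa <- fits[[id]]$after
    cmp <- compare_posteriors(fb, fa, n_resamples = config$n_resamples,
                              seed = (config$seed + 104729L * i) %% 2000000000L)
    for (pp in c("b", "c", "d")) {
      be <- point_fun(fb$draws[, pp])
      ae <- point_fun(fa$draws[, pp])
      cl <- classify_change(be, ae)
      r <- cmp[cmp$parameter == pp, ]
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        stock_id = id, parameter = pp,
        before_est = be, after_est = ae,
        delta = change_of_effect(be, ae),
        p_after_gt_before = r$p_after_gt_before,
        flag80 = r$flag80, flag90 = r$flag90,
        category = as.character(cl), stringsAsFactors = FALSE)
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        stock_id = id, parameter = pp, period = "before", estimate = be,
        stringsAsFactors = FALSE)
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        stock_id = id, parameter = pp, period = "after", estimate = ae,
        stringsAsFactors = FALSE)
    }
  }
  comparison_tbl <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  medians_tbl <- if (length(med_rows)) do.call(rbind, med_rows) else NULL

  sign_ratios <- if (!is.null(medians_tbl)) tabulate_sign_ratios(medians_tbl)
  class_counts <- NULL
  if (!is.null(comparison_tbl)) {
    class_counts <- as.data.frame(
      table(parameter = comparison_tbl$parameter,
            category = factor(comparison_tbl$category,
                              levels = EFFECT_CLASSES)),
      stringsAsFactors = FALSE)
    names(class_counts)[3] <- "n"
  }

  # --- grouped summaries ---------------------------------------------------
  group_summaries <- NULL
  if (!is.null(comparison_tbl) && length(retained) > 0L) {
    meta <- do.call(rbind, lapply(retained, function(id) {
      st <- stock_by_id[[id]]
      data.frame(stock_id = id, habitat = st$habitat,
                 K = st$life_history$K,
                 common_length = st$life_history$common_length,
                 longevity = st$life_history$longevity,
                 stringsAsFactors = FALSE)
    }))
    deltas <- comparison_tbl[c("stock_id", "parameter", "delta")]
    group_summaries <- lapply(
      stats::setNames(nm = c("habitat", "K", "common_length", "longevity")),
      function(v) {
        gs <- group_summary(deltas, meta, by = v)
        list(table = gs, edges = attr(gs, "edges"))
      })
  }

  structure(list(
    config = unclass(config)[setdiff(names(unclass(config)), "mcmc")],
    mcmc = unclass(config$mcmc),
    counts = list(n_in = n_in, n_selected = length(selected),
                  n_fitted = length(fits), n_retained = length(retained)),
    selection = verdict_tbl,
    retention = flt$log,
    sign_ratios = sign_ratios,
    class_counts = class_counts,
    comparisons = comparison_tbl,
    group_summaries = group_summaries,
    errors = errors,
    truth = cohort$truth), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(paste0("<run_report> %d stocks in, %d selected, %d fitted, ",
                     "%d retained\n"),
              x$counts$n_in, x$counts$n_selected, x$counts$n_fitted,
              x$counts$n_retained))
  if (!is.null(x$sign_ratios)) {
    cat("  sign ratios (negative/positive):\n")
    print(x$sign_ratios[c("parameter", "period", "ratio")], row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a run report to structured text
#'
#' Writes the report as JSON with stable key order and fixed numeric
#' formatting, so identical runs produce byte-identical files.
#'
#' @param report A `run_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
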