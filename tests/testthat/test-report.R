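test_that("change of effect is the after-minus-before difference", {
  expect_equal(change_of_effect(-0.4, -0.1), 0.3)
  expect_equal(change_of_effect(0.7, 0.7), 0)
  # positive delta = toward a more positive effect
  expect_gt(change_of_effect(-0.5, 0.2), 0)
  expect_lt(change_of_effect(0.2, -0.5), 0)
})

test_that("group summaries reproduce quartile arithmetic and conservation", {
  deltas <- data.frame(stock_id = sprintf("s%d", 1:5), parameter = "b",
                       delta = c(1, 2, 3, 4, 5))
  meta <- data.frame(stock_id = sprintf("s%d", 1:5), habitat = "pelagic",
                     K = 1:5 / 10, common_length = 50, longevity = 10)
  gs <- group_summary(deltas, meta, by = "habitat")
  row <- gs[gs$group == "pelagic", ]
  expect_equal(row$n, 5)
  expect_equal(row$median, 3)
  expect_equal(row$q1, 2)
  expect_equal(row$q3, 4)
  expect_equal(sum(gs$n), 5)   # empty habitats contribute n = 0
  expect_true(all(gs$n[gs$group != "pelagic"] == 0))
  expect_true(all(is.na(gs$median[gs$group != "pelagic"])))
})

test_that("quantiles agree with an independent sort-and-interpolate oracle", {
  # oracle: type-7 linear interpolation written out directly
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(70)
  for (rep in 1:5) {
    v <- rnorm(sample(5:40, 1))
    deltas <- data.frame(stock_id = sprintf("s%d", seq_along(v)),
                         parameter = "c", delta = v)
    meta <- data.frame(stock_id = deltas$stock_id, habitat = "demersal",
                       K = 0.2, common_length = 50, longevity = 10)
    gs <- group_summary(deltas, meta, by = "habitat")
    row <- gs[gs$group == "demersal", ]
    expect_equal(row$p5, q7(v, 0.05), tolerance = 1e-12)
    expect_equal(row$q1, q7(v, 0.25), tolerance = 1e-12)
    expect_equal(row$median, q7(v, 0.5), tolerance = 1e-12)
    expect_equal(row$q3, q7(v, 0.75), tolerance = 1e-12)
    expect_equal(row$p95, q7(v, 0.95), tolerance = 1e-12)
  }
})

test_that("life-history grouping uses tertile bins with logged edges", {
  set.seed(71)
  n <- 12
  deltas <- data.frame(stock_id = sprintf("s%d", 1:n), parameter = "b",
                       delta = rnorm(n))
  meta <- data.frame(stock_id = deltas$stock_id, habitat = "demersal",
                     K = runif(n, 0.1, 0.6), common_length = 50,
                     longevity = 10)
  gs <- group_summary(deltas, meta, by = "K")
  expect_setequal(unique(gs$group), c("low", "mid", "high"))
  expect_equal(sum(gs$n), n)
  edges <- attr(gs, "edges")
  expect_length(edges, 2)
  expect_equal(edges, quantile(meta$K, c(1/3, 2/3), names = FALSE),
               tolerance = 1e-12)
  expect_error(group_summary(deltas, meta, by = "weight"), "unknown grouping")
})

make_pipeline_cohort <- function(seed = 5) {
  simulate_cohort(8, qualifying_fraction = 0.5, seed = seed, sigma = 0.08)
}

fast_pipeline_config <- function(seed = 11) {
  pipeline_config(mcmc = fast_mcmc(), n_resamples = 2000, seed = seed)
}

test_that("the pipeline runs end to end with correct stage accounting", {
  coh <- make_pipeline_cohort()
  rep <- run_pipeline(coh, config = fast_pipeline_config())
  expect_equal(rep$counts$n_in, 8)
  expect_equal(rep$counts$n_selected, sum(coh$truth$qualifies))
  expect_lte(rep$counts$n_retained, rep$counts$n_fitted)
  # conservation: six-area counts sum to retained stocks per parameter
  if (!is.null(rep$class_counts)) {
    sums <- tapply(rep$class_counts$n, rep$class_counts$parameter, sum)
    expect_true(all(sums == rep$counts$n_retained))
  }
  # sign ratios conserve too
  expect_true(all(rep$sign_ratios$negative + rep$sign_ratios$positive ==
                    rep$counts$n_retained))
  # group summaries count every retained stock once per parameter
  hab <- rep$group_summaries$habitat$table
  expect_true(all(tapply(hab$n, hab$parameter, sum) == rep$counts$n_retained))
})

test_that("pipeline reruns with identical config are byte-identical", {
  coh <- make_pipeline_cohort()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "r1.json"); p2 <- file.path(dir, "r2.json")
  write_run_report(run_pipeline(coh, config = fast_pipeline_config()), p1)
  write_run_report(run_pipeline(coh, config = fast_pipeline_config()), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("a failing stock is isolated, not fatal", {
  coh <- make_pipeline_cohort()
  # corrupt one qualifying stock so its fit stage errors (constant F)
  qi <- which(coh$truth$qualifies)[1]
  coh$stocks[[qi]]$data$f_per_yr <- rep(0.3, nrow(coh$stocks[[qi]]$data))
  rep <- run_pipeline(coh, config = fast_pipeline_config())
  bad_id <- coh$stocks[[qi]]$stock_id
  expect_true(bad_id %in% names(rep$errors))
  expect_equal(rep$counts$n_fitted, rep$counts$n_selected - 1)
})

test_that("the sst-field route matches the stock-column route", {
  coh <- make_pipeline_cohort(seed = 13)
  qi <- which(coh$truth$qualifies)
  coh$stocks <- coh$stocks[qi]
  coh$truth <- coh$truth[qi, ]
  # shared bbox; field embeds the first stock's exact annual temperatures
  bbox <- c(lat_min = 0, lat_max = 10, lon_min = 0, lon_max = 10)
  st <- coh$stocks[[1]]
  st$bbox <- bbox
  fld <- simulate_sst_field(bbox, st$data$year, seed = 1,
                            annual_means = st$data$sst_c)
  coh$stocks <- list(st)
  coh$truth <- coh$truth[1, ]
  r_col <- run_pipeline(coh, config = fast_pipeline_config())
  r_fld <- run_pipeline(coh, sst_field = fld, config = fast_pipeline_config())
  expect_equal(r_fld$comparisons$p_after_gt_before,
               r_col$comparisons$p_after_gt_before, tolerance = 1e-10)
  expect_identical(r_fld$comparisons$category, r_col$comparisons$category)
})
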