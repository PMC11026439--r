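#' Write a cohort to delimited text plus a JSON sidecar
#'
#' The time series go to `stocks.csv` (one row per stock-year: stock_id,
#' year, biomass_mt, f_per_yr, recruitment_n, sst_c); habitat, life-history
#' traits, bounding boxes and — when present — the simulator's truth block
#' go to `metadata.json`.
#'
#' @param cohort List with `stocks` (list of [stock_series()]) and
#'   optionally `truth` (data frame).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(cohort$stocks, function(st)
    cbind(stock_id = st$stock_id, st$data)))
  utils::write.csv(rows, file.path(dir, "stocks.csv"), row.names = FALSE)
  meta <- lapply(cohort$stocks, function(st) {
    tr <- st$truth
    list(stock_id = st$stock_id, habitat = st$habitat,
         life_history = st$life_history, bbox = as.list(st$bbox),
         truth = if (is.null(tr)) NULL else list(
           params = lapply(tr$params, unclass),
           eps = tr$eps, linpred = tr$linpred,
           collapse_year = tr$collapse_year,
           windows = tr$windows))
  })
  payload <- list(stocks = meta, truth_table = cohort$truth)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"),
             file.path(dir, "metadata.json"), useBytes = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `stocks.csv` and `metadata.json`.
#' @return List with `stocks` and `truth` as produced by
#'   [simulate_cohort()] (the truth block's parameter lists are restored as
#'   `driver_params`).
#' @export
read_cohort <- function(dir) {
  rows <- utils::read.csv(file.path(dir, "stocks.csv"),
                          stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"),
                             simplifyDataFrame = FALSE)
  stocks <- lapply(meta$stocks, function(m) {
    d <- rows[rows$stock_id == m$stock_id,
              c("year", "biomass_mt", "f_per_yr", "recruitment_n", "sst_c")]
    truth <- NULL
    if (!is.null(m$truth)) {
      pb <- m$truth$params$before
      pa <- m$truth$params$after
      truth <- list(
        params = driver_params_set(
          driver_params(pb$a, pb$b, pb$c, pb$d, pb$sigma),
          driver_params(pa$a, pa$b, pa$c, pa$d, pa$sigma)),
        eps = unlist(m$truth$eps), linpred = unlist(m$truth$linpred),
        collapse_year = m$truth$collapse_year,
        windows = lapply(m$truth$windows, unlist))
    }
    stock_series(m$stock_id, d, habitat = m$habitat,
                 life_history = m$life_history,
                 bbox = unlist(m$bbox), truth = truth)
  })
  truth_tbl <- NULL
  if (!is.null(meta$truth_table))
    truth_tbl <- do.call(rbind, lapply(meta$truth_table, function(r)
      as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                    stringsAsFactors = FALSE)))
  list(stocks = stocks, truth = truth_tbl)
}

#' Write a gridded temperature field as long-format delimited text
#'
#' One row per (year, month, lat, lon) cell with the temperature in deg C;
#' grid coordinates go to a JSON sidecar. (An array-file stand-in usable
#' without a netCDF reader.)
#'
#' @param field An `sst_field`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sst_field <- function(field, dir) {
  stopifnot(inherits(field, "sst_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ny <- length(field$years)
  grid <- expand.grid(lon = field$lon, lat = field$lat,
                      month = 1:12, year = field$years)
  # temp is [time, lat, lon]; build matching vector
  vals <- numeric(nrow(grid))
  k <- 1L
  nlat <- length(field$lat); nlon <- length(field$lon)
  for (yi in seq_len(ny)) for (m in 1:12) {
    r <- (yi - 1L) * 12L + m
    block <- t(field$temp[r, , , drop = TRUE])   # lon x lat
    vals[k:(k + nlat * nlon - 1L)] <- as.vector(block)
    k <- k + nlat * nlon
  }
  grid$sst_c <- vals
  utils::write.csv(grid[c("year", "month", "lat", "lon", "sst_c")],
                   file.path(dir, "sst_field.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(list(years = field$years, lat = field$lat,
                                   lon = field$lon),
                              digits = NA, pretty = TRUE),
             file.path(dir, "sst_meta.json"), useBytes = TRUE)
  invisible(dir)
}

#' Read a gridded temperature field written by [write_sst_field()]
#'
#' @param dir Directory holding `sst_field.csv` and `sst_meta.json`.
#' @return An `sst_field`.
#' @export
read_sst_field <- function(dir) {
  rows <- utils::read.csv(file.path(dir, "sst_field.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "sst_meta.json"))
  years <- as.integer(meta$years)
  lat <- meta$lat; lon <- meta$lon
  ny <- length(years); nlat <- length(lat); nlon <- length(lon)
  temp <- array(NA_real_, dim = c(12L * ny, nlat, nlon))
  yi <- match(rows$year, years)
  mi <- rows$month
  li <- match(rows$lat, lat)
  lj <- match(rows$lon, lon)
  temp[cbind((yi - 1L) * 12L + mi, li, lj)] <- rows$sst_c
  structure(list(temp = temp, years = years, months = rep(1:12, ny),
                 lat = lat, lon = lon), class = "sst_field")
}
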