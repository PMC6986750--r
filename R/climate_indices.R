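# Monthly climate variables: temperature means, precipitation sums and the
# thresholded cumulative dry-period index, plus per-month linear detrending.

# Internal constructor for a year x month climate matrix.
month_matrix <- function(values, variable, threshold = NA) {
  structure(values, variable = variable, threshold = threshold)
}

check_daily <- function(daily) {
  need <- c("date", "tmean_c", "precip_mm")
  assert_that(all(need %in% names(daily)),
              paste("daily climate needs columns:", paste(need, collapse = ", ")))
  d <- as.Date(daily$date)
  assert_that(!anyDuplicated(d), "duplicate dates in daily climate")
  assert_that(all(diff(sort(d)) == 1), "daily climate has date gaps")
  assert_that(all(daily$precip_mm >= 0), "negative precipitation")
  invisible(d)
}

#' Find dry spells in a daily precipitation record
#'
#' A dry spell is a maximal run of consecutive days with precipitation at or
#' below `wet_cutoff`. Spells may cross month (and year) boundaries.
#'
#' @param daily daily climate table (`date`, `tmean_c`, `precip_mm`),
#'   gap-free.
#' @param wet_cutoff precipitation (mm) at or below which a day counts as
#'   dry. The default 0 is the strict "non-raining" reading; 0.5 is a common
#'   trace-rain convention.
#' @return data.frame with `start` (Date) and `length` (days) per spell.
#' @export
find_dry_spells <- function(daily, wet_cutoff = 0) {
  check_daily(daily)
  o <- order(as.Date(daily$date))
  dates <- as.Date(daily$date)[o]
  dry <- daily$precip_mm[o] <= wet_cutoff
  r <- rle(dry)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = dates[starts[keep]], length = r$lengths[keep])
}

#' Monthly cumulative dry-period index
#'
#' For threshold k, a spell qualifies if its full length is at least k days;
#' each qualifying spell contributes its days to the calendar month each day
#' falls in (a spell spanning a month boundary registers in both months).
#' At k = 1 the index is simply the number of dry days per month. Short
#' dry breaks below k days are thereby ignored, so the index accumulates
#' sustained drought exposure per month.
#'
#' @param daily daily climate table.
#' @param threshold minimum spell length k in days (1-7 in routine use;
#'   larger values are allowed but tend to fail the zero-ratio rule).
#' @param wet_cutoff see [find_dry_spells()].
#' @return year x month matrix (rownames years, colnames "01".."12") with
#'   attributes `variable = "dry"` and `threshold`.
#' @export
monthly_dry_index <- function(daily, threshold, wet_cutoff = 0) {
  assert_that(length(threshold) == 1 && threshold >= 1,
              "threshold must be a single value >= 1")
  dates <- check_daily(daily)
  dates <- sort(dates)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  m <- matrix(0, nrow = length(years), ncol = 12,
              dimnames = list(as.character(years), sprintf("%02d", 1:12)))
  spells <- find_dry_spells(daily, wet_cutoff)
  spells <- spells[spells$length >= threshold, , drop = FALSE]
  if (nrow(spells)) {
    days <- do.call(c, lapply(seq_len(nrow(spells)), function(i)
      seq(spells$start[i], by = "day", length.out = spells$length[i])))
    tab <- table(format(days, "%Y"), format(days, "%m"))
    m[rownames(tab), colnames(tab)] <- m[rownames(tab), colnames(tab)] + tab
  }
  month_matrix(m, "dry", threshold)
}

#' Fraction of zero cells in a monthly climate matrix
#'
#' Large dry-period thresholds produce many months with no qualifying spell;
#' a threshold is admissible when fewer than half the (year, month) cells are
#' zero, guarding correlation traits against near-constant climate vectors.
#'
#' @param m a year x month matrix.
#' @return fraction of cells equal to zero.
#' @export
zero_ratio <- function(m) {
  assert_that(length(m) > 0, "empty climate matrix")
  mean(m == 0)
}

#' @rdname zero_ratio
#' @export
admissible_threshold <- function(m) zero_ratio(m) < 0.5

#' Monthly temperature and precipitation aggregates
#'
#' Arithmetic mean of daily mean temperature and sum of daily precipitation
#' per calendar month.
#'
#' @param daily daily climate table.
#' @return list with `temperature` and `precipitation` year x month matrices.
#' @export
monthly_aggregate <- function(daily) {
  check_daily(daily)
  y <- format(as.Date(daily$date), "%Y")
  mo <- format(as.Date(daily$date), "%m")
  years <- sort(unique(y))
  shape <- function(tab) {
    m <- matrix(NA_real_, length(years), 12,
                dimnames = list(years, sprintf("%02d", 1:12)))
    m[cbind(match(rownames(tab), years)[row(tab)],
            match(colnames(tab), colnames(m))[col(tab)])] <- tab
    m
  }
  tmp <- tapply(daily$tmean_c, list(y, mo), mean)
  prc <- tapply(daily$precip_mm, list(y, mo), sum)
  list(temperature = month_matrix(shape(tmp), "temperature"),
       precipitation = month_matrix(shape(prc), "precipitation"))
}

#' Linearly detrend a monthly climate matrix
#'
#' Each month label is detrended separately across years (March against
#' Marches, ...) by OLS regression on calendar year; residuals replace the
#' values, removing any secular trend while preserving seasonality. The
#' operation is idempotent.
#'
#' @param m year x month matrix with years as rownames.
#' @return matrix of residuals, same shape and attributes.
#' @export
linear_detrend <- function(m) {
  assert_that(nrow(m) >= 3, "need >= 3 years to detrend")
  yr <- as.numeric(rownames(m))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- is.finite(v)
    if (sum(ok) >= 3) out[ok, j] <- stats::residuals(stats::lm(v[ok] ~ yr[ok]))
  }
  month_matrix(out, attr(m, "variable"), attr(m, "threshold"))
}

#' Build all monthly climate matrices used by the sensitivity stage
#'
#' Temperature, precipitation and the dry-period index at each requested
#' threshold, optionally linearly detrended (the default, applied to all
#' variables).
#'
#' @param daily daily climate table.
#' @param thresholds dry-period thresholds (days).
#' @param wet_cutoff see [find_dry_spells()].
#' @param detrend linearly detrend every matrix.
#' @return named list of matrices: `temperature`, `precipitation`,
#'   `dry_k1`.. Each carries `variable`/`threshold` attributes.
#' @export
build_climate_matrices <- function(daily, thresholds = 1:7, wet_cutoff = 0,
                                   detrend = TRUE) {
  agg <- monthly_aggregate(daily)
  out <- list(temperature = agg$temperature, precipitation = agg$precipitation)
  for (k in thresholds)
    out[[sprintf("dry_k%d", k)]] <- monthly_dry_index(daily, k, wet_cutoff)
  if (detrend) out <- lapply(out, linear_detrend)
  out
}
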