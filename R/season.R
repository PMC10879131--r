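#' Built-in trial monsoon calendar
#'
#' The monsoon windows used in the trial analyses: May 27 to September 27
#' in 2014 and April 1 to September 26 in 2015, derived from elevated
#' precipitation weeks in rainfall matched to the cohort.
#'
#' @return A `season_calendar`: data frame (`year`, `start`, `end`).
#' @export
trial_season_calendar <- function() {
  cal <- data.frame(
    year = c(2014L, 2015L),
    start = as.Date(c("2014-05-27", "2015-04-01")),
    end = as.Date(c("2014-09-27", "2015-09-26"))
  )
  class(cal) <- c("season_calendar", "data.frame")
  cal
}

#' Read a daily rainfall series
#'
#' Validates a (date, mm) table: dates strictly increasing with no gaps
#' within a year, precipitation nonnegative.
#'
#' @param x Data frame with columns `date` (Date or parseable) and `mm`,
#'   or a path to a two-column CSV.
#' @return A validated data frame (`date`, `mm`) of class `rain_series`.
#' @export
rain_series <- function(x) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(x), all(c("date", "mm") %in% names(x)))
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable dates in rainfall series")
  if (any(diff(as.numeric(x$date)) <= 0))
    stop("rainfall dates must be strictly increasing")
  d <- diff(as.numeric(x$date))
  yr <- as.integer(format(x$date, "%Y"))
  if (any(d[yr[-length(yr)] == yr[-1]] != 1))
    stop("rainfall series has gaps within a year")
  if (any(x$mm < 0 | !is.finite(x$mm)))
    stop("precipitation must be finite and nonnegative")
  x <- x[, c("date", "mm")]
  class(x) <- c("rain_series", "data.frame")
  x
}

#' Detect the monsoon window from daily rainfall
#'
#' Computes a trailing (right-aligned) rolling mean of daily precipitation
#' and, within each year, marks the monsoon interval as spanning the
#' first through the last day whose rolling mean is strictly above the
#' threshold.  Years with no exceedance get no interval.
#'
#' @param rain A [rain_series()] (or coercible data frame).
#' @param threshold_mm Rolling-mean exceedance threshold (default 10 mm).
#' @param window_days Rolling window length in days (default 5).
#' @param align `"right"` (trailing, default) or `"center"`.
#' @return A `season_calendar` data frame (`year`, `start`, `end`);
#'   zero rows if no year exceeds the threshold.
#' @export
detect_monsoon_window <- function(rain, threshold_mm = 10, window_days = 5,
                                  align = c("right", "center")) {
  align <- match.arg(align)
  rain <- rain_series(rain)
  if (window_days < 1) stop("`window_days` must be >= 1")
  roll <- zoo::rollapply(rain$mm, window_days, mean,
                         align = align, fill = NA)
  yr <- as.integer(format(rain$date, "%Y"))
  out <- data.frame(year = integer(), start = as.Date(character()),
                    end = as.Date(character()))
  for (y in unique(yr)) {
    idx <- which(yr == y & !is.na(roll) & roll > threshold_mm)
    if (length(idx) == 0) next
    out <- rbind(out, data.frame(year = y,
                                 start = rain$date[min(idx)],
                                 end = rain$date[max(idx)]))
  }
  rownames(out) <- NULL
  class(out) <- c("season_calendar", "data.frame")
  out
}

#' Label dates as monsoon or dry
#'
#' A date is monsoon if and only if it falls inside its year's calendar
#' interval, endpoints inclusive.  Dates in years not covered by the
#' calendar are labelled dry with a warning.
#'
#' @param dates Date vector (or parseable).
#' @param calendar A `season_calendar`; defaults to the trial windows
#'   ([trial_season_calendar()]).
#' @return Character vector, `"monsoon"` or `"dry"`.
#' @export
#' @examples
#' label_season(as.Date(c("2014-06-15", "2014-05-26")))
label_season <- function(dates, calendar = trial_season_calendar()) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  uncov <- setdiff(unique(yr), calendar$year)
  if (length(uncov) > 0)
    warning("calendar does not cover year(s) ",
            paste(uncov, collapse = ", "), "; labelling them dry")
  i <- match(yr, calendar$year)
  mons <- !is.na(i) & dates >= calendar$start[i] & dates <= calendar$end[i]
  ifelse(mons, "monsoon", "dry")
}

#' Heavy-rain indicator with a one-week lag
#'
#' For each query date, returns 1 if at least one of the 7 calendar days
#' ending the day before the date had precipitation strictly above the
#' 80th percentile of all daily totals in the series (percentile computed
#' once over the whole series, R's default inclusive empirical quantile).
#'
#' @param rain A [rain_series()] (or coercible data frame).
#' @param dates Query date(s); each needs at least 7 days of history in
#'   the series.
#' @param percentile Quantile defining "heavy" (default 0.8).
#' @return Integer vector of 0/1.
#' @export
heavy_rain_lag1w <- function(rain, dates, percentile = 0.8) {
  rain <- rain_series(rain)
  dates <- as.Date(dates)
  thr <- quantile(rain$mm, percentile, names = FALSE)
  out <- integer(length(dates))
  for (k in seq_along(dates)) {
    window <- seq(dates[k] - 7, dates[k] - 1, by = "day")
    i <- match(window, rain$date)
    if (anyNA(i))
      stop("insufficient rainfall history before ", format(dates[k]))
    out[k] <- as.integer(any(rain$mm[i] > thr))
  }
  out
}

#' Simulate a daily rainfall series
#'
#' Gamma-distributed daily totals (shape 2) with elevated mean inside a
#' per-year wet window, one value per calendar day; a zero mean gives
#' exact zeros.
#'
#' @param years Integer vector of calendar years to cover.
#' @param wet_window Data frame (`year`, `start`, `end`) giving each
#'   year's wet interval; one row per year at most.
#' @param wet_mean,dry_mean Mean daily precipitation (mm) inside/outside
#'   the wet window; `wet_mean > dry_mean >= 0` required.
#' @param seed Integer seed.
#' @return A [rain_series()] data frame (`date`, `mm`).
#' @export
simulate_rainfall <- function(years, wet_window, wet_mean = 20,
                              dry_mean = 1, seed = 1L) {
  stopifnot(wet_mean >= dry_mean, dry_mean >= 0)
  wet_window$start <- as.Date(wet_window$start)
  wet_window$end <- as.Date(wet_window$end)
  if (any(duplicated(wet_window$year)))
    stop("overlapping wet windows within a year")
  if (any(wet_window$start > wet_window$end))
    stop("wet window start after end")
  set.seed(as.integer(seed))
  out <- NULL
  for (y in sort(unique(as.integer(years)))) {
    days <- seq(as.Date(sprintf("%d-01-01", y)),
                as.Date(sprintf("%d-12-31", y)), by = "day")
    mu <- rep(dry_mean, length(days))
    row <- wet_window[wet_window$year == y, ]
    if (nrow(row) == 1)
      mu[days >= row$start & days <= row$end] <- wet_mean
    mm <- rgamma(length(days), shape = 2, scale = mu / 2)  # scale 0 -> exact 0
    out <- rbind(out, data.frame(date = days, mm = mm))
  }
  rain_series(out)
}
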