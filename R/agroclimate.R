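#' Validate a daily weather table
#'
#' Daily weather is a data.frame with columns `date` (Date or ISO-8601
#' string), `tmin`, `tmax` (degrees C) and `precip` (mm/day). Dates must be
#' strictly increasing; `tmin <= tmax`; `precip >= 0`.
#'
#' @param weather data.frame as above.
#' @return The validated data.frame with `date` coerced to `Date`.
#' @export
daily_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "precip")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather lacks column(s): ", paste(miss, collapse = ", "))
  weather$date <- tryCatch(as.Date(weather$date),
                           error = function(e) rep(as.Date(NA), nrow(weather)))
  if (anyNA(weather$date)) stop("unparseable dates in weather series")
  if (is.unsorted(weather$date, strictly = TRUE))
    stop("weather dates must be strictly increasing")
  if (any(weather$tmin > weather$tmax)) stop("tmin exceeds tmax on some days")
  if (any(weather$precip < 0)) stop("negative precipitation")
  weather
}

#' Extract the weather window for one growing season
#'
#' Returns the `duration_days` consecutive daily records of the half-open
#' window `[planting_date, planting_date + duration_days)`. Any date of the
#' window missing from the series is an error naming the missing dates.
#'
#' @param weather Daily weather table (see [daily_weather()]).
#' @param planting_date Date (or ISO-8601 string).
#' @param duration_days Nonnegative integer window length in days.
#' @return The window as a daily weather data.frame (empty for duration 0).
#' @export
link_weather_window <- function(weather, planting_date, duration_days) {
  weather <- daily_weather(weather)
  planting_date <- as.Date(planting_date)
  if (duration_days < 0) stop("duration_days must be >= 0")
  if (duration_days == 0) return(weather[0L, , drop = FALSE])
  wanted <- planting_date + seq_len(duration_days) - 1L
  pos <- match(wanted, weather$date)
  if (anyNA(pos))
    stop("weather series does not cover: ",
         paste(format(wanted[is.na(pos)]), collapse = ", "))
  weather[pos, , drop = FALSE]
}

check_window <- function(window) {
  if (!nrow(window)) stop("empty weather window")
  window
}

#' Growing degree days
#'
#' \eqn{GDD = \sum_{days} \max(0, (tmax + tmin)/2 - t_{base})}, the simple
#' daily-average formulation with no upper cap by default. Supplying
#' `t_cap` truncates `tmax` at that value before averaging (the capped
#' variant used for heat-limited crops).
#'
#' @param window Non-empty daily weather window.
#' @param t_base Base temperature in degrees C.
#' @param t_cap Optional upper cap on `tmax` in degrees C.
#' @return Accumulated degree-days.
#' @export
growing_degree_days <- function(window, t_base = 10, t_cap = NULL) {
  window <- check_window(window)
  tmax <- if (is.null(t_cap)) window$tmax else pmin(window$tmax, t_cap)
  sum(pmax(0, (tmax + window$tmin) / 2 - t_base))
}

#' Maximum dry spell length
#'
#' Length of the longest run of consecutive days with precipitation below
#' `threshold_mm` (the conventional < 1 mm dry-day definition).
#'
#' @param window Non-empty daily weather window.
#' @param threshold_mm Dry-day threshold in mm/day.
#' @return Integer number of days (0 if every day is wet).
#' @export
max_dry_spell <- function(window, threshold_mm = 1.0) {
  window <- check_window(window)
  dry <- window$precip < threshold_mm
  if (!any(dry)) return(0L)
  runs <- rle(dry)
  max(runs$lengths[runs$values])
}

#' Count of heat-stress days
#'
#' Number of days with `tmax` strictly above `t_crit`.
#'
#' @param window Non-empty daily weather window.
#' @param t_crit Critical temperature in degrees C.
#' @return Integer count.
#' @export
heat_days <- function(window, t_crit = 35) {
  window <- check_window(window)
  sum(window$tmax > t_crit)
}

#' Agro-climatic covariates for a set of packages
#'
#' Computes the three standard indices (growing degree days, maximum dry
#' spell, heat days) over each package's growing window and returns them as
#' a covariate table ready for [fit_pl_tree()]. `planting` maps packages to
#' planting dates; one row per package.
#'
#' @param weather Daily weather table.
#' @param planting data.frame with columns `package_id`, `planting_date`.
#' @param duration_days Window length in days.
#' @param t_base,t_crit,threshold_mm Index parameters.
#' @return data.frame with columns `package_id`, `gdd`, `max_dry_spell`,
#'   `heat_days`.
#' @export
agroclimate_covariates <- function(weather, planting, duration_days,
                                   t_base = 10, t_crit = 35,
                                   threshold_mm = 1.0) {
  need <- c("package_id", "planting_date")
  miss <- setdiff(need, names(planting))
  if (length(miss)) stop("planting lacks column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(planting)), function(i) {
    win <- link_weather_window(weather, planting$planting_date[i], duration_days)
    data.frame(package_id = planting$package_id[i],
               gdd = growing_degree_days(win, t_base = t_base),
               max_dry_spell = max_dry_spell(win, threshold_mm = threshold_mm),
               heat_days = heat_days(win, t_crit = t_crit))
  })
  do.call(rbind, rows)
}
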