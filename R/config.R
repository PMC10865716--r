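#' Enclosure and trial configuration
#'
#' Describes the physical layout of the enclosure (resource zones on a
#' planar grid) and the temporal frame of a trial. The default mirrors a
#' field enclosure with eight weather-protected resource zones arranged in
#' a 2 x 4 grid, monitored for 10 days. All downstream analysis works on a
#' seconds-since-trial-start axis; `trial_start` is only used when parsing
#' absolute timestamps out of raw logs.
#'
#' @param zone_ids Character vector of zone identifiers (>= 2 zones).
#' @param zone_coords Data frame or tibble with columns `zone_id`, `x`, `y`
#'   giving zone positions in meters. Defaults to a 2 x 4 grid with 15 m
#'   spacing.
#' @param trial_start Absolute start time (`POSIXct`), used to convert log
#'   timestamps to trial seconds. Defaults to the Unix epoch.
#' @param trial_days Integer number of observation days (default 10).
#' @param day_boundary_rule Either `"rolling_24h_from_start"` (default;
#'   day d covers `[(d-1)*86400, d*86400)` trial seconds) or
#'   `"calendar_midnight"` (days cut at local midnight of `trial_start`'s
#'   timezone).
#'
#' @return An object of class `enclosure_config`.
#' @examples
#' cfg <- enclosure_config()
#' cfg$zone_ids
#' @export
enclosure_config <- function(zone_ids = paste0("Z", 1:8),
                             zone_coords = NULL,
                             trial_start = as.POSIXct("1970-01-01", tz = "UTC"),
                             trial_days = 10L,
                             day_boundary_rule = c("rolling_24h_from_start",
                                                   "calendar_midnight")) {
  day_boundary_rule <- match.arg(day_boundary_rule)
  zone_ids <- as.character(zone_ids)
  if (length(zone_ids) < 2L) {
    abort("`zone_ids` must contain at least 2 zones.")
  }
  if (anyDuplicated(zone_ids)) {
    abort("`zone_ids` must be unique.")
  }
  trial_days <- as.integer(trial_days)
  if (is.na(trial_days) || trial_days < 1L) {
    abort("`trial_days` must be a positive integer.")
  }
  if (is.null(zone_coords)) {
    n <- length(zone_ids)
    ncol_grid <- ceiling(n / 2)
    zone_coords <- tibble::tibble(
      zone_id = zone_ids,
      x = 15 * ((seq_len(n) - 1) %% ncol_grid),
      y = 15 * ((seq_len(n) - 1) %/% ncol_grid)
    )
  } else {
    zone_coords <- tibble::as_tibble(zone_coords)
    req <- c("zone_id", "x", "y")
    if (!all(req %in% names(zone_coords))) {
      abort("`zone_coords` needs columns zone_id, x, y.")
    }
    zone_coords$zone_id <- as.character(zone_coords$zone_id)
    if (!setequal(zone_coords$zone_id, zone_ids)) {
      abort("`zone_coords` must cover exactly the zones in `zone_ids`.")
    }
    zone_coords <- zone_coords[match(zone_ids, zone_coords$zone_id), req]
  }
  if (!all(is.finite(zone_coords$x)) || !all(is.finite(zone_coords$y))) {
    abort("Zone coordinates must be finite.")
  }
  structure(
    list(
      zone_ids = zone_ids,
      zone_coords = zone_coords,
      trial_start = trial_start,
      trial_days = trial_days,
      day_boundary_rule = day_boundary_rule
    ),
    class = "enclosure_config"
  )
}

#' @export
print.enclosure_config <- function(x, ...) {
  cat("<enclosure_config> ", length(x$zone_ids), " zones, ",
      x$trial_days, " days, day rule: ", x$day_boundary_rule, "\n", sep = "")
  invisible(x)
}

trial_span_seconds <- function(config) {
  config$trial_days * 86400
}

#' Map trial seconds to a 1-based day index
#'
#' Days are half-open: under the rolling rule the instant `t = k * 86400`
#' belongs to day `k + 1`. Every instant in `[0, trial_days * 86400)` maps
#' to exactly one day.
#'
#' @param t Numeric vector of seconds since trial start.
#' @param config An [enclosure_config()].
#' @return Integer vector of day indices in `1:trial_days`.
#' @examples
#' assign_day(c(0, 86399, 86400), enclosure_config())
#' @export
assign_day <- function(t, config = enclosure_config()) {
  span <- trial_span_seconds(config)
  if (any(t < 0 | t >= span, na.rm = TRUE)) {
    abort(sprintf("`t` must lie in [0, %d) trial seconds.", span))
  }
  if (config$day_boundary_rule == "rolling_24h_from_start") {
    return(as.integer(floor(t / 86400)) + 1L)
  }
  # calendar_midnight: boundary offsets measured from trial_start
  start <- config$trial_start
  midnight <- as.POSIXct(format(start, "%Y-%m-%d"),
                         tz = format(start, "%Z") %||% "UTC")
  offset <- as.numeric(difftime(start, midnight, units = "secs"))
  as.integer(floor((t + offset) / 86400)) + 1L
}

#' Remove post-disappearance reads (censoring)
#'
#' Animals that die or disappear mid-trial are censored after their last
#' valid day: their reads on later days are dropped, while the animal stays
#' in the metadata so that daily partner-availability denominators can be
#' computed downstream. Idempotent.
#'
#' @param reads Tibble of reads with columns `mouse_id`, `zone_id`, `t`.
#' @param mice Mouse metadata tibble with `mouse_id` and `last_valid_day`
#'   (`NA` = never censored).
#' @param config An [enclosure_config()].
#' @return The reads tibble with censored rows removed.
#' @export
censor_reads <- function(reads, mice, config = enclosure_config()) {
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) == 0L || !"last_valid_day" %in% names(mice)) {
    return(reads)
  }
  lvd <- setNames(mice$last_valid_day, mice$mouse_id)
  keep_until <- lvd[reads$mouse_id]
  day <- assign_day(reads$t, config)
  keep <- is.na(keep_until) | day <= keep_until
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(sprintf("censor_reads: dropped %d read(s) after last valid day.",
                   dropped))
  }
  reads[keep, , drop = FALSE]
}

#' Which mice are observable (uncensored) on a given day?
#'
#' @param mice Mouse metadata tibble.
#' @param day Integer day index.
#' @return Character vector of mouse ids alive on `day`.
#' @export
mice_alive_on <- function(mice, day) {
  lvd <- mice$last_valid_day %||% rep(NA_integer_, nrow(mice))
  mice$mouse_id[is.na(lvd) | lvd >= day]
}
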