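#' Within-zone inter-read intervals
#'
#' The elapsed time between consecutive detections of the same mouse at
#' the same zone. Pairs of consecutive reads at different zones are zone
#' transitions, not within-zone gaps, and are excluded; so is any pair
#' separated by a read at another zone.
#'
#' @param reads Read tibble (`mouse_id`, `zone_id`, `t`).
#' @return Tibble with `mouse_id`, `zone_id`, `gap` (seconds), one row per
#'   consecutive same-zone read pair.
#' @export
interread_intervals <- function(reads) {
  reads <- dplyr::arrange(tibble::as_tibble(reads), .data$mouse_id, .data$t)
  reads |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(
      gap = .data$t - dplyr::lag(.data$t),
      same_zone = .data$zone_id == dplyr::lag(.data$zone_id)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap), .data$same_zone) |>
    dplyr::select("mouse_id", "zone_id", "gap")
}

#' Estimate the bout gap threshold from inter-read intervals
#'
#' Returns the smallest whole-second value capturing at least a fraction
#' `q` of all within-zone inter-read intervals (the empirical quantile,
#' lower value on ties, ceiling to whole seconds). The packaged default
#' threshold when estimation is skipped is 139 s.
#'
#' @param gaps Numeric vector of gap durations in seconds (or the tibble
#'   from [interread_intervals()], whose `gap` column is used).
#' @param q Coverage fraction, default 0.99.
#' @return Threshold in whole seconds.
#' @examples
#' estimate_threshold(c(rep(5, 99), 500))
#' @export
estimate_threshold <- function(gaps, q = 0.99) {
  if (is.data.frame(gaps)) gaps <- gaps$gap
  if (length(gaps) == 0L) {
    abort(paste("No gaps supplied; cannot estimate a threshold.",
                "Use the packaged default of 139 s instead."))
  }
  g <- sort(gaps)
  idx <- max(1L, ceiling(q * length(g)))
  as.numeric(ceiling(g[idx]))
}

#' Default gap threshold (seconds) for grouping reads into visit bouts
#' @export
DEFAULT_GAP_THRESHOLD <- 139

#' Group reads into zone visit bouts
#'
#' A read extends the mouse's open bout when it is at the same zone and
#' within `threshold` seconds (inclusive) of the previous read; a read at
#' a different zone closes the open bout at its last read time and starts
#' a new one. A closed bout containing a single isolated read is assigned
#' a nominal duration of 1 s; multi-read bouts span first to last read.
#'
#' @param reads Read tibble (`mouse_id`, `zone_id`, `t`).
#' @param threshold Gap threshold in seconds (default 139).
#' @param config An [enclosure_config()]; sets the day of each bout
#'   (the day of its first read; bouts spanning a day boundary are not
#'   split).
#' @return Tibble of bouts: `mouse_id`, `zone_id`, `t_start`, `t_end`,
#'   `duration`, `n_reads`, `day`.
#' @examples
#' reads <- tibble::tibble(mouse_id = "a", zone_id = "Z1", t = c(0, 100, 200))
#' group_bouts(reads)
#' @export
group_bouts <- function(reads, threshold = DEFAULT_GAP_THRESHOLD,
                        config = enclosure_config()) {
  reads <- dplyr::arrange(tibble::as_tibble(reads), .data$mouse_id, .data$t)
  if (nrow(reads) == 0L) {
    return(tibble::tibble(mouse_id = character(), zone_id = character(),
                          t_start = numeric(), t_end = numeric(),
                          duration = numeric(), n_reads = integer(),
                          day = integer()))
  }
  bouts <- reads |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(
      new_bout = dplyr::row_number() == 1L |
        .data$zone_id != dplyr::lag(.data$zone_id) |
        .data$t - dplyr::lag(.data$t) > .env$threshold
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(bout_id = cumsum(.data$new_bout)) |>
    dplyr::group_by(.data$bout_id) |>
    dplyr::summarise(
      mouse_id = dplyr::first(.data$mouse_id),
      zone_id = dplyr::first(.data$zone_id),
      t_start = min(.data$t),
      t_end = max(.data$t),
      n_reads = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      duration = ifelse(.data$n_reads == 1L, 1, .data$t_end - .data$t_start),
      day = assign_day(.data$t_start, config)
    ) |>
    dplyr::select("mouse_id", "zone_id", "t_start", "t_end", "duration",
                  "n_reads", "day") |>
    dplyr::arrange(.data$mouse_id, .data$t_start)
  bouts
}

# The half-open interval a bout occupies for time accounting:
# [t_start, t_start + duration). For multi-read bouts this is exactly
# [t_start, t_end); isolated reads contribute their nominal 1 s so that
# total accounted time equals total bout duration.
bout_occupancy_interval <- function(bouts) {
  dplyr::mutate(bouts, occ_start = .data$t_start,
                occ_end = .data$t_start + .data$duration)
}

#' Daily zone monopolization by the most-present animal
#'
#' For each zone-day, the fraction of all reads sourced by animals of one
#' sex that belong to the single most-detected animal of that sex. Values
#' near 1 indicate exclusive use. Zone-days without reads from that sex
#' are omitted rather than reported as zero.
#'
#' @param reads Read tibble.
#' @param mice Metadata tibble with `mouse_id`, `sex`.
#' @param sex Which sex to evaluate ("M" or "F").
#' @param config An [enclosure_config()].
#' @return Tibble: `day`, `zone_id`, `top_mouse`, `top_fraction`,
#'   `n_reads`.
#' @export
zone_monopolization <- function(reads, mice, sex = "M",
                                config = enclosure_config()) {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  counts <- reads |>
    tibble::as_tibble() |>
    dplyr::filter(sex_of[.data$mouse_id] == .env$sex) |>
    dplyr::mutate(day = assign_day(.data$t, config)) |>
    dplyr::count(.data$day, .data$zone_id, .data$mouse_id)
  if (nrow(counts) == 0L) {
    return(tibble::tibble(day = integer(), zone_id = character(),
                          top_mouse = character(), top_fraction = numeric(),
                          n_reads = integer()))
  }
  counts |>
    dplyr::group_by(.data$day, .data$zone_id) |>
    dplyr::summarise(
      top_mouse = .data$mouse_id[which.max(.data$n)],
      top_fraction = max(.data$n) / sum(.data$n),
      n_reads = sum(.data$n),
      .groups = "drop"
    )
}

#' Minimum distance traveled per mouse per day
#'
#' Lower bound on movement: the sum of straight-line distances between
#' zones over consecutive reads at different zones, using the configured
#' zone coordinates. Consecutive reads at the same zone contribute zero.
#' Each transition is credited to the day of the arriving read.
#'
#' @param reads Read tibble.
#' @param config An [enclosure_config()] with zone coordinates.
#' @return Tibble: `mouse_id`, `day`, `distance_m`.
#' @export
min_distance_traveled <- function(reads, config = enclosure_config()) {
  xs <- setNames(config$zone_coords$x, config$zone_coords$zone_id)
  ys <- setNames(config$zone_coords$y, config$zone_coords$zone_id)
  reads |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$mouse_id, .data$t) |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(prev_zone = dplyr::lag(.data$zone_id)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_zone), .data$zone_id != .data$prev_zone) |>
    dplyr::mutate(
      day = assign_day(.data$t, config),
      step = sqrt((xs[.data$zone_id] - xs[.data$prev_zone])^2 +
                    (ys[.data$zone_id] - ys[.data$prev_zone])^2)
    ) |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(distance_m = sum(.data$step), .groups = "drop")
}

#' Daily and cumulative zone-use summaries
#'
#' Per mouse per day: the number of distinct zones visited, the cumulative
#' number of distinct zones visited since day 1, and the share of the
#' mouse's cumulative bout time spent in its most-occupied zone. Days
#' without bouts yield a count of zero and carry the cumulative values
#' forward.
#'
#' @param bouts Bout tibble from [group_bouts()].
#' @param config An [enclosure_config()] (sets the day range 1..trial_days).
#' @return Tibble: `mouse_id`, `day`, `n_zones`, `cum_zones`,
#'   `top_zone_share`.
#' @export
daily_zone_counts <- function(bouts, config = enclosure_config()) {
  days <- seq_len(config$trial_days)
  per_mouse <- function(b) {
    zones_by_day <- purrr::map(days, function(d) unique(b$zone_id[b$day == d]))
    cum_sets <- purrr::accumulate(zones_by_day, union)
    top_share <- purrr::map_dbl(days, function(d) {
      bb <- b[b$day <= d, ]
      if (nrow(bb) == 0L) return(NA_real_)
      tot <- tapply(bb$duration, bb$zone_id, sum)
      max(tot) / sum(tot)
    })
    tibble::tibble(
      day = as.integer(days),
      n_zones = lengths(zones_by_day),
      cum_zones = lengths(cum_sets),
      top_zone_share = top_share
    )
  }
  bouts |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::group_modify(~ per_mouse(.x)) |>
    dplyr::ungroup()
}
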