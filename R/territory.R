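#' Daily same-sex zone occupancy fractions
#'
#' For each (day, zone), the fraction of all same-sex bout time at that
#' zone contributed by each mouse. Fractions over one zone-day sum to 1
#' when any same-sex mouse used the zone, and no rows are emitted for
#' unused zone-days (occupancy 0 for everyone).
#'
#' @param bouts Bout tibble from [group_bouts()].
#' @param mice Metadata tibble with `mouse_id`, `sex`.
#' @param sex Sex whose competition is scored ("M" or "F"); the score is
#'   sex-generic and computed within-sex.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `zone_id`, `time_s`, `occupancy`.
#' @export
zone_occupancy <- function(bouts, mice, sex = "M",
                           config = enclosure_config()) {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  bouts |>
    tibble::as_tibble() |>
    dplyr::filter(sex_of[.data$mouse_id] == .env$sex) |>
    dplyr::group_by(.data$mouse_id, .data$day, .data$zone_id) |>
    dplyr::summarise(time_s = sum(.data$duration), .groups = "drop") |>
    dplyr::group_by(.data$day, .data$zone_id) |>
    dplyr::mutate(occupancy = .data$time_s / sum(.data$time_s)) |>
    dplyr::ungroup()
}

#' Daily capture scores
#'
#' A mouse's capture score on a day is the sum of its occupancy fractions
#' over all zones, penalized by subtracting 1 when it holds a majority
#' (occupancy strictly greater than 0.5) in no zone — i.e. it captured no
#' zone that day. A mouse with no recorded bout time on a day it was
#' observable scores -1 (all-zero occupancy plus the penalty); censored
#' days contribute 0 and are flagged.
#'
#' @param occupancy Tibble from [zone_occupancy()].
#' @param mice Metadata tibble (supplies the same-sex competitor set and
#'   censoring); only mice of `sex` are scored.
#' @param sex Sex being scored.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `capture_score`, `censored`.
#' @export
capture_scores <- function(occupancy, mice, sex = "M",
                           config = enclosure_config()) {
  ids <- mice$mouse_id[mice$sex == sex]
  lvd <- setNames(mice$last_valid_day %||% rep(NA_integer_, nrow(mice)),
                  mice$mouse_id)
  grid <- tidyr::expand_grid(mouse_id = ids,
                             day = seq_len(config$trial_days))
  daily <- occupancy |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(total_occ = sum(.data$occupancy),
                     captured = any(.data$occupancy > 0.5),
                     .groups = "drop")
  grid |>
    dplyr::left_join(daily, by = c("mouse_id", "day")) |>
    dplyr::mutate(
      total_occ = tidyr::replace_na(.data$total_occ, 0),
      captured = tidyr::replace_na(.data$captured, FALSE),
      censored = !is.na(lvd[.data$mouse_id]) &
        .data$day > lvd[.data$mouse_id],
      capture_score = dplyr::if_else(
        .data$censored, 0,
        .data$total_occ - dplyr::if_else(.data$captured, 0, 1))
    ) |>
    dplyr::select("mouse_id", "day", "capture_score", "censored") |>
    dplyr::arrange(.data$mouse_id, .data$day)
}

#' Priority access score series
#'
#' The cumulative sum of daily capture scores, day by day. The day-final
#' value classifies each mouse as territorial (strictly positive) or
#' non-territorial. Values well above the number of trial days indicate
#' monopolization of more than one zone.
#'
#' @param capture Tibble from [capture_scores()] (or any tibble with
#'   `mouse_id`, `day`, `capture_score`).
#' @return A tibble of class `rfid_pas`: `mouse_id`, `day`,
#'   `capture_score`, `pas`, plus attributes consumed by [glance()] and
#'   [autoplot()].
#' @export
priority_access <- function(capture) {
  out <- capture |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$mouse_id, .data$day) |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(pas = cumsum(.data$capture_score)) |>
    dplyr::ungroup()
  class(out) <- c("rfid_pas", class(out))
  out
}

#' End-to-end priority access scoring from bouts
#'
#' Convenience wrapper: [zone_occupancy()] then [capture_scores()] then
#' [priority_access()].
#'
#' @inheritParams zone_occupancy
#' @return An `rfid_pas` tibble.
#' @export
priority_access_scores <- function(bouts, mice, sex = "M",
                                   config = enclosure_config()) {
  zone_occupancy(bouts, mice, sex, config) |>
    capture_scores(mice, sex, config) |>
    priority_access()
}

#' @method glance rfid_pas
#' @export
glance.rfid_pas <- function(x, ...) {
  x |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(final_day = max(.data$day),
                     final_pas = .data$pas[which.max(.data$day)],
                     .groups = "drop") |>
    dplyr::mutate(status = dplyr::if_else(.data$final_pas > 0,
                                          "territorial", "non_territorial"))
}

#' @method tidy rfid_pas
#' @export
tidy.rfid_pas <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Territory holder of a zone at a time point
#'
#' The male holding strictly more than 50% of all male-sourced reads at
#' the zone over the rolling 24 h window ending at `t` (half-open,
#' `[max(0, t - 86400), t)`), or `NA` if no male does or the window holds
#' no male reads.
#'
#' @param reads Read tibble.
#' @param mice Metadata tibble.
#' @param zone Zone id.
#' @param t Time point (trial seconds).
#' @param sex Sex defining both candidate holders and the read
#'   denominator (default "M").
#' @return A mouse id or `NA_character_`.
#' @export
territory_holder <- function(reads, mice, zone, t, sex = "M") {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  win <- reads[reads$zone_id == zone &
                 sex_of[reads$mouse_id] == sex &
                 reads$t >= max(0, t - 86400) & reads$t < t, ]
  if (nrow(win) == 0L) return(NA_character_)
  counts <- table(win$mouse_id)
  if (max(counts) / sum(counts) > 0.5) names(counts)[which.max(counts)]
  else NA_character_
}

# Batch holder lookup: for many (zone, t) queries, count male reads per
# candidate via findInterval on pre-sorted per-(zone, mouse) read times.
holder_batch <- function(reads, mice, zones, ts, sex = "M") {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  male_reads <- reads[sex_of[reads$mouse_id] == sex, ]
  by_zone <- split(male_reads[c("mouse_id", "t")], male_reads$zone_id)
  times <- lapply(by_zone, function(df) {
    lapply(split(df$t, df$mouse_id), sort)
  })
  vapply(seq_along(zones), function(i) {
    tz <- times[[zones[i]]]
    if (is.null(tz)) return(NA_character_)
    lo <- max(0, ts[i] - 86400)
    counts <- vapply(tz, function(tt) {
      findInterval(ts[i] - 1e-9, tt) - findInterval(lo - 1e-9, tt)
    }, integer(1))
    tot <- sum(counts)
    if (tot > 0 && max(counts) / tot > 0.5) names(counts)[which.max(counts)]
    else NA_character_
  }, character(1))
}

#' Infer dyadic displacement contests
#'
#' Scans each zone's male occupancy for episodes in which a single male is
#' joined by exactly one other male and one of the two then leaves: the
#' leaver is the loser, the male remaining is the winner. Episodes that
#' reach three or more males, begin with a simultaneous arrival, or end
#' with a simultaneous departure (a tie) are excluded. Each participant's
#' context is `home` when he is the zone's territory holder at the moment
#' co-occupancy begins, `away` when another male is, and `neutral` when
#' the zone has no holder yet.
#'
#' @param bouts Bout tibble (all sexes; males are selected internally).
#' @param reads Read tibble (used for the rolling 24 h holder rule).
#' @param mice Metadata tibble.
#' @param config An [enclosure_config()].
#' @param min_co_duration Minimum co-occupancy seconds for an episode to
#'   count as a contest (default 0: any strictly positive overlap).
#' @return Tibble: `t`, `zone_id`, `day`, `present_first`, `joining`,
#'   `winner`, `loser`, `co_duration`, `holder`, `winner_context`,
#'   `loser_context`.
#' @export
detect_contests <- function(bouts, reads, mice,
                            config = enclosure_config(),
                            min_co_duration = 0) {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  male_bouts <- bouts[sex_of[bouts$mouse_id] == "M", , drop = FALSE]
  empty <- tibble::tibble(t = numeric(), zone_id = character(),
                          day = integer(), present_first = character(),
                          joining = character(), winner = character(),
                          loser = character(), co_duration = numeric(),
                          holder = character(), winner_context = character(),
                          loser_context = character())
  segs <- occupancy_segments(male_bouts)
  if (nrow(segs) == 0L) return(empty)

  scan_zone <- function(s) {
    s <- s[order(s$t_start), ]
    n <- nrow(s)
    out <- list()
    i <- 1L
    while (i <= n) {
      if (s$n_mice[i] >= 2L) {
        # collect the co-occupancy episode: consecutive n >= 2 segments
        # of the same run
        j <- i
        while (j < n && s$n_mice[j + 1L] >= 2L && s$run[j + 1L] == s$run[j]) {
          j <- j + 1L
        }
        members <- unique(unlist(s$members[i:j]))
        peak <- max(s$n_mice[i:j])
        prev_ok <- i > 1L && s$run[i - 1L] == s$run[i] && s$n_mice[i - 1L] == 1L
        next_ok <- j < n && s$run[j + 1L] == s$run[j] && s$n_mice[j + 1L] == 1L
        co_dur <- s$t_end[j] - s$t_start[i]
        if (peak == 2L && length(members) == 2L && prev_ok && next_ok &&
            co_dur > min_co_duration) {
          first_male <- s$members[[i - 1L]]
          remaining <- s$members[[j + 1L]]
          out[[length(out) + 1L]] <- tibble::tibble(
            t = s$t_start[i],
            present_first = first_male,
            joining = setdiff(members, first_male),
            winner = remaining,
            loser = setdiff(members, remaining),
            co_duration = co_dur
          )
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
    dplyr::bind_rows(out)
  }

  contests <- segs |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::group_modify(~ scan_zone(.x)) |>
    dplyr::ungroup()
  if (nrow(contests) == 0L) return(empty)

  contests$holder <- holder_batch(reads, mice, contests$zone_id, contests$t)
  ctx <- function(male, holder) {
    dplyr::case_when(is.na(holder) ~ "neutral",
                     male == holder ~ "home",
                     TRUE ~ "away")
  }
  contests |>
    dplyr::mutate(
      day = assign_day(.data$t, config),
      winner_context = ctx(.data$winner, .data$holder),
      loser_context = ctx(.data$loser, .data$holder)
    ) |>
    dplyr::select("t", "zone_id", "day", "present_first", "joining",
                  "winner", "loser", "co_duration", "holder",
                  "winner_context", "loser_context") |>
    dplyr::arrange(.data$t)
}

#' Per-male win rates at home and away
#'
#' Win rate within each context (home = the male is the zone's territory
#' holder at contest start; away = another male is). Neutral-context
#' participations (no holder yet) are tallied but excluded from the
#' home/away rates. Males observed in both contexts are flagged, mirroring
#' the analysis set for home-advantage comparisons.
#'
#' @param contests Tibble from [detect_contests()].
#' @return Tibble: `mouse_id`, `n_home`, `home_wins`, `home_win_rate`,
#'   `n_away`, `away_wins`, `away_win_rate`, `n_neutral`,
#'   `both_contexts`.
#' @export
home_away_win_rates <- function(contests) {
  long <- dplyr::bind_rows(
    dplyr::transmute(contests, mouse_id = .data$winner,
                     context = .data$winner_context, won = TRUE),
    dplyr::transmute(contests, mouse_id = .data$loser,
                     context = .data$loser_context, won = FALSE)
  )
  rate <- function(w) if (length(w) == 0L) NA_real_ else mean(w)
  long |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(
      n_home = sum(.data$context == "home"),
      home_wins = sum(.data$won & .data$context == "home"),
      home_win_rate = rate(.data$won[.data$context == "home"]),
      n_away = sum(.data$context == "away"),
      away_wins = sum(.data$won & .data$context == "away"),
      away_win_rate = rate(.data$won[.data$context == "away"]),
      n_neutral = sum(.data$context == "neutral"),
      .groups = "drop"
    ) |>
    dplyr::mutate(both_contexts = .data$n_home > 0 & .data$n_away > 0)
}

#' Observed versus null territorial/intruder spatiotemporal overlap
#'
#' Over a late-trial window (default the last six days, when territories
#' are established), compares the observed co-occupancy hours between
#' territorial and intruder (non-territorial) males with the null
#' expectation `(H * I) / (24 * n_days * n_zones)` where `H` and `I` are
#' the total territorial-male and intruder-male zone hours. Negative
#' percent deviations indicate spatiotemporal avoidance.
#'
#' @param bouts Bout tibble.
#' @param mice Metadata tibble.
#' @param territorial Character vector of territorial male ids (e.g. males
#'   with final priority access score > 0).
#' @param config An [enclosure_config()].
#' @param days Integer vector of day indices for the window; default the
#'   last six trial days.
#' @return One-row tibble: `holder_hours`, `intruder_hours`,
#'   `observed_hours`, `expected_hours`, `pct_deviation`.
#' @export
overlap_null_deviation <- function(bouts, mice, territorial,
                                   config = enclosure_config(),
                                   days = NULL) {
  if (is.null(days)) {
    days <- seq(max(1L, config$trial_days - 5L), config$trial_days)
  }
  sex_of <- setNames(mice$sex, mice$mouse_id)
  males <- mice$mouse_id[mice$sex == "M"]
  intruders <- setdiff(males, territorial)
  b <- bouts[bouts$day %in% days & sex_of[bouts$mouse_id] == "M", ]
  hours_of <- function(ids) sum(b$duration[b$mouse_id %in% ids]) / 3600
  H <- hours_of(territorial)
  I <- hours_of(intruders)
  dy <- dyad_overlaps(b, config)
  cross <- (dy$mouse_a %in% territorial & dy$mouse_b %in% intruders) |
    (dy$mouse_b %in% territorial & dy$mouse_a %in% intruders)
  observed <- sum(dy$duration[cross]) / 3600
  expected <- (H * I) / (24 * length(days) * length(config$zone_ids))
  tibble::tibble(
    holder_hours = H, intruder_hours = I,
    observed_hours = observed, expected_hours = expected,
    pct_deviation = if (expected > 0) 100 * (observed - expected) / expected
                    else NA_real_
  )
}
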