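#' Partition zone time into segments of constant occupancy
#'
#' The workhorse behind all co-occupancy accounting. Each bout occupies
#' the half-open interval `[t_start, t_start + duration)`; per zone, time
#' is cut at every interval endpoint into elementary segments during which
#' the set of present mice is constant. Contiguous stretches of non-empty
#' occupancy form "runs": maximal chains of temporally overlapping bouts
#' (two bouts that merely touch end-to-start are in different runs).
#'
#' @param bouts Bout tibble from [group_bouts()].
#' @return Tibble: `zone_id`, `run` (chain index within zone), `t_start`,
#'   `t_end`, `n_mice`, `members` (list column of mouse ids).
#' @export
occupancy_segments <- function(bouts) {
  bouts <- bout_occupancy_interval(tibble::as_tibble(bouts))
  bouts <- bouts[bouts$occ_end > bouts$occ_start, , drop = FALSE]
  empty <- tibble::tibble(zone_id = character(), run = integer(),
                          t_start = numeric(), t_end = numeric(),
                          n_mice = integer(), members = list())
  if (nrow(bouts) == 0L) return(empty)

  sweep_zone <- function(b, zone) {
    n <- nrow(b)
    mice <- unique(b$mouse_id)
    midx <- match(b$mouse_id, mice)
    ev_t <- c(b$occ_start, b$occ_end)
    ev_delta <- rep(c(1L, -1L), each = n)
    ev_mouse <- c(midx, midx)
    ord <- order(ev_t, ev_delta)  # ends (-1) before starts (+1) at ties
    ev_t <- ev_t[ord]; ev_delta <- ev_delta[ord]; ev_mouse <- ev_mouse[ord]

    active <- integer(length(mice))
    total <- 0L
    run <- 0L
    in_run <- FALSE
    m <- length(ev_t)
    seg_start <- numeric(m); seg_end <- numeric(m)
    seg_run <- integer(m); seg_n <- integer(m)
    seg_members <- vector("list", m)
    k <- 0L
    for (i in seq_len(m)) {
      mi <- ev_mouse[i]
      active[mi] <- active[mi] + ev_delta[i]
      total <- total + ev_delta[i]
      if (total == 0L) {
        in_run <- FALSE
      } else if (!in_run) {
        run <- run + 1L
        in_run <- TRUE
      }
      if (i < m && total > 0L && ev_t[i + 1L] > ev_t[i]) {
        k <- k + 1L
        seg_start[k] <- ev_t[i]
        seg_end[k] <- ev_t[i + 1L]
        seg_run[k] <- run
        present <- which(active > 0L)
        seg_n[k] <- length(present)
        seg_members[[k]] <- mice[present]
      }
    }
    if (k == 0L) return(NULL)
    tibble::tibble(zone_id = zone, run = seg_run[seq_len(k)],
                   t_start = seg_start[seq_len(k)],
                   t_end = seg_end[seq_len(k)],
                   n_mice = seg_n[seq_len(k)],
                   members = seg_members[seq_len(k)])
  }

  out <- bouts |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::group_map(~ sweep_zone(.x, .y$zone_id))
  out <- dplyr::bind_rows(purrr::compact(out))
  if (nrow(out) == 0L) empty else out
}

#' Dyadic spatiotemporal overlaps
#'
#' Every maximal non-empty intersection of a visit bout of one mouse with
#' a visit bout of another at the same zone (half-open intervals; touching
#' endpoints are not overlaps).
#'
#' @param bouts Bout tibble.
#' @param config An [enclosure_config()] used to date each overlap by its
#'   start.
#' @return Tibble: `mouse_a`, `mouse_b` (sorted within pair), `zone_id`,
#'   `t_start`, `t_end`, `duration`, `day`.
#' @export
dyad_overlaps <- function(bouts, config = enclosure_config()) {
  segs <- occupancy_segments(bouts)
  empty <- tibble::tibble(mouse_a = character(), mouse_b = character(),
                          zone_id = character(), t_start = numeric(),
                          t_end = numeric(), duration = numeric(),
                          day = integer())
  segs <- segs[segs$n_mice >= 2L, , drop = FALSE]
  if (nrow(segs) == 0L) return(empty)
  pair_rows <- purrr::pmap(
    list(segs$zone_id, segs$run, segs$t_start, segs$t_end, segs$members),
    function(zone, run, t0, t1, mem) {
      mem <- sort(mem)
      pr <- utils::combn(mem, 2)
      tibble::tibble(mouse_a = pr[1, ], mouse_b = pr[2, ], zone_id = zone,
                     run = run, t_start = t0, t_end = t1)
    }
  )
  dplyr::bind_rows(pair_rows) |>
    dplyr::arrange(.data$mouse_a, .data$mouse_b, .data$zone_id,
                   .data$t_start) |>
    dplyr::group_by(.data$mouse_a, .data$mouse_b, .data$zone_id) |>
    dplyr::mutate(
      new_block = dplyr::row_number() == 1L |
        .data$t_start > dplyr::lag(.data$t_end)
    ) |>
    dplyr::mutate(block = cumsum(.data$new_block)) |>
    dplyr::group_by(.data$mouse_a, .data$mouse_b, .data$zone_id,
                    .data$block) |>
    dplyr::summarise(t_start = min(.data$t_start), t_end = max(.data$t_end),
                     .groups = "drop") |>
    dplyr::mutate(duration = .data$t_end - .data$t_start,
                  day = assign_day(.data$t_start, config)) |>
    dplyr::select(-"block") |>
    dplyr::arrange(.data$zone_id, .data$t_start)
}

#' Spatiotemporal association events
#'
#' Chains of temporally overlapping visit bouts at one zone. Each
#' connected component of the per-zone bout-overlap graph involving at
#' least two distinct mice becomes one event spanning the component's
#' full coverage, with each participating mouse counted once.
#'
#' @param bouts Bout tibble.
#' @param config An [enclosure_config()].
#' @return Tibble: `zone_id`, `t_start`, `t_end`, `members` (list column),
#'   `n_members`, `day` (day of event start).
#' @export
association_events <- function(bouts, config = enclosure_config()) {
  segs <- occupancy_segments(bouts)
  empty <- tibble::tibble(zone_id = character(), t_start = numeric(),
                          t_end = numeric(), members = list(),
                          n_members = integer(), day = integer())
  if (nrow(segs) == 0L) return(empty)
  segs |>
    dplyr::group_by(.data$zone_id, .data$run) |>
    dplyr::summarise(
      t_start = min(.data$t_start),
      t_end = max(.data$t_end),
      members = list(sort(unique(unlist(.data$members)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_members = lengths(.data$members)) |>
    dplyr::filter(.data$n_members >= 2L) |>
    dplyr::mutate(day = assign_day(.data$t_start, config)) |>
    dplyr::select("zone_id", "t_start", "t_end", "members", "n_members",
                  "day") |>
    dplyr::arrange(.data$zone_id, .data$t_start)
}

# Per-mouse segment membership with sex composition: one row per
# (segment, member), carrying the segment's male/female counts.
segment_membership <- function(bouts, mice, config = enclosure_config()) {
  segs <- occupancy_segments(bouts)
  if (nrow(segs) == 0L) {
    return(tibble::tibble(zone_id = character(), t_start = numeric(),
                          t_end = numeric(), n_mice = integer(),
                          mouse_id = character(), n_males = integer(),
                          n_females = integer(), day = integer(),
                          length_s = numeric()))
  }
  sex_of <- setNames(mice$sex, mice$mouse_id)
  segs$n_males <- purrr::map_int(segs$members,
                                 ~ sum(sex_of[.x] == "M", na.rm = TRUE))
  segs$n_females <- segs$n_mice - segs$n_males
  segs$day <- assign_day(segs$t_start, config)
  segs$length_s <- segs$t_end - segs$t_start
  tidyr::unnest(segs, "members") |>
    dplyr::rename(mouse_id = "members") |>
    dplyr::select("zone_id", "t_start", "t_end", "n_mice", "mouse_id",
                  "n_males", "n_females", "day", "length_s")
}

#' Mouse-hours by group sex composition
#'
#' Time is partitioned into segments of constant occupancy; a segment of
#' length L containing m males and f females contributes `(m + f) * L`
#' mouse-time to the composition cell `(m, f)` — each co-present mouse's
#' time counts separately, so two mice together for 60 min are two
#' mouse-hours. Cells `(1, 0)` and `(0, 1)` are solitary time.
#'
#' @param bouts Bout tibble.
#' @param mice Metadata tibble with `mouse_id`, `sex`.
#' @param config An [enclosure_config()].
#' @return Tibble: `day`, `n_males`, `n_females`, `mouse_hours`.
#' @export
group_composition_hours <- function(bouts, mice,
                                    config = enclosure_config()) {
  segs <- occupancy_segments(bouts)
  if (nrow(segs) == 0L) {
    return(tibble::tibble(day = integer(), n_males = integer(),
                          n_females = integer(), mouse_hours = numeric()))
  }
  sex_of <- setNames(mice$sex, mice$mouse_id)
  segs |>
    dplyr::mutate(
      n_males = purrr::map_int(.data$members,
                               ~ sum(sex_of[.x] == "M", na.rm = TRUE)),
      n_females = .data$n_mice - .data$n_males,
      day = assign_day(.data$t_start, config),
      mouse_time = .data$n_mice * (.data$t_end - .data$t_start)
    ) |>
    dplyr::group_by(.data$day, .data$n_males, .data$n_females) |>
    dplyr::summarise(mouse_hours = sum(.data$mouse_time) / 3600,
                     .groups = "drop")
}

#' Fraction of recorded time spent alone
#'
#' A mouse's alone time is its total bout time minus the time it spends
#' in segments shared with at least one other mouse. Mice with no bout
#' time on a day have no row for that day (undefined, not zero).
#'
#' @param bouts Bout tibble.
#' @param mice Metadata tibble.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `alone_s`, `total_s`,
#'   `alone_fraction`; plus one `day = NA` row per mouse with the
#'   whole-trial totals.
#' @export
time_alone <- function(bouts, mice, config = enclosure_config()) {
  mem <- segment_membership(bouts, mice, config)
  if (nrow(mem) == 0L) {
    return(tibble::tibble(mouse_id = character(), day = integer(),
                          alone_s = numeric(), total_s = numeric(),
                          alone_fraction = numeric()))
  }
  daily <- mem |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(
      alone_s = sum(.data$length_s[.data$n_mice == 1L]),
      total_s = sum(.data$length_s),
      .groups = "drop"
    ) |>
    dplyr::mutate(alone_fraction = .data$alone_s / .data$total_s)
  total <- daily |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(day = NA_integer_, alone_s = sum(.data$alone_s),
                     total_s = sum(.data$total_s), .groups = "drop") |>
    dplyr::mutate(alone_fraction = .data$alone_s / .data$total_s)
  dplyr::bind_rows(daily, total) |>
    dplyr::arrange(.data$mouse_id, .data$day)
}

#' Same-sex versus opposite-sex association time
#'
#' For each mouse and day, its association time (time in segments with two
#' or more mice) is split focal-relatively: a segment counts as
#' opposite-sex when at least one member of the other sex is present, and
#' same-sex when every other member shares the focal mouse's sex. Shares
#' sum to one per mouse-day; mouse-days with no association time are
#' absent.
#'
#' @param bouts Bout tibble.
#' @param mice Metadata tibble.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `assoc_s`, `same_sex_share`,
#'   `opposite_sex_share`.
#' @export
sex_association_fractions <- function(bouts, mice,
                                      config = enclosure_config()) {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  mem <- segment_membership(bouts, mice, config) |>
    dplyr::filter(.data$n_mice >= 2L)
  if (nrow(mem) == 0L) {
    return(tibble::tibble(mouse_id = character(), day = integer(),
                          assoc_s = numeric(), same_sex_share = numeric(),
                          opposite_sex_share = numeric()))
  }
  mem |>
    dplyr::mutate(
      n_other_sex = ifelse(sex_of[.data$mouse_id] == "M",
                           .data$n_females, .data$n_males),
      opposite = .data$n_other_sex >= 1L
    ) |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(
      assoc_s = sum(.data$length_s),
      opposite_sex_share = sum(.data$length_s[.data$opposite]) /
        sum(.data$length_s),
      .groups = "drop"
    ) |>
    dplyr::mutate(same_sex_share = 1 - .data$opposite_sex_share) |>
    dplyr::select("mouse_id", "day", "assoc_s", "same_sex_share",
                  "opposite_sex_share")
}

#' Daily cage-mate association preference versus a partner-count null
#'
#' For each female and day: the observed share of her female-female
#' overlap time spent with cage mates (siblings), the null share expected
#' if partners were interchangeable — the number of her available
#' (uncensored) cage mates over the number of available female partners,
#' both excluding herself — and the percent deviation
#' `100 * (observed - null) / null`. Female-days with no female-female
#' overlap time are omitted; a null of zero (no living cage mates) leaves
#' the deviation `NA`.
#'
#' @param dyads Dyadic overlap tibble from [dyad_overlaps()].
#' @param mice Metadata tibble with `sex`, `cage_id`, `last_valid_day`.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `ff_time_s`, `observed_share`,
#'   `null_share`, `pct_deviation`.
#' @export
cagemate_preference <- function(dyads, mice, config = enclosure_config()) {
  sex_of <- setNames(mice$sex, mice$mouse_id)
  cage_of <- setNames(mice$cage_id, mice$mouse_id)
  ff <- dyads |>
    dplyr::filter(sex_of[.data$mouse_a] == "F", sex_of[.data$mouse_b] == "F")
  empty <- tibble::tibble(mouse_id = character(), day = integer(),
                          ff_time_s = numeric(), observed_share = numeric(),
                          null_share = numeric(), pct_deviation = numeric())
  if (nrow(ff) == 0L) return(empty)
  focal <- dplyr::bind_rows(
    dplyr::transmute(ff, mouse_id = .data$mouse_a, partner = .data$mouse_b,
                     day = .data$day, duration = .data$duration),
    dplyr::transmute(ff, mouse_id = .data$mouse_b, partner = .data$mouse_a,
                     day = .data$day, duration = .data$duration)
  )
  obs <- focal |>
    dplyr::mutate(is_cagemate = cage_of[.data$partner] ==
                    cage_of[.data$mouse_id]) |>
    dplyr::group_by(.data$mouse_id, .data$day) |>
    dplyr::summarise(
      ff_time_s = sum(.data$duration),
      observed_share = sum(.data$duration[.data$is_cagemate]) /
        sum(.data$duration),
      .groups = "drop"
    )
  females <- mice$mouse_id[mice$sex == "F"]
  null_for <- function(m, d) {
    avail <- intersect(mice_alive_on(mice, d), females)
    avail <- setdiff(avail, m)
    if (length(avail) == 0L) return(NA_real_)
    sum(cage_of[avail] == cage_of[m]) / length(avail)
  }
  obs |>
    dplyr::mutate(
      null_share = purrr::map2_dbl(.data$mouse_id, .data$day, null_for),
      pct_deviation = ifelse(
        is.na(.data$null_share) | .data$null_share == 0, NA_real_,
        100 * (.data$observed_share - .data$null_share) / .data$null_share)
    )
}
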