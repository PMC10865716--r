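# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Behavioral profile for one simulated mouse
#'
#' Parameters of the discrete-choice relocation process that the
#' generator runs per mouse: a mouse alternates between zone visits
#' (log-normal durations) and at-large periods between zones (exponential
#' with a 10 s minimum inter-zone travel time), choosing each next zone by
#' weighted preference.
#'
#' @param p_move_per_min Per-minute probability of ending an at-large
#'   period (so mean at-large time is `1 / p_move_per_min` minutes).
#' @param zone_preference Named non-negative weights over zone ids, or
#'   `NULL` for uniform.
#' @param visit_duration_mean Mean visit duration in minutes (log-normal).
#' @param visit_duration_sdlog Log-scale SD of visit durations.
#' @param read_rate_hz Detections per second while at a zone.
#' @param cagemate_bias Multiplier (>= 1) on the weight of a zone
#'   currently occupied by a cage mate.
#' @param exploration_growth Per-day additive broadening of the zone
#'   preference toward uniform: on day d the uniform distribution receives
#'   extra mass `exploration_growth * (d - 1)` relative to the normalized
#'   base preference.
#' @return A `behavior_profile` list.
#' @export
behavior_profile <- function(p_move_per_min = 0.06,
                             zone_preference = NULL,
                             visit_duration_mean = 1.5,
                             visit_duration_sdlog = 1,
                             read_rate_hz = 2.5,
                             cagemate_bias = 1,
                             exploration_growth = 0) {
  stopifnot(p_move_per_min > 0, p_move_per_min <= 1,
            visit_duration_mean > 0, read_rate_hz > 0,
            cagemate_bias >= 1, exploration_growth >= 0)
  structure(list(
    p_move_per_min = p_move_per_min,
    zone_preference = zone_preference,
    visit_duration_mean = visit_duration_mean,
    visit_duration_sdlog = visit_duration_sdlog,
    read_rate_hz = read_rate_hz,
    cagemate_bias = cagemate_bias,
    exploration_growth = exploration_growth
  ), class = "behavior_profile")
}

#' Create a synthetic cohort
#'
#' Builds mouse metadata for a trial: same-sex sibling cages of
#' `n_per_cage` (the last cage of a sex may be smaller), each cage
#' released at one zone (cages cycle through a seed-shuffled zone order),
#' two PIT tags per mouse.
#'
#' @param n_males,n_females Non-negative counts.
#' @param genotype Genotype label stamped on every mouse.
#' @param n_per_cage Cage (sibling group) size, >= 1.
#' @param seed Integer seed; the same arguments and seed give identical
#'   cohorts.
#' @param config An [enclosure_config()].
#' @return Metadata tibble: `mouse_id`, `tag_code_1`, `tag_code_2`,
#'   `sex`, `genotype`, `cage_id`, `release_zone`, `last_valid_day`.
#' @export
make_cohort <- function(n_males = 10, n_females = 10, genotype = "C57",
                        n_per_cage = 2, seed = 1,
                        config = enclosure_config()) {
  if (n_males < 0 || n_females < 0) abort("Counts must be non-negative.")
  if (n_per_cage < 1) abort("`n_per_cage` must be >= 1.")
  with_seed(seed, {
    zones <- sample(config$zone_ids)
    build_sex <- function(n, sex) {
      if (n == 0L) return(NULL)
      ids <- sprintf("%s%02d", sex, seq_len(n))
      cage_idx <- (seq_len(n) - 1) %/% n_per_cage + 1
      tibble::tibble(
        mouse_id = ids,
        sex = sex,
        cage_id = sprintf("%s-%s-C%d", genotype, sex, cage_idx),
        cage_idx = cage_idx
      )
    }
    mice <- dplyr::bind_rows(build_sex(n_males, "M"),
                             build_sex(n_females, "F"))
    cages <- unique(mice$cage_id)
    zone_of_cage <- setNames(
      zones[(seq_along(cages) - 1) %% length(zones) + 1], cages)
    mice |>
      dplyr::mutate(
        genotype = genotype,
        tag_code_1 = sprintf("T%03dA", dplyr::row_number()),
        tag_code_2 = sprintf("T%03dB", dplyr::row_number()),
        release_zone = unname(zone_of_cage[.data$cage_id]),
        last_valid_day = NA_integer_
      ) |>
      dplyr::select("mouse_id", "tag_code_1", "tag_code_2", "sex",
                    "genotype", "cage_id", "release_zone",
                    "last_valid_day")
  })
}

#' Load a scenario preset
#'
#' Presets bundle per-sex behavior profile parameters and territorial
#' dynamics parameters. `"c57_like"` emulates broadly exploring females
#' with weak cage-mate bias; `"wd_like"` emulates site-faithful females
#' with strong cage-mate bias and lower movement rates. A path to a
#' custom YAML file is also accepted.
#'
#' @param name `"c57_like"`, `"wd_like"`, or a YAML file path.
#' @return Nested list of preset parameters.
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "rfidsoc")
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("Unknown preset '%s'.", name))
  }
  yaml::read_yaml(path)
}

#' Build per-mouse behavior profiles from a preset
#'
#' Each mouse receives its sex's preset parameters; its zone preference
#' puts `release_zone_weight` on the release zone and 1 elsewhere.
#'
#' @param mice Metadata tibble from [make_cohort()].
#' @param config An [enclosure_config()].
#' @param preset Preset name or list from [load_preset()].
#' @return Named list of [behavior_profile()]s, one per mouse.
#' @export
preset_profiles <- function(mice, config = enclosure_config(),
                            preset = "c57_like") {
  if (is.character(preset)) preset <- load_preset(preset)
  prof_for <- function(sex, release) {
    p <- if (sex == "M") preset$male else preset$female
    w <- setNames(rep(1, length(config$zone_ids)), config$zone_ids)
    w[release] <- p$release_zone_weight %||% 1
    behavior_profile(
      p_move_per_min = p$p_move_per_min,
      zone_preference = w,
      visit_duration_mean = p$visit_duration_mean,
      visit_duration_sdlog = p$visit_duration_sdlog %||% 1,
      read_rate_hz = p$read_rate_hz %||% 2.5,
      cagemate_bias = p$cagemate_bias %||% 1,
      exploration_growth = p$exploration_growth %||% 0
    )
  }
  profs <- purrr::map2(mice$sex, mice$release_zone, prof_for)
  setNames(profs, mice$mouse_id)
}

#' Emit a Poisson RFID read stream from presence intervals
#'
#' Each presence interval of duration `d` contributes `Poisson(d * rate)`
#' reads placed uniformly within it, plus one guaranteed read at the
#' interval start so that arbitrarily brief true visits remain detectable
#' (mirroring isolated reads in field data).
#'
#' @param intervals Tibble with `mouse_id`, `zone_id`, `t_start`, `t_end`.
#' @param read_rate_hz Detections per second (scalar or per-interval
#'   vector); must be positive.
#' @param seed Optional integer seed for reproducible streams.
#' @return Read tibble (`mouse_id`, `zone_id`, `t`), time-sorted.
#' @export
emit_reads <- function(intervals, read_rate_hz = 2.5, seed = NULL) {
  if (any(read_rate_hz <= 0)) abort("`read_rate_hz` must be positive.")
  gen <- function() {
    d <- intervals$t_end - intervals$t_start
    n <- rpois(length(d), d * read_rate_hz)
    t_extra <- rep(intervals$t_start, n) + runif(sum(n)) * rep(d, n)
    tibble::tibble(
      mouse_id = c(intervals$mouse_id, rep(intervals$mouse_id, n)),
      zone_id = c(intervals$zone_id, rep(intervals$zone_id, n)),
      t = c(intervals$t_start, t_extra)
    ) |>
      dplyr::arrange(.data$t)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate an RFID trial with known ground truth
#'
#' Runs an event-driven relocation process for every mouse: alternating
#' zone visits (log-normal durations) and at-large periods (exponential
#' with a 10 s floor), with zone choice by preference weights modulated by
#' daily exploration growth and cage-mate attraction. In the
#' `territorial_males` scenario one male per zone (up to
#' `min(n_males, n_zones)`) becomes its owner from `capture_day` onward:
#' owners direct `home_bias` of their visits to the owned zone with
#' `home_visit_mult`-fold longer stays, and whenever an owner and a single
#' other male co-occupy the owned zone a displacement contest occurs — the
#' owner wins with probability `p_home_win` and the loser's visit is
#' truncated (the loser also avoids that zone on its next relocation,
#' while the winner is kept in the zone past the loser's departure).
#' Reads are then emitted by [emit_reads()].
#'
#' @param mice Metadata tibble from [make_cohort()].
#' @param profiles Named list of [behavior_profile()]s covering every
#'   mouse.
#' @param config An [enclosure_config()].
#' @param scenario One of `"territorial_males"`, `"floaters_only"`,
#'   `"uniform_random"`.
#' @param seed Integer seed; the full simulation is deterministic given
#'   the seed.
#' @param capture_day First day of territory ownership (default 3).
#' @param p_home_win Probability the owner wins a home contest (default
#'   0.82).
#' @param home_bias Probability an owner's relocation targets its own
#'   zone (default 0.97).
#' @param home_visit_mult Multiplier on an owner's visit duration at its
#'   own zone (default 6).
#' @return List with `trial` (an [rfid_trial()]) and `truth`: the ground
#'   truth as `territory_map` (day, zone_id, owner), `presence_intervals`
#'   and `contest_log` (t, zone_id, holder, intruder, winner).
#' @export
simulate_trial <- function(mice, profiles, config = enclosure_config(),
                           scenario = c("territorial_males",
                                        "floaters_only",
                                        "uniform_random"),
                           seed = 1, capture_day = 3, p_home_win = 0.82,
                           home_bias = 0.97, home_visit_mult = 6) {
  scenario <- match.arg(scenario)
  ids <- mice$mouse_id
  if (!all(ids %in% names(profiles))) {
    abort("`profiles` must be defined for every mouse.")
  }
  profiles <- profiles[ids]
  nz <- length(config$zone_ids)
  zones <- config$zone_ids
  span <- trial_span_seconds(config)
  n <- length(ids)
  is_male <- mice$sex == "M"

  # ownership: one male per zone, males in cohort order claiming their
  # release zone when still free, otherwise the first unclaimed zone
  owner_of_zone <- rep(NA_character_, nz)
  own_zone_of <- setNames(rep(NA_character_, n), ids)
  if (scenario == "territorial_males") {
    males <- which(is_male)
    k <- min(length(males), nz)
    for (i in males[seq_len(k)]) {
      rz <- match(mice$release_zone[i], zones)
      z <- if (!is.na(rz) && is.na(owner_of_zone[rz])) rz else
        which(is.na(owner_of_zone))[1]
      owner_of_zone[z] <- ids[i]
      own_zone_of[ids[i]] <- zones[z]
    }
  }

  # per-mouse parameter vectors
  p_move <- vapply(profiles, `[[`, numeric(1), "p_move_per_min")
  vmeanlog <- vapply(profiles, function(p) {
    log(p$visit_duration_mean * 60) - p$visit_duration_sdlog^2 / 2
  }, numeric(1))
  vsdlog <- vapply(profiles, `[[`, numeric(1), "visit_duration_sdlog")
  cm_bias <- vapply(profiles, `[[`, numeric(1), "cagemate_bias")
  expl <- vapply(profiles, `[[`, numeric(1), "exploration_growth")
  rate_hz <- vapply(profiles, `[[`, numeric(1), "read_rate_hz")
  base_w <- t(vapply(profiles, function(p) {
    if (scenario == "uniform_random" || is.null(p$zone_preference)) {
      w <- rep(1, nz)
    } else {
      w <- p$zone_preference[zones]
      w[is.na(w)] <- 0
    }
    if (all(w == 0)) abort("Zone preference weights must not be all zero.")
    w / sum(w)
  }, numeric(nz)))
  cagemates <- lapply(seq_len(n), function(i) {
    which(mice$cage_id == mice$cage_id[i] & seq_len(n) != i)
  })

  with_seed(seed, {
    loc <- rep(NA_integer_, n)          # zone index or NA (at large)
    t_next <- 10 + rexp(n, p_move / 60) # first zone entry
    cur_start <- rep(NA_real_, n)
    avoid <- rep(NA_integer_, n)        # zone to skip on next choice

    cap <- 4096L
    iv_m <- integer(cap); iv_z <- integer(cap)
    iv_s <- numeric(cap); iv_e <- numeric(cap)
    n_iv <- 0L
    push_interval <- function(m, z, s, e) {
      n_iv <<- n_iv + 1L
      if (n_iv > cap) {
        cap <<- cap * 2L
        length(iv_m) <<- cap; length(iv_z) <<- cap
        length(iv_s) <<- cap; length(iv_e) <<- cap
      }
      iv_m[n_iv] <<- m; iv_z[n_iv] <<- z
      iv_s[n_iv] <<- s; iv_e[n_iv] <<- e
    }
    contests <- list()

    choose_zone <- function(i, day) {
      oz <- own_zone_of[i]
      if (!is.na(oz) && day >= capture_day) {
        if (runif(1) < home_bias) return(match(oz, zones))
        w <- base_w[i, ]
        w[match(oz, zones)] <- 0
      } else {
        g <- expl[i] * (day - 1)
        w <- base_w[i, ] + g / nz
        if (cm_bias[i] > 1 && length(cagemates[[i]]) > 0) {
          cm_zones <- loc[cagemates[[i]]]
          cm_zones <- cm_zones[!is.na(cm_zones)]
          w[cm_zones] <- w[cm_zones] * cm_bias[i]
        }
      }
      if (!is.na(avoid[i])) {
        w[avoid[i]] <- 0
        avoid[i] <<- NA_integer_
      }
      if (all(w == 0)) w <- rep(1, nz)
      sample.int(nz, 1, prob = w)
    }

    draw_visit <- function(i, z, day) {
      d <- rlnorm(1, vmeanlog[i], vsdlog[i])
      if (!is.na(own_zone_of[i]) && day >= capture_day &&
          zones[z] == own_zone_of[i]) {
        d <- d * home_visit_mult
      }
      d
    }

    repeat {
      m <- which.min(t_next)
      t <- t_next[m]
      if (t >= span) break
      day <- floor(t / 86400) + 1
      if (is.na(loc[m])) {
        # entering a zone
        z <- choose_zone(m, day)
        dur <- draw_visit(m, z, day)
        if (scenario == "territorial_males" && is_male[m] &&
            day >= capture_day && !is.na(owner_of_zone[z])) {
          oid <- owner_of_zone[z]
          o <- match(oid, ids)
          present_males <- which(loc == z & is_male)
          if (m == o && length(present_males) == 1L) {
            # owner returns to find a single intruder
            intr <- present_males
            co <- runif(1, 10, 60)
            if (runif(1) < p_home_win) {
              t_next[intr] <- t + co
              dur <- max(dur, co + runif(1, 30, 120))
              avoid[intr] <- z
              winner <- oid
            } else {
              dur <- co
              if (t_next[intr] <= t + co + 5) {
                t_next[intr] <- t + co + runif(1, 30, 120)
              }
              avoid[m] <- z
              winner <- ids[intr]
            }
            contests[[length(contests) + 1L]] <- c(t, z, o, intr,
                                                   match(winner, ids))
          } else if (m != o && length(present_males) == 1L &&
                     present_males == o) {
            # intruder joins the owner at home
            co <- runif(1, 10, 60)
            if (runif(1) < p_home_win) {
              dur <- co
              if (t_next[o] <= t + co + 5) {
                t_next[o] <- t + co + runif(1, 30, 120)
              }
              avoid[m] <- z
              winner <- oid
            } else {
              t_next[o] <- t + co
              dur <- max(dur, co + runif(1, 30, 120))
              avoid[o] <- z
              winner <- ids[m]
            }
            contests[[length(contests) + 1L]] <- c(t, z, o, m,
                                                   match(winner, ids))
          }
        }
        loc[m] <- z
        cur_start[m] <- t
        t_next[m] <- t + dur
      } else {
        # leaving a zone
        push_interval(m, loc[m], cur_start[m], min(t, span))
        loc[m] <- NA_integer_
        cur_start[m] <- NA_real_
        t_next[m] <- t + 10 + rexp(1, p_move[m] / 60)
      }
    }
    # close intervals still open at the end of the trial
    for (m in which(!is.na(loc))) {
      if (cur_start[m] < span) push_interval(m, loc[m], cur_start[m], span)
    }

    intervals <- tibble::tibble(
      mouse_id = ids[iv_m[seq_len(n_iv)]],
      zone_id = zones[iv_z[seq_len(n_iv)]],
      t_start = iv_s[seq_len(n_iv)],
      t_end = iv_e[seq_len(n_iv)]
    ) |>
      dplyr::arrange(.data$mouse_id, .data$t_start)

    reads <- emit_reads(intervals,
                        read_rate_hz = rate_hz[match(intervals$mouse_id,
                                                     ids)])

    contest_log <- if (length(contests) == 0L) {
      tibble::tibble(t = numeric(), zone_id = character(),
                     holder = character(), intruder = character(),
                     winner = character())
    } else {
      cm <- do.call(rbind, contests)
      tibble::tibble(t = cm[, 1], zone_id = zones[cm[, 2]],
                     holder = ids[cm[, 3]], intruder = ids[cm[, 4]],
                     winner = ids[cm[, 5]])
    }

    territory_map <- if (scenario == "territorial_males") {
      tidyr::expand_grid(day = seq_len(config$trial_days),
                         zone_id = zones) |>
        dplyr::mutate(owner = ifelse(
          .data$day >= capture_day,
          owner_of_zone[match(.data$zone_id, zones)], NA_character_))
    } else {
      tibble::tibble(day = integer(), zone_id = character(),
                     owner = character())
    }

    list(
      trial = rfid_trial(config, mice, reads),
      truth = list(territory_map = territory_map,
                   presence_intervals = intervals,
                   contest_log = contest_log)
    )
  })
}

#' Simulate a full preset trial
#'
#' Convenience wrapper: build a cohort, derive profiles from a preset and
#' run the territorial-males scenario.
#'
#' @param preset Preset name or list (see [load_preset()]).
#' @param n_males,n_females Cohort sizes (default 10 and 10).
#' @param seed Integer seed.
#' @param config An [enclosure_config()].
#' @param ... Passed to [simulate_trial()].
#' @return As [simulate_trial()].
#' @export
simulate_preset <- function(preset = "c57_like", n_males = 10,
                            n_females = 10, seed = 1,
                            config = enclosure_config(), ...) {
  if (is.character(preset)) preset <- load_preset(preset)
  genotype <- preset$name %||% "C57"
  mice <- make_cohort(n_males, n_females, genotype = genotype,
                      n_per_cage = preset$n_per_cage %||% 2,
                      seed = seed, config = config)
  profiles <- preset_profiles(mice, config, preset)
  terr <- preset$territorial %||% list()
  simulate_trial(
    mice, profiles, config,
    scenario = "territorial_males", seed = seed + 1,
    capture_day = terr$capture_day %||% 3,
    p_home_win = terr$p_home_win %||% 0.82,
    home_bias = terr$home_bias %||% 0.97,
    home_visit_mult = terr$home_visit_mult %||% 6,
    ...
  )
}
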