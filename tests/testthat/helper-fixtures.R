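# Shared fixtures and independent oracles. All fixtures are built in code;
# bout endpoints in random generators are integers so that per-second
# discretization oracles are exact.

two_sex_mice <- function(n_m = 2, n_f = 2, cage_size = 2) {
  n <- n_m + n_f
  tibble::tibble(
    mouse_id = c(sprintf("m%02d", seq_len(n_m)),
                 sprintf("f%02d", seq_len(n_f)))[seq_len(n)],
    sex = rep(c("M", "F"), c(n_m, n_f)),
    genotype = "C57",
    cage_id = paste0("c", (seq_len(n) - 1) %/% cage_size + 1),
    release_zone = "Z1",
    last_valid_day = NA_integer_
  )
}

# Hand-built bout rows following the package's bout contract.
make_bouts <- function(mouse_id, zone_id, t_start, t_end,
                       config = enclosure_config()) {
  tibble::tibble(
    mouse_id = mouse_id, zone_id = zone_id,
    t_start = t_start, t_end = t_end,
    duration = ifelse(t_end > t_start, t_end - t_start, 1),
    n_reads = ifelse(t_end > t_start, 2L, 1L),
    day = assign_day(t_start, config)
  )
}

# Random per-mouse non-overlapping bouts with integer endpoints, possibly
# touching end-to-start, spread over a few zones of one day.
random_bouts <- function(n_mice = 4, n_zones = 2, max_bouts = 6,
                         horizon = 3000, config = enclosure_config()) {
  rows <- list()
  for (i in seq_len(n_mice)) {
    t <- sample(0:50, 1)
    for (b in seq_len(sample(1:max_bouts, 1))) {
      dur <- sample(1:300, 1)
      if (t + dur >= horizon) break
      rows[[length(rows) + 1]] <- list(
        mouse_id = sprintf("m%02d", i),
        zone_id = paste0("Z", sample(n_zones, 1)),
        t_start = t, t_end = t + dur
      )
      t <- t + dur + sample(0:400, 1)  # gap 0 allows touching bouts
    }
  }
  df <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  make_bouts(df$mouse_id, df$zone_id, df$t_start, df$t_end, config)
}

# Independent read-by-read bout grouping oracle: an explicit loop applying
# the gap/transition/isolated-read rules one read at a time.
oracle_group_bouts <- function(reads, threshold = 139,
                               config = enclosure_config()) {
  out <- list()
  for (m in unique(reads$mouse_id)) {
    r <- reads[reads$mouse_id == m, ]
    r <- r[order(r$t), ]
    cur <- NULL
    flush <- function(cur) {
      n <- length(cur$ts)
      tibble::tibble(
        mouse_id = m, zone_id = cur$zone,
        t_start = cur$ts[1], t_end = cur$ts[n],
        duration = if (n == 1) 1 else cur$ts[n] - cur$ts[1],
        n_reads = n, day = assign_day(cur$ts[1], config)
      )
    }
    for (i in seq_len(nrow(r))) {
      if (is.null(cur)) {
        cur <- list(zone = r$zone_id[i], ts = r$t[i])
      } else if (r$zone_id[i] == cur$zone &&
                 r$t[i] - cur$ts[length(cur$ts)] <= threshold) {
        cur$ts <- c(cur$ts, r$t[i])
      } else {
        out[[length(out) + 1]] <- flush(cur)
        cur <- list(zone = r$zone_id[i], ts = r$t[i])
      }
    }
    if (!is.null(cur)) out[[length(out) + 1]] <- flush(cur)
  }
  dplyr::bind_rows(out) |> dplyr::arrange(mouse_id, t_start)
}

# Per-second discretization of bout occupancy: returns, for each zone and
# tick [t, t + 1), the set of present mice (bouts occupy
# [t_start, t_start + duration), matching the package's convention).
discretize_bouts <- function(bouts) {
  ticks <- list()
  for (z in unique(bouts$zone_id)) {
    b <- bouts[bouts$zone_id == z, ]
    lo <- floor(min(b$t_start)); hi <- ceiling(max(b$t_start + b$duration))
    for (t in lo:(hi - 1)) {
      present <- b$mouse_id[b$t_start <= t & t < b$t_start + b$duration]
      if (length(present) > 0) {
        ticks[[length(ticks) + 1]] <- list(zone_id = z, t = t,
                                           members = list(present))
      }
    }
  }
  dplyr::bind_rows(lapply(ticks, tibble::as_tibble))
}

# Direct-count SRI oracle on a binary GBI.
oracle_sri <- function(gbi, a, b) {
  x <- sum(gbi[, a] == 1 & gbi[, b] == 1)
  ya <- sum(gbi[, a] == 1 & gbi[, b] == 0)
  yb <- sum(gbi[, a] == 0 & gbi[, b] == 1)
  if (x + ya + yb == 0) 0 else x / (x + ya + yb)
}

random_gbi <- function(n_events, n_mice, p = 0.3) {
  matrix(rbinom(n_events * n_mice, 1, p), n_events, n_mice,
         dimnames = list(NULL, sprintf("m%02d", seq_len(n_mice))))
}

# Small floater simulation reused by several tests.
small_floater_sim <- function(seed = 42, n_m = 2, n_f = 2, days = 3,
                              read_rate = 2.5) {
  cfg <- enclosure_config(trial_days = days)
  mice <- make_cohort(n_m, n_f, n_per_cage = 2, seed = seed, config = cfg)
  profs <- lapply(seq_len(nrow(mice)), function(i)
    behavior_profile(read_rate_hz = read_rate))
  names(profs) <- mice$mouse_id
  simulate_trial(mice, profs, cfg, scenario = "floaters_only", seed = seed)
}
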