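cfg <- enclosure_config()

test_that("occupancy fractions follow the worked 4h/1h example and sum to one", {
  mice <- two_sex_mice(2, 0)
  b <- make_bouts(c("m01", "m02"), "Z1", c(0, 20000),
                  c(4 * 3600, 20000 + 3600))
  occ <- zone_occupancy(b, mice, "M", cfg)
  expect_equal(occ$occupancy[occ$mouse_id == "m01"], 0.8)
  expect_equal(occ$occupancy[occ$mouse_id == "m02"], 0.2)
  # sole visitor -> 1
  occ1 <- zone_occupancy(make_bouts("m01", "Z2", 50000, 51000), mice, "M", cfg)
  expect_equal(occ1$occupancy, 1)
  # per zone-day, same-sex fractions always sum to 1
  withr::local_seed(3)
  b <- random_bouts(n_mice = 4, n_zones = 3)
  occ <- zone_occupancy(b, two_sex_mice(4, 0), "M", cfg)
  sums <- dplyr::summarise(dplyr::group_by(occ, day, zone_id),
                           s = sum(occupancy))
  expect_equal(sums$s, rep(1, nrow(sums)))
})

test_that("capture scores apply the majority penalty with a strict 0.5 cut", {
  mice <- two_sex_mice(2, 0)
  occ <- tibble::tibble(mouse_id = c("m01", "m02"), day = 1L, zone_id = "Z1",
                        time_s = c(4, 1) * 3600, occupancy = c(0.8, 0.2))
  cs <- capture_scores(occ, mice, "M", cfg)
  expect_equal(cs$capture_score[cs$mouse_id == "m01" & cs$day == 1], 0.8)
  expect_equal(cs$capture_score[cs$mouse_id == "m02" & cs$day == 1], -0.8)
  # occupancy exactly 0.5 is not a capture
  occ <- tibble::tibble(mouse_id = c("m01", "m02"), day = 1L, zone_id = "Z1",
                        time_s = c(1, 1), occupancy = c(0.5, 0.5))
  cs <- capture_scores(occ, mice, "M", cfg)
  expect_equal(cs$capture_score[cs$day == 1], c(-0.5, -0.5))
})

test_that("priority access accumulates capture scores and classifies status", {
  mice <- two_sex_mice(2, 0)
  b <- dplyr::bind_rows(lapply(0:9, function(d)
    make_bouts(c("m01", "m02"), "Z1", c(d, d) * 86400,
               d * 86400 + c(4, 1) * 3600)))
  pas <- priority_access_scores(b, mice, "M", cfg)
  expect_equal(pas$pas[pas$mouse_id == "m01" & pas$day == 10], 8)
  expect_equal(pas$pas[pas$mouse_id == "m02" & pas$day == 10], -8)
  g <- glance(pas)
  expect_identical(g$status, c("territorial", "non_territorial"))
  # telescoping: PAS(D) - PAS(D-1) = capture(D)
  diffs <- dplyr::mutate(dplyr::group_by(pas, mouse_id),
                         d = pas - dplyr::lag(pas, default = 0))
  expect_equal(diffs$d, pas$capture_score)
  # full monopolization of k zones every day -> PAS = k * days
  b2 <- dplyr::bind_rows(lapply(0:9, function(d) make_bouts(
    rep("m01", 2), c("Z1", "Z2"),
    d * 86400 + c(0, 40000), d * 86400 + c(3600, 43600))))
  pas2 <- priority_access_scores(b2, mice, "M", cfg)
  expect_equal(pas2$pas[pas2$mouse_id == "m01" & pas2$day == 10], 20)
  # the competitor with no bout time at all accrues the daily penalty
  expect_equal(pas2$pas[pas2$mouse_id == "m02" & pas2$day == 10], -10)
})

test_that("censored days contribute zero capture and are flagged", {
  mice <- two_sex_mice(2, 0)
  mice$last_valid_day <- c(NA, 5L)
  occ <- tibble::tibble(mouse_id = "m01", day = 1L, zone_id = "Z1",
                        time_s = 3600, occupancy = 1)
  cs <- capture_scores(occ, mice, "M", cfg)
  m2 <- cs[cs$mouse_id == "m02", ]
  expect_true(all(m2$censored[m2$day > 5]))
  expect_equal(m2$capture_score[m2$day > 5], rep(0, 5))
  expect_equal(m2$capture_score[m2$day <= 5], rep(-1, 5))
})

test_that("the territory holder needs a strict majority of 24 h male reads", {
  mice <- two_sex_mice(2, 1)
  reads <- tibble::tibble(
    mouse_id = c(rep("m01", 60), rep("m02", 40), rep("f01", 500)),
    zone_id = "Z1", t = seq_len(600))
  expect_identical(territory_holder(reads, mice, "Z1", 1000), "m01")
  # exact 50/50 -> none
  reads <- tibble::tibble(mouse_id = rep(c("m01", "m02"), 50),
                          zone_id = "Z1", t = seq_len(100))
  expect_identical(territory_holder(reads, mice, "Z1", 1000), NA_character_)
  # no male reads in window -> none
  expect_identical(territory_holder(reads, mice, "Z1", 90000), NA_character_)
  # reads at or after t are outside the half-open window
  reads <- tibble::tibble(mouse_id = "m01", zone_id = "Z1", t = c(5, 10))
  expect_identical(territory_holder(reads, mice, "Z1", 5), NA_character_)
})

test_that("contest inference finds join-then-leave episodes with contexts", {
  mice <- two_sex_mice(3, 1)
  # m01 holds the zone (majority of reads day before); intruder m02 joins
  # [40,60] within m01's [0,100] bout and leaves first
  reads <- tibble::tibble(mouse_id = rep("m01", 200), zone_id = "Z1",
                          t = seq(0, 199) + 86400)
  day2 <- 86400
  b <- make_bouts(c("m01", "m02"), "Z1",
                  day2 + c(300, 340), day2 + c(400, 360))
  ct <- detect_contests(b, reads, mice, cfg)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$winner, "m01")
  expect_identical(ct$loser, "m02")
  expect_identical(ct$holder, "m01")
  expect_identical(ct$winner_context, "home")
  expect_identical(ct$loser_context, "away")
  expect_equal(ct$co_duration, 20)

  # simultaneous departure is a tie -> excluded
  b <- make_bouts(c("m01", "m02"), "Z1", day2 + c(0, 40), day2 + c(100, 100))
  expect_identical(nrow(detect_contests(b, reads, mice, cfg)), 0L)

  # a third male joining before anyone leaves voids the episode
  b <- make_bouts(c("m01", "m02", "m03"), "Z1",
                  day2 + c(0, 40, 50), day2 + c(100, 60, 80))
  expect_identical(nrow(detect_contests(b, reads, mice, cfg)), 0L)

  # no holder (no prior reads) -> neutral contexts
  b <- make_bouts(c("m01", "m02"), "Z1", c(0, 40), c(100, 60))
  ct <- detect_contests(b, tibble::tibble(mouse_id = character(),
                                          zone_id = character(),
                                          t = numeric()), mice, cfg)
  expect_identical(ct$winner_context, "neutral")
})

test_that("win rates split by context and flag the both-context set", {
  contests <- tibble::tibble(
    t = 1:6, zone_id = "Z1", day = 1L,
    present_first = "a", joining = "b",
    winner = c("a", "a", "a", "a", "b", "b"),
    loser = c("b", "b", "b", "b", "a", "a"),
    co_duration = 10, holder = "a",
    winner_context = c(rep("home", 4), "away", "away"),
    loser_context = c(rep("away", 4), "home", "home"))
  wr <- home_away_win_rates(contests)
  a <- wr[wr$mouse_id == "a", ]
  expect_equal(a$home_win_rate, 4 / 6)
  expect_identical(a$n_home, 6L)
  b <- wr[wr$mouse_id == "b", ]
  expect_equal(b$away_win_rate, 2 / 6)
  expect_true(all(!wr$both_contexts))  # neither male seen in both contexts
  expect_true(is.na(a$away_win_rate))
})

test_that("null overlap deviation evaluates the printed formula", {
  mice <- two_sex_mice(2, 0)
  # H = 10 h for the holder, I = 5 h for the intruder, disjoint in time
  b <- dplyr::bind_rows(lapply(4:9, function(d) make_bouts(
    c("m01", "m02"), "Z1",
    d * 86400 + c(0, 50000), d * 86400 + c(6000, 53000))))
  out <- overlap_null_deviation(b, mice, "m01", cfg)
  expect_equal(out$holder_hours, 10)
  expect_equal(out$intruder_hours, 5)
  expect_equal(out$expected_hours, 50 / 1152)
  expect_equal(out$pct_deviation, -100)  # full avoidance
  # observed equal to expected -> 0 (arithmetic identity)
  expect_equal(100 * (out$expected_hours - out$expected_hours) /
                 out$expected_hours, 0)
})
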