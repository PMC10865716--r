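cfg <- enclosure_config()

test_that("dyad overlaps are half-open maximal intersections within a zone", {
  b <- make_bouts(c("a", "b"), "Z1", c(0, 40), c(100, 60))
  d <- dyad_overlaps(b, cfg)
  expect_identical(nrow(d), 1L)
  expect_equal(c(d$t_start, d$t_end, d$duration), c(40, 60, 20))
  # touching endpoints are not overlaps
  b <- make_bouts(c("a", "b"), "Z1", c(0, 50), c(50, 80))
  expect_identical(nrow(dyad_overlaps(b, cfg)), 0L)
  # different zones never overlap
  b <- make_bouts(c("a", "b"), c("Z1", "Z2"), c(0, 0), c(100, 100))
  expect_identical(nrow(dyad_overlaps(b, cfg)), 0L)
})

test_that("association events are chain-overlap components of >= 2 mice", {
  b <- make_bouts(c("a", "b", "c"), "Z1", c(0, 8, 18), c(10, 20, 30))
  ev <- association_events(b, cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$members[[1]], c("a", "b", "c"))
  expect_equal(c(ev$t_start, ev$t_end), c(0, 30))
  # two disjoint dyads in one zone -> two events
  b <- make_bouts(c("a", "b", "c", "d"), "Z1",
                  c(0, 5, 500, 505), c(10, 15, 510, 515))
  expect_identical(nrow(association_events(b, cfg)), 2L)
  # a solitary bout is not an event
  b <- make_bouts("a", "Z1", 0, 100)
  expect_identical(nrow(association_events(b, cfg)), 0L)
  # a mouse with several bouts in one component is counted once
  b <- make_bouts(c("a", "b", "a"), "Z1", c(0, 5, 12), c(10, 20, 18))
  ev <- association_events(b, cfg)
  expect_identical(ev$members[[1]], c("a", "b"))
})

test_that("events match an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  withr::local_seed(5)
  for (rep in 1:20) {
    b <- random_bouts(n_mice = 4, n_zones = 2, max_bouts = 5)
    got <- association_events(b, cfg)
    # oracle: pairwise positive intersection graph per zone
    want_n <- 0L
    for (z in unique(b$zone_id)) {
      bz <- b[b$zone_id == z, ]
      nb <- nrow(bz)
      if (nb == 0) next
      adj <- matrix(FALSE, nb, nb)
      for (i in seq_len(nb)) for (j in seq_len(nb)) {
        if (i != j) {
          lo <- max(bz$t_start[i], bz$t_start[j])
          hi <- min(bz$t_start[i] + bz$duration[i],
                    bz$t_start[j] + bz$duration[j])
          adj[i, j] <- hi > lo
        }
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comps <- igraph::components(g)$membership
      for (k in unique(comps)) {
        mem <- unique(bz$mouse_id[comps == k])
        if (length(mem) >= 2) want_n <- want_n + 1L
      }
    }
    expect_identical(nrow(got), want_n)
  }
})

test_that("composition accounting credits each co-present mouse separately", {
  mice <- two_sex_mice(2, 2)
  # one male + one female together for an hour -> 2 mouse-hours in (1,1)
  b <- make_bouts(c("m01", "f01"), "Z1", c(0, 0), c(3600, 3600))
  comp <- group_composition_hours(b, mice, cfg)
  expect_equal(comp$mouse_hours[comp$n_males == 1 & comp$n_females == 1], 2)
  # one mouse alone an hour -> 1 mouse-hour in (1,0)
  b <- make_bouts("m01", "Z1", 0, 3600)
  comp <- group_composition_hours(b, mice, cfg)
  expect_equal(comp$mouse_hours, 1)
  # worked segment partition: a [0,100], b [40,60], both male
  b <- make_bouts(c("m01", "m02"), "Z1", c(0, 40), c(100, 60))
  comp <- group_composition_hours(b, mice, cfg)
  expect_equal(comp$mouse_hours[comp$n_males == 1] * 3600, 80)
  expect_equal(comp$mouse_hours[comp$n_males == 2] * 3600, 40)
  expect_equal(sum(comp$mouse_hours) * 3600, sum(b$duration))
})

test_that("segment accounting matches per-second discretization on random bouts", {
  withr::local_seed(13)
  # metadata ids must match random_bouts ids (m01..m04): two males, two females
  mice <- tibble::tibble(mouse_id = sprintf("m%02d", 1:4),
                         sex = c("M", "M", "F", "F"), genotype = "C57",
                         cage_id = c("c1", "c1", "c2", "c2"),
                         release_zone = "Z1", last_valid_day = NA_integer_)
  for (rep in 1:15) {
    b <- random_bouts(n_mice = 4, n_zones = 2, max_bouts = 5)
    ticks <- discretize_bouts(b)
    # composition conservation and cellwise equality (1 s resolution exact
    # because endpoints are integers)
    comp <- group_composition_hours(b, mice, cfg)
    expect_equal(sum(comp$mouse_hours) * 3600, sum(b$duration))
    sex_of <- setNames(mice$sex, mice$mouse_id)
    tick_cells <- table(
      vapply(ticks$members, function(m) {
        paste(sum(sex_of[m] == "M"), sum(sex_of[m] == "F"))
      }, character(1)))
    for (cell in names(tick_cells)) {
      mf <- as.integer(strsplit(cell, " ")[[1]])
      got <- comp$mouse_hours[comp$n_males == mf[1] &
                                comp$n_females == mf[2]] * 3600
      want <- as.numeric(tick_cells[[cell]]) * sum(mf)
      expect_equal(sum(got), want)
    }
    # alone time per mouse matches tick counts
    alone <- time_alone(b, mice, cfg)
    alone_tot <- alone[is.na(alone$day), ]
    for (m in alone_tot$mouse_id) {
      in_tick <- vapply(ticks$members, function(x) m %in% x, logical(1))
      solo <- vapply(ticks$members, function(x)
        m %in% x && length(x) == 1, logical(1))
      expect_equal(alone_tot$alone_s[alone_tot$mouse_id == m], sum(solo))
      expect_equal(alone_tot$total_s[alone_tot$mouse_id == m], sum(in_tick))
    }
    # dyad totals match tick co-presence
    dy <- dyad_overlaps(b, cfg)
    prs <- utils::combn(mice$mouse_id, 2)
    for (k in seq_len(ncol(prs))) {
      pair <- sort(prs[, k])
      both <- vapply(ticks$members, function(x) all(pair %in% x), logical(1))
      got <- sum(dy$duration[dy$mouse_a == pair[1] & dy$mouse_b == pair[2]])
      expect_equal(got, sum(both))
    }
  }
})

test_that("alone fractions are proportions of each mouse's own bout time", {
  mice <- two_sex_mice(2, 0)
  b <- make_bouts(c("m01", "m02"), "Z1", c(0, 40), c(100, 60))
  al <- time_alone(b, mice, cfg)
  a_tot <- al[al$mouse_id == "m01" & is.na(al$day), ]
  expect_equal(a_tot$alone_fraction, 0.8)
  # a never co-occurring mouse is fully alone; absent mice yield no rows
  b <- make_bouts("m01", "Z1", 0, 500)
  al <- time_alone(b, mice, cfg)
  expect_equal(al$alone_fraction, c(1, 1))
  expect_false("m02" %in% al$mouse_id)
})

test_that("sex association shares are focal-relative and sum to one", {
  mice <- two_sex_mice(1, 2)
  # f01: 10 min female-female, then 30 min female-male
  b <- dplyr::bind_rows(
    make_bouts(c("f01", "f02"), "Z1", c(0, 0), c(600, 600)),
    make_bouts(c("f01", "m01"), "Z2", c(10000, 10000), c(11800, 11800))
  )
  sf <- sex_association_fractions(b, mice, cfg)
  f <- sf[sf$mouse_id == "f01", ]
  expect_equal(sum(f$assoc_s * f$same_sex_share) / sum(f$assoc_s), 0.25)
  expect_equal(sum(f$assoc_s * f$opposite_sex_share) / sum(f$assoc_s), 0.75)
  expect_equal(f$same_sex_share + f$opposite_sex_share, rep(1, nrow(f)))
  # every association includes a male -> opposite share 1
  m <- sf[sf$mouse_id == "m01", ]
  expect_equal(m$opposite_sex_share, 1)
  # a mouse with no associations is absent
  mice3 <- two_sex_mice(1, 3)
  expect_false("f03" %in% sex_association_fractions(b, mice3, cfg)$mouse_id)
})

test_that("cagemate preference compares observed share to the partner-count null", {
  # 10 females: f01 caged with f02 (cage c1), 8 others in other cages
  mice <- two_sex_mice(0, 10, cage_size = 2)
  expect_identical(mice$cage_id[1:2], c("c1", "c1"))
  # f01 spends all female-female time with its cage mate
  b <- make_bouts(c("f01", "f02"), "Z1", c(0, 0), c(3600, 3600))
  dy <- dyad_overlaps(b, cfg)
  cm <- cagemate_preference(dy, mice, cfg)
  f <- cm[cm$mouse_id == "f01", ]
  expect_equal(f$observed_share, 1)
  expect_equal(f$null_share, 1 / 9)
  expect_equal(f$pct_deviation, 800)
  # observed equal to null -> deviation 0
  cm0 <- tibble::tibble(mouse_id = "x", day = 1L, ff_time_s = 10,
                        observed_share = 1 / 9, null_share = 1 / 9)
  expect_equal(100 * (cm0$observed_share - cm0$null_share) / cm0$null_share, 0)
  # censoring shrinks the available-partner denominator
  mice$last_valid_day <- c(NA, NA, rep(0L, 8))
  cm <- cagemate_preference(dy, mice, cfg)
  expect_equal(cm$null_share[cm$mouse_id == "f01"], 1)
  expect_equal(cm$pct_deviation[cm$mouse_id == "f01"], 0)
})
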