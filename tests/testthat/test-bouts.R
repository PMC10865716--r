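cfg <- enclosure_config()

test_that("inter-read intervals are within-mouse, within-zone only", {
  reads <- tibble::tibble(mouse_id = "a", zone_id = "Z1", t = c(0, 1, 3))
  expect_equal(interread_intervals(reads)$gap, c(1, 2))
  # a transition in between removes the would-be within-zone gap
  reads <- tibble::tibble(mouse_id = "a", zone_id = c("Z1", "Z2", "Z1"),
                          t = c(0, 50, 100))
  expect_identical(nrow(interread_intervals(reads)), 0L)
  # single read -> no gaps; two mice never mix
  expect_identical(
    nrow(interread_intervals(tibble::tibble(mouse_id = "a", zone_id = "Z1",
                                            t = 5))), 0L)
  reads <- tibble::tibble(mouse_id = c("a", "b"), zone_id = "Z1", t = c(0, 9))
  expect_identical(nrow(interread_intervals(reads)), 0L)
})

test_that("threshold estimation takes the ceiling of the empirical quantile", {
  expect_equal(estimate_threshold(c(rep(5, 99), 500), q = 0.99), 5)
  expect_equal(estimate_threshold(rep(7, 10), q = 0.5), 7)
  expect_equal(estimate_threshold(rep(7, 10), q = 0.99), 7)
  expect_equal(estimate_threshold(c(1.2, 2.7), q = 0.99), 3)  # whole seconds
  expect_error(estimate_threshold(numeric(0)), "139")
  expect_equal(DEFAULT_GAP_THRESHOLD, 139)
})

test_that("bout grouping follows the gap, transition and isolated-read rules", {
  b <- group_bouts(tibble::tibble(mouse_id = "a", zone_id = "Z1",
                                  t = c(0, 100, 200)), config = cfg)
  expect_identical(nrow(b), 1L)
  expect_equal(b$t_start, 0); expect_equal(b$t_end, 200)
  expect_equal(b$duration, 200); expect_identical(b$n_reads, 3L)

  # isolated single read gets nominal 1 s duration
  b <- group_bouts(tibble::tibble(mouse_id = "a", zone_id = "Z1", t = 500),
                   config = cfg)
  expect_equal(b$duration, 1)

  # gap of exactly 139 extends; 140 splits
  b <- group_bouts(tibble::tibble(mouse_id = "a", zone_id = "Z1",
                                  t = c(0, 139)), config = cfg)
  expect_identical(nrow(b), 1L)
  b <- group_bouts(tibble::tibble(mouse_id = "a", zone_id = "Z1",
                                  t = c(0, 140)), config = cfg)
  expect_identical(nrow(b), 2L)
  expect_equal(b$duration, c(1, 1))

  # a zone transition closes the open bout even within the gap window
  b <- group_bouts(tibble::tibble(mouse_id = "a", zone_id = c("Z1", "Z2"),
                                  t = c(0, 50)), config = cfg)
  expect_identical(b$zone_id, c("Z1", "Z2"))
  expect_equal(b$duration, c(1, 1))
  expect_equal(b$t_start, c(0, 50))
})

test_that("bout grouping matches a read-by-read oracle on random streams", {
  withr::local_seed(7)
  for (rep in 1:25) {
    n <- sample(2:120, 1)
    reads <- tibble::tibble(
      mouse_id = sample(c("a", "b"), n, replace = TRUE),
      zone_id = sample(c("Z1", "Z2", "Z3"), n, replace = TRUE),
      t = sort(round(runif(n, 0, 2000), 1))
    )
    got <- group_bouts(reads, config = cfg)
    want <- oracle_group_bouts(reads, 139, cfg)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # read conservation
    expect_identical(sum(got$n_reads), n)
  }
})

test_that("raising the threshold merges bouts and never shrinks durations", {
  withr::local_seed(11)
  reads <- tibble::tibble(mouse_id = "a", zone_id = "Z1",
                          t = sort(runif(200, 0, 5000)))
  thresholds <- c(5, 20, 60, 139, 500)
  res <- lapply(thresholds, function(th) group_bouts(reads, th, cfg))
  counts <- vapply(res, nrow, integer(1))
  expect_true(all(diff(counts) <= 0))
  total_dur <- vapply(res, function(b) sum(b$duration), numeric(1))
  expect_true(all(diff(total_dur) >= 0))
  # inferred presence never exceeds the trial span
  expect_true(all(total_dur <= 10 * 86400))
})

test_that("zone monopolization reports the top same-sex share per zone-day", {
  mice <- two_sex_mice(2, 1)
  reads <- tibble::tibble(
    mouse_id = c(rep("m01", 60), rep("m02", 40), rep("f01", 30)),
    zone_id = "Z1", t = seq(1, 130))
  z <- zone_monopolization(reads, mice, "M", cfg)
  expect_equal(z$top_fraction, 0.6)
  expect_identical(z$top_mouse, "m01")
  # a zone with only female reads is omitted under the male filter
  reads_f <- tibble::tibble(mouse_id = "f01", zone_id = "Z2", t = 1:10)
  expect_identical(nrow(zone_monopolization(reads_f, mice, "M", cfg)), 0L)
  # single male sourcing everything -> 1
  z1 <- zone_monopolization(reads[reads$mouse_id == "m01", ], mice, "M", cfg)
  expect_equal(z1$top_fraction, 1)
})

test_that("minimum distance sums straight-line inter-zone transitions", {
  grid <- enclosure_config()
  xs <- setNames(grid$zone_coords$x, grid$zone_coords$zone_id)
  ys <- setNames(grid$zone_coords$y, grid$zone_coords$zone_id)
  d <- function(a, b) sqrt((xs[a] - xs[b])^2 + (ys[a] - ys[b])^2)
  # all reads at one zone -> no rows (zero distance)
  r <- tibble::tibble(mouse_id = "a", zone_id = "Z1", t = 1:5)
  expect_identical(nrow(min_distance_traveled(r, grid)), 0L)
  # A -> B -> A doubles the leg
  r <- tibble::tibble(mouse_id = "a", zone_id = c("Z1", "Z2", "Z1"),
                      t = c(0, 100, 200))
  expect_equal(min_distance_traveled(r, grid)$distance_m,
               unname(2 * d("Z1", "Z2")))
  # A -> B -> C sums both legs
  r <- tibble::tibble(mouse_id = "a", zone_id = c("Z1", "Z2", "Z7"),
                      t = c(0, 100, 200))
  expect_equal(sum(min_distance_traveled(r, grid)$distance_m),
               unname(d("Z1", "Z2") + d("Z2", "Z7")))
})

test_that("daily zone counts accumulate distinct zones and top-zone share", {
  b <- make_bouts(
    mouse_id = "a",
    zone_id = c("Z1", "Z2", "Z1", "Z3"),
    t_start = c(0, 1000, 86400, 2 * 86400),
    t_end = c(600, 1100, 86800, 2 * 86400 + 100)
  )
  out <- daily_zone_counts(b, cfg)
  expect_identical(out$n_zones[1:3], c(2L, 1L, 1L))
  expect_identical(out$cum_zones[1:3], c(2L, 2L, 3L))
  # day 1: Z1 600 s of 700 total
  expect_equal(out$top_zone_share[1], 600 / 700)
  # all in one zone -> share 1
  b1 <- make_bouts("a", "Z1", c(0, 1000), c(100, 1200))
  expect_equal(daily_zone_counts(b1, cfg)$top_zone_share[1], 1)
  # day with no bouts keeps cumulative, zero count
  expect_identical(out$n_zones[4:10], rep(0L, 7))
  expect_identical(out$cum_zones[10], 3L)
})
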