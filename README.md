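# rfidsoc

Social and territorial behavior inference from RFID tracking data.

`rfidsoc` is an R package for behavioral ecologists who monitor
individually PIT-tagged animals (here: house mice in outdoor field
enclosures) with RFID antennas placed at discrete resource zones. Raw
antenna logs — millions of tag detections at ~2–3 Hz — are turned, stage
by stage, into biologically interpretable quantities:

1. **Visit bouts** — detections of one mouse at one zone are chained into
   bouts whenever consecutive reads fall within a gap threshold (139 s by
   default, the cut-off capturing 99% of within-zone inter-read
   intervals; estimable from the data with `estimate_threshold()`).
   Isolated single reads become 1 s bouts; zone transitions always split
   bouts.
2. **Spatiotemporal associations** — overlapping bouts at one zone form
   dyadic overlaps and chain-overlap association events, from which the
   package derives mouse-hours by group composition, time spent alone,
   same- versus opposite-sex association shares, and each female's
   cage-mate preference against a partner-availability null.
3. **Territory structure** — daily, sex-specific zone occupancy fractions
   feed the capture score

   `Capture(M, D) = Σ_z Occupancy(M, D, z) − 1{no z with Occupancy > 0.5}`

   whose cumulative sum over days is the **priority access score (PAS)**;
   a strictly positive final PAS marks a territorial animal. Dyadic
   displacement contests (one male present, a second joins, one leaves;
   the leaver loses) are inferred per zone, with home/away context from
   the rolling 24 h majority-of-male-reads territory-holder rule, and
   territorial–intruder spatiotemporal overlap is compared with the null
   expectation `(H × I) / (24 h × days × zones)`.
4. **Social networks** — daily group-by-individual matrices yield Simple
   Ratio Index weights, `SRI = x / (x + y_a + y_b)`, and weighted daily
   networks with components, edge density, degree centrality, node
   strength and page rank.
5. **Synthetic trials** — an agent-based generator (`simulate_trial()`,
   `simulate_preset()`) produces ground-truthed read streams with
   territorial males, floaters, and females of configurable exploration
   breadth and cage-mate bias, so every inference stage can be validated
   by parameter recovery without any field data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` accessors and `autoplot()` methods for the fitted objects.

## Worked example

Simulate a 10-day trial (10 males, 10 females, eight zones in a 2 × 4
grid) under the laboratory-strain-like preset and run the whole
pipeline:

```r
library(rfidsoc)
library(dplyr)

sim <- simulate_preset("c57_like", seed = 1)
sim$trial
#> <rfid_trial> 20 mice, 7097618 reads, 8 zones, 10 days

res <- run_pipeline(sim$trial)
glance(res$pas_male)
#> # A tibble: 10 × 4
#>    mouse_id final_day final_pas status
#>  1 M01             10      7.27 territorial
#>  2 M02             10      7.45 territorial
#>  ...
#>  9 M09             10     -7.25 non_territorial
#> 10 M10             10     -6.67 non_territorial
```

Eight males (one per zone, known from the generator's ground truth) end
with strongly positive priority access scores — they monopolized their
zones — while the two floaters sink to ≈ −7: each day without a majority
share of any zone costs them the one-point penalty.

```r
wr <- filter(res$win_rates, n_home > 0)
sum(wr$home_wins) / sum(wr$n_home)   # pooled home win rate
#> 0.831  (498 home contests; the generator's true value is 0.82)

res$networks$day10
#> <rfid_network> day 10: 20 nodes, 164 edges, 1 components, density 0.863

res$overlap_null
#>   holder_hours intruder_hours observed_hours expected_hours pct_deviation
#> 1         405.           18.4           3.81           6.46         -41.0
```

Territory holders and intruders overlap 41% less than expected at
random — spatiotemporal avoidance. The same pipeline applied to the
`wd_like` preset (site-faithful, cage-bound females) yields sparse,
fragmented networks (edge density ≈ 0.15, 2–3 components late in the
trial), the opposite social architecture from the same inference code.

To analyze field data instead, read a CSV antenna log plus an animal
metadata table and run the identical stages:

```r
mice  <- read_mouse_meta("mice.csv")
trial <- read_rfid_log("reads.csv", mice, enclosure_config())
res   <- run_pipeline(trial, threshold = "auto")
```

A thin command-line wrapper with `simulate`, `bouts`, `associations`,
`territory`, `networks` and `run-all` subcommands is installed at
`system.file("cli", "rfidsoc.R", package = "rfidsoc")`.

## Documentation

The methods vignette (`vignettes/rfidsoc-methods.Rmd`) describes the
inference rules, the generator's movement model, all tunable parameters
with their defaults, and known limitations.
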