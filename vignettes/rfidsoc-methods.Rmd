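---
title: "Methods: from RFID reads to bouts, territories and social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RFID reads to bouts, territories and social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rfidsoc)
```

`rfidsoc` infers space use, territoriality and social structure of
PIT-tagged animals from antenna detections at discrete resource zones.
This vignette documents the inference rules, their assumptions, the
tunable parameters, and the design decisions taken where more than one
reasonable convention exists.

## The data model

A trial is a fixed enclosure (`enclosure_config()`: by default eight
zones on a 2 × 4 grid with 15 m spacing, observed 10 days), a cohort of
animals each carrying up to two PIT tags, and a stream of reads
`(mouse_id, zone_id, t)` on a seconds-since-release axis. Days are
half-open rolling 24 h windows from release (`[0, 86400)` is day 1);
animals are typically released in the evening, so calendar days would
split the first active night — a calendar rule remains available via
`day_boundary_rule`. Reads of an animal after its `last_valid_day`
(death/disappearance) are censored; the animal stays in the metadata so
daily partner-availability denominators and network node sets shrink
correctly.

When parsing raw logs, detections of one mouse at one antenna within
0.5 s are collapsed to a single read. The window corresponds to one
scan cycle at the hardware's 2–3 Hz rate and absorbs both dual-tag
double-detections and scanner bounce; it is configurable
(`dedup_window`), and unknown tag codes are warn-and-dropped by default
(field logs contain ghost reads) with a strict mode for synthetic data.

## Visit bouts

Within a mouse, a read extends the open bout when it is at the same
zone and within the gap threshold of the previous read; otherwise a new
bout opens. Conventions:

* **Threshold 139 s, inclusive.** The packaged default is the
  whole-second 99% quantile of within-zone inter-read intervals
  reported for this kind of data; `estimate_threshold()` recomputes it
  from any read stream (empirical quantile, lower value on ties,
  ceiling to whole seconds). A gap of exactly the threshold extends the
  bout; "within" is read as inclusive.
* **Transitions always split.** A read at a different zone closes the
  open bout at its last read time, regardless of the gap.
* **Isolated reads get 1 s.** A closed bout with a single read receives
  a nominal 1 s duration — a mouse detected once was certainly present,
  briefly. Multi-read bouts span first to last read with no tail
  padding.
* **A bout belongs to the day of its first read.** Bouts spanning a day
  boundary are not split; daily totals attribute such a bout wholly to
  its start day. This keeps bouts atomic and matters little at
  realistic bout lengths (minutes) versus day lengths.

For all time accounting a bout occupies the half-open interval
`[t_start, t_start + duration)`. Using `duration` (rather than
`t_end − t_start`) makes the accounting identity exact: summed
mouse-time over all composition cells equals summed bout durations,
isolated reads included. The convention can in principle let an
isolated read's 1 s interval brush the next bout at another zone; with
any plausible inter-zone travel time (≥ 10 s) this does not occur.

## Associations

Time at each zone is partitioned at every bout endpoint into segments
of constant occupancy (`occupancy_segments()`); maximal chains of
overlapping bouts form "runs". Two framings are exposed, because both
are standard:

* **Instantaneous (segment-based)** for time accounting: mouse-hours by
  group sex composition (each co-present animal's time counts
  separately), time alone, and focal-relative same-/opposite-sex
  association shares (a mixed segment is opposite-sex time for every
  member with at least one other-sex partner; stricter definitions can
  be derived from the segment table).
* **Event-based (chain overlap)** for networks and participation: every
  connected component of the per-zone bout-overlap graph with ≥ 2
  distinct mice is one association event. Chain overlap is chosen over
  pairwise-only grouping because association indices are computed from
  binary event participation; a mouse with several bouts in one
  component counts once. Touching intervals (end = start) do not
  overlap — intervals are half-open — so back-to-back bouts never chain.

Cage-mate preference compares each female's observed share of
female–female overlap time spent with cage mates against a
partner-count null: available cage mates over available female
partners that day (both excluding herself and censored animals). The
null uses partner counts, not partner-time, because availability — not
activity — is the relevant chance expectation. Females with no
female–female time that day are undefined, not zero; a female with no
living cage mates has an undefined deviation and is flagged.

## Territory

Daily, sex-specific occupancy at a zone is an animal's share of all
same-sex bout time there. The capture score sums an animal's occupancy
fractions over zones and subtracts 1 if no zone exceeds 0.5 (strict:
exactly half is not a majority). The priority access score (PAS) is the
running sum of capture scores; a strictly positive final PAS defines
territorial status. The score is sex-generic and is computed for
females with identical rules. An observable animal with no recorded
time on a day scores −1 (zero occupancy everywhere plus the penalty);
censored days contribute 0 and are flagged.

Displacement contests are inferred from male-only occupancy segments: a
single male joined by exactly one other male, followed by one of the two
leaving, is a contest; the leaver loses. Ties (simultaneous departure),
simultaneous arrivals, and episodes reaching three males are excluded
rather than guessed. "Joined" requires strictly positive co-occupancy;
a minimum co-occupancy duration is configurable (default 0 s). Contexts
come from the territory-holder rule — the male with a strict majority of
male-sourced reads at the zone over the rolling 24 h ending at contest
start (`[t − 86400, t)`, read as rolling rather than previous calendar
day); contests with no holder yet (common early) are reported as
neutral and excluded from home/away rates.

Territorial–intruder avoidance over a late-trial window (default the
last six days, when territories are established) compares observed
co-occupancy hours between territorial males (final PAS > 0) and the
rest against `(H × I) / (24 × days × zones)` with `H`, `I` the two
groups' total zone hours.

## Networks

Daily association events over the animals observable that day form a
binary group-by-individual matrix; dyadic weights are the Simple Ratio
Index `x / (x + y_a + y_b)` (0 when neither member attends any event).
Graph metrics are computed in-package with deliberately plain
implementations — breadth-first components (isolated nodes count as
components), edge density over `n(n−1)/2`, binary degree centrality
normalized by `n − 1`, strength as summed incident weights, and page
rank by power iteration (damping 0.85, transition probability
proportional to edge weight, dangling nodes teleporting uniformly;
L1 tolerance 1e−12). The test suite cross-checks all of them against
igraph on random weighted graphs, keeping implementation and oracle
independent. Degree centrality uses the binarized-neighbor convention
common for SRI graphs; a weighted variant is recoverable from the
adjacency matrix, which every network object carries. Networks are per
day; cumulative variants can be built by passing multi-day events to
`gbi_matrix()` directly.

## The synthetic generator

`simulate_trial()` runs an event-driven discrete-choice relocation
process per mouse: alternate zone visits (log-normal durations, mean
`visit_duration_mean` minutes, `sdlog` 1) and at-large periods
(exponential with per-minute hazard `p_move_per_min`, plus a 10 s
minimum inter-zone travel time — the floor stands in for explicit
travel-time draws, which add nothing at the zone-level statistics the
pipeline measures). Zone choice is by preference weights, flattened
toward uniform by `exploration_growth` per elapsed day and multiplied
by `cagemate_bias` for zones currently holding a cage mate. Reads are a
homogeneous Poisson stream at `read_rate_hz` (default 2.5) within each
presence interval, plus one guaranteed read at interval start so
arbitrarily brief visits stay detectable.

In the `territorial_males` scenario, one male per zone (claiming his
release zone when free) becomes its owner from `capture_day` (default
3): owners direct 97% of relocations home (`home_bias`) with 6× longer
stays (`home_visit_mult`). When an owner and a single other male
co-occupy the owned zone, a contest is logged: the owner wins with
`p_home_win` (default 0.82), the loser's visit is truncated after a
10–60 s co-occupancy draw, the winner is retained past the loser's
departure, and the loser avoids that zone on its next relocation (a
fleeing response that also keeps the truncated bout from merging with
an immediate revisit). The ground truth records presence intervals,
the territory map and the contest log, making every downstream stage
testable by parameter recovery.

Two presets bundle sex-specific parameters:

* `c57_like` — exploratory: moderate release-zone preference (weight 4
  vs 1), exploration growth 0.2 (males) / 0.5 (females) per day, weak
  cage-mate bias (1.2/1.5), `p_move` 0.06 per min.
* `wd_like` — site-faithful: strong release-zone preference (weight
  400/600), no exploration growth, strong female cage-mate bias (6),
  lower movement rates (`p_move` 0.02/0.015 per min).

The preset values were chosen so the generator reproduces the
qualitative contrasts this kind of field data shows — broad exploration
reaching all zones with dense, single-component late networks versus
site fidelity with a few cumulative zones, under half of partners ever
met, and sparse fragmented networks — while both share identical
territorial-male dynamics. The generator claims structural, not
quantitative, fidelity: it has no energetics, breeding, infanticide or
explicit space between zones, mice never queue at entrances, read
probability does not depend on position within a zone, and true
movement statistics of wild animals are unknown. Passing
parameter-recovery tests therefore shows the inference is correct for
data generated under its own assumptions, not that field data satisfy
those assumptions.

## Numerical choices and degenerate inputs

* Interval comparisons are half-open throughout; zero-length
  intersections are never overlaps, simultaneous end/start events are
  ordered end-before-start so touching bouts split runs.
* Empty inputs return typed empty tibbles; empty denominators (a mouse
  with no bout time that day, a zone-day with no same-sex reads, a
  network with ≤ 1 node) yield absent rows or `NA`, never silent zeros.
* `estimate_threshold()` on an empty gap set is an error pointing to
  the 139 s default rather than a silent fallback.
* Page rank is iterated to an L1 tolerance of 1e−12 (cap 2000
  iterations), well below any biological signal.
* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; identical seeds give bit-identical trials.

## Problem sizes in the test suite

The suite validates the oracle equivalences on hundreds of randomized
small instances (read streams up to 500 reads, bout sets of ≤ 24 bouts
discretized per second, 50 random weighted graphs) and the end-to-end
parameter recovery on full-size preset trials (10 males, 10 females,
10 days, ~7 million reads), with the preset contrast replicated over
five seed pairs. These sizes exercise every code path at full trial
scale while keeping a complete run of the suite within a few minutes.

## Known limitations

* The gambit of the group: co-presence at a zone is taken as
  association; RFID cannot resolve interaction content or direction.
* Bouts spanning day boundaries are attributed wholly to their start
  day.
* Contest inference requires clean dyadic episodes; crowded zones
  (≥ 3 males) are excluded, and the win/loss assignment assumes the
  loser leaves first, which a simultaneous-departure tie violates
  (such ties are dropped).
* The territory-holder rule needs 24 h of history; day-1 contests are
  mostly neutral-context.
* Sub-zone localization, permutation-based network null models and
  mixed-effects inference are out of scope; `export_model_frame()`
  emits a tidy frame for external modeling tools instead.
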