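# Scenario preset emulating a wild-derived-like trial: site-faithful
# females who stay near the release zone with strong cage-mate bias,
# lower movement rates, territorial males.
name: WD
n_per_cage: 2
male:
  p_move_per_min: 0.02
  visit_duration_mean: 2.5
  visit_duration_sdlog: 1.0
  read_rate_hz: 2.5
  release_zone_weight: 400
  cagemate_bias: 1.5
  exploration_growth: 0
female:
  p_move_per_min: 0.015
  visit_duration_mean: 3.0
  visit_duration_sdlog: 1.0
  read_rate_hz: 2.5
  release_zone_weight: 600
  cagemate_bias: 6
  exploration_growth: 0
territorial:
  capture_day: 3
  p_home_win: 0.82
  home_bias: 0.97
  home_visit_mult: 6
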