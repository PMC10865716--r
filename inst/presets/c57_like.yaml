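# Scenario preset emulating a laboratory-strain-like trial: broadly
# exploring females whose zone preference flattens day by day, weak
# cage-mate bias, territorial males.
name: C57
n_per_cage: 2
male:
  p_move_per_min: 0.06
  visit_duration_mean: 1.5
  visit_duration_sdlog: 1.0
  read_rate_hz: 2.5
  release_zone_weight: 4
  cagemate_bias: 1.2
  exploration_growth: 0.2
female:
  p_move_per_min: 0.06
  visit_duration_mean: 1.5
  visit_duration_sdlog: 1.0
  read_rate_hz: 2.5
  release_zone_weight: 4
  cagemate_bias: 1.5
  exploration_growth: 0.5
territorial:
  capture_day: 3
  p_home_win: 0.82
  home_bias: 0.97
  home_visit_mult: 6
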