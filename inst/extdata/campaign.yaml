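# Default campaign configuration: 4 waves of 14 days, intake transformation
# constants, cap bounds per dynamic task, fixed capability fallbacks, and the
# generic control-arm schedule.
W: 4
wave_days: 14
stride_m: 0.73
walks_per_day: 3
rides_per_week: 5
goal_uplift: 1.1
goal_sports_increment: 1
caps:
  walk: [1000, 10000]
  ride: [2000, 17500]
  sports: [2, 10]
capability_defaults:
  walk: 1000
  ride: 2000
  sports: 2
control_schedule:
  - {wave: 1, min_walk_distance: 1500, min_ride_distance: 3500, rewarded_sports_sessions: 4}
  - {wave: 2, min_walk_distance: 2000, min_ride_distance: 4000, rewarded_sports_sessions: 4}
  - {wave: 3, min_walk_distance: 2250, min_ride_distance: 4250, rewarded_sports_sessions: 5}
  - {wave: 4, min_walk_distance: 2500, min_ride_distance: 4500, rewarded_sports_sessions: 5}
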