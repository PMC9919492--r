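# Null preset: identical marginal walk rate in every hour-of-week cell.
# Walking carries no temporal signal, so no classifier should beat chance
# after class balancing.
name: "null"
n_participants: 41
n_days: 43
walks_per_day: 2.6
missing_day_prob: 0.369
background_minutes_per_day: 119
hour_profile: [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
               1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
dow_multiplier: [1, 1, 1, 1, 1, 1, 1]
bout_duration:
  family: lognormal
  meanlog: 2.05
  sdlog: 0.70
  floor: 5
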