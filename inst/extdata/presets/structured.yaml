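# Structured preset: walk mass concentrated into weekday commute and lunch
# hours. Hour-of-day (and recent-history) features are strongly predictive,
# so a competent classifier clears chance by a wide margin.
name: structured
n_participants: 41
n_days: 43
walks_per_day: 2.6
missing_day_prob: 0.369
background_minutes_per_day: 119
hour_profile: [0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
               0.0, 0.30, 0.30, 0.0, 0.0, 0.0,
               0.15, 0.0, 0.0, 0.0, 0.0, 0.15,
               0.10, 0.0, 0.0, 0.0, 0.0, 0.0]
dow_multiplier: [1.0, 1.0, 1.0, 1.0, 1.0, 0.1, 0.1]
bout_duration:
  family: lognormal
  meanlog: 2.05
  sdlog: 0.70
  floor: 5
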