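# Default synthetic cohort: circadian weekday structure with morning, lunch
# and evening walk peaks, slightly quieter weekends, ~2.6 detected walk
# bouts per recorded day of mean length ~10.3 min, ~36.9% of days missing.
name: default
n_participants: 41
n_days: 43
walks_per_day: 2.70
missing_day_prob: 0.369
background_minutes_per_day: 119
hour_profile: [0.0, 0.0, 0.0, 0.0, 0.0, 0.01,
               0.06, 0.10, 0.11, 0.07, 0.05, 0.06,
               0.10, 0.07, 0.05, 0.05, 0.07, 0.10,
               0.09, 0.06, 0.04, 0.02, 0.01, 0.0]
dow_multiplier: [1.0, 1.0, 1.0, 1.0, 1.0, 0.85, 0.85]
bout_duration:
  family: lognormal
  meanlog: 2.05
  sdlog: 0.70
  floor: 5
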