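[
  {"id": "a1", "period": 1, "timestamp": "00:00:12.400",
   "possession_team": {"id": 1, "name": "Synth Town"},
   "type": {"id": 30, "name": "Pass"}, "duration": 1.8,
   "location": [45.0, 32.5]},
  {"id": "a2", "period": 1, "timestamp": "00:10:03.000",
   "possession_team": {"id": 2, "name": "Fiction United"},
   "type": {"id": 43, "name": "Carry"}, "duration": 3.2,
   "location": [78.4, 61.0]},
  {"id": "a3", "period": 1, "timestamp": "00:20:00.000",
   "possession_team": {"id": 1, "name": "Synth Town"},
   "type": {"id": 18, "name": "Half Start"}},
  {"id": "a4", "period": 2, "timestamp": "00:05:40.250",
   "possession_team": {"id": 1, "name": "Synth Town"},
   "type": {"id": 16, "name": "Shot"}, "duration": 0.9,
   "location": [112.2, 41.7]},
  {"id": "a5", "period": 5, "timestamp": "00:01:00.000",
   "possession_team": {"id": 2, "name": "Fiction United"},
   "type": {"id": 30, "name": "Pass"}, "duration": 1.0,
   "location": [60.0, 40.0]}
]
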