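{
  "schema_version": 1,
  "days": 365,
  "start_date": "2023-01-01",
  "dt": 20,
  "out_dt": 60,
  "entrain_days": 7,
  "scenarios": ["daylight", "electric", "dimming"],
  "sleep_types": ["scheduled", "disrupted"],
  "view_depths": [0, 0.5, 1],
  "plots": false
}
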