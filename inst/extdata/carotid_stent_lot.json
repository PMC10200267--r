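{
  "lot_id": "carotid-stents-2021",
  "horizon_months": 12,
  "baseline_utility": 0.93,
  "wtp_per_qaly": 60000,
  "starting_price": 600,
  "days_per_year": 365,
  "currency_label": "euro",
  "endpoints": [
    {
      "endpoint_id": "minor_stroke",
      "label": "minor stroke",
      "disutility": 0.15,
      "duration_months": 3,
      "cost_per_event": 6000
    },
    {
      "endpoint_id": "major_stroke",
      "label": "major stroke",
      "disutility": 0.55,
      "duration_months": 12,
      "cost_per_event": 72210.3125
    },
    {
      "endpoint_id": "death",
      "label": "death",
      "disutility": 0.93,
      "duration_months": 12,
      "cost_per_event": 150000
    }
  ]
}
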