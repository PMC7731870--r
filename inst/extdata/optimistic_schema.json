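{
  "id": "facility_id",
  "factors": {
    "pre_rate": {"kind": "numeric"},
    "during_rate": {"kind": "numeric"},
    "don_turnover": {"kind": "crisp"},
    "support": {"kind": "crisp"},
    "low_baseline": {"kind": "crisp"},
    "chess": {"kind": "crisp"}
  },
  "outcomes": ["decline10", "decline20"]
}
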