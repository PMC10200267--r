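{
  "comment": "Published intermediate totals for the ABBOTT step trace, supplied as given step inputs (see NOTES). NON-AUTHORITATIVE for any other device.",
  "ABBOTT": {
    "disutility_qalds": 26.2625,
    "cost_total": 891.5365
  }
}
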