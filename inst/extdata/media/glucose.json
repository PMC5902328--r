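{
  "name": "glucose",
  "sugar_budget": 10,
  "components": [
    {"metabolite": "thr_e", "category": "limited_uptake", "bound": 1},
    {"metabolite": "nh4_e", "category": "non_limiting"},
    {"metabolite": "h2o_e", "category": "non_limiting"},
    {"metabolite": "pi_e", "category": "non_limiting"},
    {"metabolite": "ac_e", "category": "secretion_only"},
    {"metabolite": "ppa_e", "category": "secretion_only"},
    {"metabolite": "glc_e", "category": "sugar"}
  ]
}
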