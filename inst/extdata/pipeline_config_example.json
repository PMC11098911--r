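{
  "simulate": {"scale": 1, "seed": 20221208, "write": false},
  "primary": "catatonia",
  "features": ["malignant catatonia", "withdrawal catatonia", "automatism",
               "echolalia", "echopraxia", "posturing", "waxy flexibility"],
  "co_occurrence": ["agitation", "eating disorder", "speech disorder",
                    "stereotypy", "social avoidant behaviour"],
  "bands": ["infant", "child", "adolescent"],
  "min_cases": 5,
  "roles": ["suspect", "interacting"],
  "background": "stratum",
  "hcp": ["physician", "pharmacist", "other_health_professional"],
  "out_dir": "pvsignal-out"
}
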