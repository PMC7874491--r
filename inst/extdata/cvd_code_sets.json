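{
  "narrow": {
    "icd_include": ["I63", "I64", "I20.0", "I21", "I22", "I24", "I25", "I73.9", "I70.2"],
    "icd_exclude": ["I25.3", "I25.4", "I25.10", "I25.19"],
    "ops_include": ["5-361", "5-362", "5-363", "8-836", "8-837", "8-84"]
  },
  "narrow_chf": {
    "icd_include": ["I63", "I64", "I20.0", "I21", "I22", "I24", "I25", "I73.9", "I70.2", "I50"],
    "icd_exclude": ["I25.3", "I25.4", "I25.10", "I25.19"],
    "ops_include": ["5-361", "5-362", "5-363", "8-836", "8-837", "8-84"]
  },
  "wide": {
    "icd_include": ["I20", "I21", "I22", "I23", "I24", "I25", "I60", "I61", "I62", "I63", "I64", "I73.9", "I70.2", "I50"],
    "icd_exclude": [],
    "ops_include": ["5-361", "5-362", "5-363", "8-836", "8-837", "8-84"]
  }
}
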