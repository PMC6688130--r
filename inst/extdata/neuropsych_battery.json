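[
  {
    "test": "mmse",
    "domain": "global",
    "higher_is_better": true
  },
  {
    "test": "ravlt_total",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "ravlt_delayed",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "ravlt_immediate",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "rcf_3min",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "rcf_20min",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "wlm_delayed",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "wlm_immediate",
    "domain": "memory",
    "higher_is_better": true
  },
  {
    "test": "bnt",
    "domain": "language",
    "higher_is_better": true
  },
  {
    "test": "verbal_fluency_fas",
    "domain": "language",
    "higher_is_better": true
  },
  {
    "test": "similarities",
    "domain": "language",
    "higher_is_better": true
  },
  {
    "test": "token_test_5",
    "domain": "language",
    "higher_is_better": true
  },
  {
    "test": "digit_span",
    "domain": "attention",
    "higher_is_better": true
  },
  {
    "test": "digit_symbol",
    "domain": "attention",
    "higher_is_better": true
  },
  {
    "test": "tmt_a",
    "domain": "attention",
    "higher_is_better": false
  },
  {
    "test": "tmt_b",
    "domain": "attention",
    "higher_is_better": false
  },
  {
    "test": "block_design",
    "domain": "spatial",
    "higher_is_better": true
  },
  {
    "test": "rcf_copy",
    "domain": "spatial",
    "higher_is_better": true
  },
  {
    "test": "silhouettes",
    "domain": "spatial",
    "higher_is_better": true
  },
  {
    "test": "letter_digit",
    "domain": "executive",
    "higher_is_better": true
  },
  {
    "test": "pasmo",
    "domain": "executive",
    "higher_is_better": false
  },
  {
    "test": "stroop_1",
    "domain": "executive",
    "higher_is_better": false
  },
  {
    "test": "stroop_2",
    "domain": "executive",
    "higher_is_better": false
  },
  {
    "test": "stroop_3",
    "domain": "executive",
    "higher_is_better": false
  },
  {
    "test": "stroop_effect",
    "domain": "executive",
    "higher_is_better": false
  }
]
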