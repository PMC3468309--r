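[
  {
    "id": 1,
    "name": "reference",
    "mode": "period",
    "rr_null": false
  },
  {
    "id": 2,
    "name": "rr_null",
    "mode": "period",
    "rr_null": true
  },
  {
    "id": 3,
    "name": "all_smokers",
    "mode": "cohort",
    "cumulative_initiation": {
      "female": 1,
      "male": 1
    },
    "cessation_multiplier": 0,
    "rr_null": false
  },
  {
    "id": 4,
    "name": "rates_1950s",
    "mode": "cohort",
    "cumulative_initiation": {
      "female": 0.55,
      "male": 0.8
    },
    "cessation_multiplier": 0.5,
    "rr_null": false
  },
  {
    "id": 5,
    "name": "rates_2004",
    "mode": "cohort",
    "rr_null": false
  },
  {
    "id": 6,
    "name": "no_smoking",
    "mode": "cohort",
    "cumulative_initiation": {
      "female": 0,
      "male": 0
    },
    "rr_null": false
  }
]
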