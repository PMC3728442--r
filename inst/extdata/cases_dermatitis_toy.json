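[
  {
    "case_id": ["toy_bp"],
    "subdomain": ["SVD"],
    "acceptable_dx": [
      ["bullous pemphigoid"]
    ],
    "true_findings": [
      ["blister"],
      ["subepidermal split"],
      ["eosinophils"]
    ]
  },
  {
    "case_id": ["toy_dh"],
    "subdomain": ["SVD"],
    "acceptable_dx": [
      ["dermatitis herpetiformis"]
    ],
    "true_findings": [
      ["blister"],
      ["neutrophils"]
    ]
  },
  {
    "case_id": ["toy_sar"],
    "subdomain": ["NDD"],
    "acceptable_dx": [
      ["sarcoidosis"]
    ],
    "true_findings": [
      ["granuloma"]
    ]
  },
  {
    "case_id": ["toy_acne"],
    "subdomain": ["NDD"],
    "acceptable_dx": [
      ["acne conglobata"]
    ],
    "true_findings": [
      ["comedones"]
    ]
  }
]
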