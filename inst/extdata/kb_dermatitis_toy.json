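{
  "findings": ["blister", "subepidermal split", "eosinophils", "neutrophils", "granuloma", "comedones"],
  "diagnoses": ["bullous pemphigoid", "dermatitis herpetiformis", "acne conglobata", "sarcoidosis"],
  "relations": [
    {
      "finding": ["blister"],
      "diagnosis": ["bullous pemphigoid"],
      "polarity": ["support"]
    },
    {
      "finding": ["subepidermal split"],
      "diagnosis": ["bullous pemphigoid"],
      "polarity": ["support"]
    },
    {
      "finding": ["eosinophils"],
      "diagnosis": ["bullous pemphigoid"],
      "polarity": ["support"]
    },
    {
      "finding": ["blister"],
      "diagnosis": ["dermatitis herpetiformis"],
      "polarity": ["support"]
    },
    {
      "finding": ["neutrophils"],
      "diagnosis": ["dermatitis herpetiformis"],
      "polarity": ["support"]
    },
    {
      "finding": ["granuloma"],
      "diagnosis": ["sarcoidosis"],
      "polarity": ["support"]
    },
    {
      "finding": ["comedones"],
      "diagnosis": ["acne conglobata"],
      "polarity": ["support"]
    },
    {
      "finding": ["eosinophils"],
      "diagnosis": ["dermatitis herpetiformis"],
      "polarity": ["refute"]
    }
  ],
  "taught_pairs": [
    ["blister", "bullous pemphigoid"],
    ["neutrophils", "dermatitis herpetiformis"],
    ["granuloma", "sarcoidosis"],
    ["comedones", "acne conglobata"]
  ]
}
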