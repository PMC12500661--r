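# Benefit-risk value tree for the NSCLC case study: chemotherapy alone
# (control) vs chemotherapy plus an adjuvant herbal decoction
# (experimental). Anchors are on the scale of the pooled per-arm outcome;
# KPS change is reported signed, so its magnitude is anchored.
version: 1
benefit_weight: 0.75
risk_weight: 0.25
criteria:
  - id: kps
    label: KPS score change
    category: benefit
    swing_weight: 80
    optimal: 11
    worst: 2
    direction: higher_is_better
    magnitude: true
  - id: ca211
    label: CA211 (CYFRA 21-1) reduction
    category: benefit
    swing_weight: 60
    optimal: 6
    worst: 3
    direction: higher_is_better
  - id: cea
    label: CEA reduction
    category: benefit
    swing_weight: 60
    optimal: 12
    worst: 6
    direction: higher_is_better
  - id: fatigue
    label: Cancer Fatigue Scale score change
    category: benefit
    swing_weight: 100
    optimal: 18
    worst: 0
    direction: higher_is_better
  - id: gi
    label: Gastrointestinal adverse reaction incidence
    category: risk
    swing_weight: 100
    optimal: 0
    worst: 1
    direction: lower_is_better
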