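age_bands:
- label: 0-6
  lower: 0.0
  upper: 6.0
- label: 7-17
  lower: 7.0
  upper: 17.0
- label: 18-45
  lower: 18.0
  upper: 45.0
- label: 46-59
  lower: 46.0
  upper: 59.0
- label: 60-79
  lower: 60.0
  upper: 79.0
- label: 80+
  lower: 80.0
  upper: inf
visit_levels:
- label: v1
  lower: 1.0
  upper: 1.0
- label: v2-3
  lower: 2.0
  upper: 3.0
- label: v4-5
  lower: 4.0
  upper: 5.0
- label: v6+
  lower: 6.0
  upper: inf
rules:
- pattern: hosp
  when:
    hosp: pos
  axes:
  - contract
  - age
  - sex
  - visits
- pattern: spchron
  when:
    sop: pos
    cop: pos
- pattern: special
  when:
    sop: pos
    cop: zero
- pattern: childchron
  when:
    cop: pos
    age_max: 6.0
- pattern: chronic
  when:
    cop: pos
    age_min: 7.0
  axes:
  - contract
  - age
  - visits
  age_bands:
  - label: 7-45
    lower: 7.0
    upper: 45.0
  - label: 46-59
    lower: 46.0
    upper: 59.0
  - label: 60+
    lower: 60.0
    upper: inf
  visit_levels:
  - label: v1
    lower: 1.0
    upper: 1.0
  - label: v2-3
    lower: 2.0
    upper: 3.0
  - label: v4+
    lower: 4.0
    upper: inf
- pattern: gop
  when:
    gop: pos
  axes:
  - contract
  - age
  - sex
  - visits
- pattern: nonatt
  when:
    attender: no
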