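ndc:
  IFN:
  - '60000000101'
  - '60000000102'
  - '60000000103'
  - '60000000104'
  GA: '60000000201'
  fingolimod: '60000000301'
  natalizumab: '60000000401'
  dalfampridine: '60000000501'
  oral_corticosteroid:
  - '60000000601'
  - '60000000602'
procedure:
  IFN: PIFN01
  GA: PGA01
  natalizumab: PNTZ01
  iv_corticosteroid: PIVS01
icd:
  ms: '340'
  exclusionary_primary:
  - '493'
  - '274'
  - '714'
  - '364'
  comorbidities:
    depression:
    - '296'
    - '311'
    diabetes: '250'
    dyslipidemia: '272'
    tobacco: '3051'
    cvd:
    - '410'
    - '411'
    - '412'
    - '413'
    - '414'
    - '428'
  symptoms:
    numbness: '7820'
    fatigue: '7807'
    bowel:
    - '5640'
    - '5641'
    headache: '7840'
    muscle:
    - '72885'
    - '7281'
    visual: '368'
    bladder: '5966'
    dizziness: '7804'
    respiration: '7860'
    walking:
    - '7812'
    - '7813'
charlson:
  mi:
    weight: 1
    prefixes:
    - '410'
    - '412'
  chf:
    weight: 1
    prefixes: '428'
  copd:
    weight: 1
    prefixes:
    - '490'
    - '491'
    - '492'
    - '496'
  diabetes:
    weight: 1
    prefixes: '250'
  liver_mild:
    weight: 1
    prefixes: '571'
  renal:
    weight: 2
    prefixes:
    - '582'
    - '585'
    - '586'
  cancer:
    weight: 2
    prefixes:
    - '140'
    - '162'
    - '174'
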