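# Default configuration for the psadapt tumor-evolution model.
# Every value here equals the package default; the file is a tested
# fixture, so editing a copy of it is the supported way to explore
# alternative parameterizations.

model:
  # PSA produced by one metastatic prostate cancer cell per 24 h (ng/mL).
  psa_per_cell: 9.8e-9
  # Shared logistic carrying capacity, expressed in PSA units (ng/mL);
  # the cell-count capacity is ccap_psa / psa_per_cell (~1.02e11 cells).
  ccap_psa: 1000
  # Fraction of surviving sensitive cells acquiring resistance per day
  # under a matched therapy (0.00005%).
  mutation_rate: 5.0e-7
  # Daily kill fraction an ADT applies to each sensitive phenotype.
  adt1_kill: 0.03
  adt2_kill: 0.03
  # Chemotherapy kill is ct_kill_coef * p (proportional to division
  # attempts).
  ct_kill_coef: 1.5
  # Bisphosphonate palliation multiplies every phenotype's proliferation
  # by (1 - bisph_damp); all clones are slowed equally and still grow
  # toward the carrying capacity.
  bisph_damp: 0.3
  # Default fraction of cells removed by a one-time debulking event
  # (surgery / radiotherapy) when the record does not state one.
  debulk_fraction: 0.9
  # Per-day proliferation (p) and apoptosis (a) fractions. NAIVE uses
  # literature-derived constants; ADT1R uses the measured pre-abiraterone
  # proliferative/apoptotic indices (2.42% / 1.68%); ADT2R uses the
  # post-abiraterone indices (1.09% / 0.02%). The chemo-resistant rows are
  # placeholders encoding chemo resistance as a 0.005/day proliferation
  # cost relative to the chemo-sensitive counterpart.
  baseline_rates:
    NAIVE:     {p: 0.0204, a: 0.0076}
    ADT1R:     {p: 0.0242, a: 0.0168}
    ADT2R:     {p: 0.0109, a: 0.0002}
    CTR:       {p: 0.0154, a: 0.0076}
    ADT1R_CTR: {p: 0.0192, a: 0.0168}
    ADT2R_CTR: {p: 0.0059, a: 0.0002}
  # Treatment-conditioned growth-rate overrides: ADT1R exposed to ADT2
  # grows with the post-abiraterone indices.
  rate_overrides:
    ADT2:
      ADT1R: {p: 0.0109, a: 0.0002}
  # Therapies each phenotype escapes. ADT2R (and ADT2R_CTR) escape both
  # ADT generations.
  resistant_to:
    NAIVE: []
    ADT1R: [ADT1]
    ADT2R: [ADT1, ADT2]
    CTR: [CT]
    ADT1R_CTR: [ADT1, CT]
    ADT2R_CTR: [ADT1, ADT2, CT]
  # Which resistant phenotype each (phenotype, therapy) pair spawns.
  # The two transitions out of CTR are inferences that close the graph
  # (a chemo-resistant clone escaping an ADT becomes doubly resistant).
  transitions:
    - {from: NAIVE, treatment: ADT1, to: ADT1R}
    - {from: NAIVE, treatment: ADT2, to: ADT2R}
    - {from: NAIVE, treatment: CT, to: CTR}
    - {from: ADT1R, treatment: ADT2, to: ADT2R}
    - {from: ADT1R, treatment: CT, to: ADT1R_CTR}
    - {from: ADT2R, treatment: CT, to: ADT2R_CTR}
    - {from: CTR, treatment: ADT1, to: ADT1R_CTR}
    - {from: CTR, treatment: ADT2, to: ADT2R_CTR}
    - {from: ADT1R_CTR, treatment: ADT2, to: ADT2R_CTR}

scheduler:
  # Intervene once total burden exceeds the cell equivalent of 1 ng/mL
  # of PSA (~1.02e8 cells).
  intervention_threshold_psa: 1.0
  # 28-day cycles: 3 weeks of therapy, 1 week holiday.
  cycle_days: 28
  on_days: 21
  # Conjectured clinical endpoint (= the carrying capacity).
  endpoint_psa: 1000
  max_days: 10000
  # The model approaches capacity from below; the endpoint fires within
  # this relative tolerance of endpoint_psa.
  endpoint_rel_tol: 1.0e-6
  # Therapy applied when each phenotype is the largest clone. CTR and
  # ADT1R_CTR get the first-line ADT still effective against them.
  case_map:
    NAIVE: ADT1
    ADT1R: ADT2
    ADT2R: CT
    CTR: ADT1
    ADT1R_CTR: ADT2
    ADT2R_CTR: BISPH
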