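# Default configuration: the published base-case inputs.
#
# All parameter values are the published ones (unit costs, utilities with
# their Beta PSA parameters, monthly transition probabilities with their
# Beta/Dirichlet pseudo-counts). Two quantities the publication leaves
# unstated are completed here and documented in the methods vignette:
#   * initial_distribution -- the starting mix over the four pain states,
#     reconstructed by calibrate_initial_distribution() against the
#     published base-case totals (see vignette); an equal 0.25 split is the
#     uncalibrated alternative.
#   * life_table -- "bundled" selects the synthetic Gompertz table shipped
#     with the package (background mortality for women aged 32-50 is tiny).
model:
  start_age: 32
  end_age: 50
  cycle_length_months: 1
  annual_discount_rate: 0.035
  discount_compounding: compound
  half_cycle_correction: true
  initial_distribution:
    no_pain: 0.065448
    mild: 0.454471
    moderate: 0.470625
    severe: 0.009456
costs:
  gp_visit_cost: 26.67
  gp_interval_months:
    nht: 3
    oc: 6
  gp_cost_mode: amortised
  # Combined oral contraceptive (Microgynon): 2.82 GBP buys a 63-tablet
  # pack, i.e. three 28-day cycles -> 0.94 GBP per monthly cycle.
  oc_pack_cost: 2.82
  oc_pack_months: 3
  # maximum-dose monthly analgesic costs ("usual care per cycle")
  paracetamol_month_max: 2.31
  ibuprofen_month_max: 2.43
  # dose scaling by pain state: none / half paracetamol / full paracetamol /
  # full paracetamol + full ibuprofen
  analgesic_scaling:
    no_pain:  {paracetamol: 0.0, ibuprofen: 0.0}
    mild:     {paracetamol: 0.5, ibuprofen: 0.0}
    moderate: {paracetamol: 1.0, ibuprofen: 0.0}
    severe:   {paracetamol: 1.0, ibuprofen: 1.0}
  # coefficient of variation assumed for the Gamma cost distributions (PSA)
  cost_cv: 0.2
utilities:
  no_pain:  {mean: 0.905, alpha: 27.357, beta: 3.153}
  mild:     {mean: 0.802, alpha: 82.023, beta: 18.242}
  moderate: {mean: 0.718, alpha: 55.931, beta: 22.142}
  severe:   {mean: 0.573, alpha: 19.336, beta: 14.487}
transitions:
  nht:
    no_pain:
      mild:     {p: 0.003,  alpha: 3,   beta: 997}
    mild:
      no_pain:  {p: 0.002,  alpha: 2,   beta: 998}
      moderate: {p: 0.002,  alpha: 2,   beta: 998}
    moderate:
      mild:     {p: 0.001,  alpha: 1,   beta: 999}
      severe:   {p: 0.003,  alpha: 3,   beta: 997}
    severe:
      moderate: {p: 0.0001, alpha: 0.1, beta: 999.9}
  oc:
    no_pain:
      mild:     {p: 0.001,  alpha: 1,   beta: 999}
    mild:
      no_pain:  {p: 0.003,  alpha: 3,   beta: 997}
      moderate: {p: 0.0015, alpha: 1.5, beta: 998.5}
    moderate:
      mild:     {p: 0.003,  alpha: 3,   beta: 997}
      severe:   {p: 0.0001, alpha: 0.1, beta: 999.9}
    severe:
      moderate: {p: 0.004,  alpha: 4,   beta: 996}
psa:
  n_draws: 1000
  seed: 42
life_table: bundled
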