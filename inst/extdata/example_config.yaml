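# Example run configuration: a synthetic spontaneous-report database with a
# known ground truth. Replace the `synthetic` block with a `tables` block
# (paths to the four delimited files plus a dialect) to analyze real data:
#
# tables:
#   demo: demo.csv
#   drug: drug.csv
#   reac: reac.csv
#   hist: hist.csv
#   dialect: jader        # or "default" for canonical UTF-8 CSV

synthetic:
  n_reports: 6000
  seed: 2024
  drug_panel: {cisplatin: 0.08, carboplatin: 0.05, gemcitabine: 0.03}
  cancer_panel: {lung: 0.06, renal: 0.04}
  event_model:
    intercept: -3.2
    coefficients:
      sex_female: 0.2852        # log(1.33)
      age_ge60: 1.0043          # log(2.73)
      lung: 0.3988              # log(1.49)
      cisplatin: 1.3987         # log(4.05)
      "cisplatin:lung": 0.4055  # log(1.50)
  onset_model:
    cisplatin: {scale: 10.38, shape: 0.98}
  missingness: {sex: 0.01, age: 0.02, start_date: 0.1, onset_date: 0.1}

# case definition: preferred terms counted as the target adverse event
event_terms: [Hyponatraemia]

# analysis panels: label -> drug names / condition terms
drug_panel:
  cisplatin: [cisplatin]
  carboplatin: [carboplatin]
  gemcitabine: [gemcitabine]
cancer_panels:
  lung: [Lung cancer]
  renal: [Renal cancer]

# adjusted logistic model
model:
  main: [reporting_year, sex_female, age_ge60, lung, renal, cisplatin]
  interactions:
    - [cisplatin, lung]
    - [cisplatin, sex_female]

# time-to-onset analysis
onset:
  drug: cisplatin
  window_days: 365

min_cases: 10
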