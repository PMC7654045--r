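# Sample synthetic-study scenario: declining seasonal amplitude and slowly
# improving baseline mortality across 19th-century birth cohorts.
# `from`/`to` pairs are interpolated linearly across the birth years.
birth_years:
  from: 1800
  to: 1901
sexes:
  - female
  - male
cohort_size: 20000
seed: 1
mu:
  from: 5.6e-5
  to: 3.4e-5
beta: 2.4e-4
alpha:
  from: 0.33
  to: 0.07
theta: -0.70516
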