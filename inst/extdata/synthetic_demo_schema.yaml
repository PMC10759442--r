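id:
  role: id
  type: continuous
unmet_financial:
  role: outcome
  type: binary
unmet_nonfinancial:
  role: outcome
  type: binary
income:
  role: ranking
  type: continuous
  units: RMB, 2011 prices
ln_income:
  role: covariate
  type: continuous
  units: log RMB
age:
  role: covariate
  type: continuous
shi:
  role: covariate
  type: binary
education:
  role: covariate
  type: categorical
  levels:
  - Illiterate
  - Primary school
  - Middle school
  - High school and above
  reference: Illiterate
chronic:
  role: covariate
  type: binary
urban:
  role: covariate
  type: binary
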