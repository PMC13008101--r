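# Base-case configuration: metabolic syndrome population, screening age 50.
# Anything omitted takes the documented package default and is recorded in
# the provenance log. See ?load_parameters for the full schema.
population: mets
start_age: 50
max_age: 100
# life_table: path to a two-column file (age, qx); omitted here, so the
# synthetic Gompertz life table ships in (see lifetable_synthetic_thai.tsv)
econ:
  discount: 0.03
  wtp: 160000
  thb_per_usd: 34.64
  ctc_ratio: 1.0
psa:
  n: 1000
  seed: 1
seed: 1
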