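# Base-case configuration: obesity population (BMI >= 25), screening age 50.
population: obesity
start_age: 50
max_age: 100
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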