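# Base-case inputs: perfect-use OC failure versus OC with enzyme-inducing or
# enzyme-neutral co-medication, four-way unintended-pregnancy outcome
# distribution, 2020-USD direct medical unit costs (payer perspective,
# literature medians with min-max ranges), mistimed-birth cost adjustment,
# and a 1,000-woman closed cohort followed monthly for one year.
#
# Rates are annual failures per 100 woman-years (Pearl index), stored as
# published; the engine divides by 100 when converting to probabilities.
# costs.birth_adjusted is the published pre-tabulated adjusted summary, kept
# for reference; the engine recomputes the adjustment from costs.birth.
schema_version: 1
strategies:
  - name: "OC alone"
    rate_point: 0.3
  - name: "OC + enzyme inducer"
    rate_point: 2.3
    rate_low: 1.9
    rate_high: 2.8
  - name: "OC + enzyme neutral"
    rate_point: 1.6
    rate_low: 1.4
    rate_high: 1.8
outcomes:
  birth: 0.492
  induced_abortion: 0.350
  spontaneous_abortion: 0.153
  ectopic: 0.005
costs:
  birth: {median: 12953, min: 5270, max: 28664}
  birth_adjusted: {median: 5497, min: 2290, max: 12453}
  induced_abortion: {median: 940, min: 601, max: 4233}
  spontaneous_abortion: {median: 1121, min: 601, max: 3594}
  ectopic: {median: 6174, min: 2840, max: 15943}
adjustment:
  f: 0.60
  disc_rate: 0.03
  delay_years: 2
settings:
  cohort_size: 1000
  cycle_length: "1/12"
  n_cycles: 12
  seed: 20211118
# Only the typical-use scenario has published parameter values; the
# abortion-share and age-specific scenarios need user-supplied inputs
# (state abortion shares, age-group outcome mixes) and ship no defaults.
scenarios:
  typical_use:
    kind: typical_use
    typical: 7.2
    perfect: 0.3
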