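# Annotated example configuration for wolfpva::run_config().
# Every field is optional; omitted fields use the packaged defaults.

seed: 1              # master seed; all randomness derives from it
iterations: 100      # Monte-Carlo iterations per scenario
years: 100           # simulation horizon in years

# Starting populations. Either point `pedigree` at a tab-delimited studbook
# (columns id, sire, dam, sex, birth_year, location; unknown parent = 0) or
# leave it null to generate the synthetic captive history.
pedigree: null
population:
  n_founders: 7      # founders of the captive population
  generations: 6     # generations of historical captive breeding
  cohort_size: 120   # individuals per generation
  initial_n: null    # wild starting census (null = parameter set's value)

# Parameter sets. Null uses default_parameter_sets(); otherwise give YAML
# files written by write_params() for each parameterization.
params: null
# params:
#   p2013: fixtures/params_2013.yaml
#   p2017: fixtures/params_2017.yaml

scenario:
  use: "2017"        # which set the `simulate` command runs

surface:
  caps: [100, 200, 300, 400, 500, 600, 700, 800, 900, 1000]
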