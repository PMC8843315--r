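# Example run configuration: synthetic condition tables for both population
# groups, costed with explicit allocation bases, projected services for
# adults and a fixed service count for children.
seed: 42
probabilities: [0.5, 0.75, 0.9]
budget: 1.0e+9
dialect: exact
shape: triangular
bases:
  annual_working_minutes: 105600   # 1,760 hours/year
  lifespan_years: 5
  annual_use_minutes: 40000
groups:
  adult:
    generator:
      n_conditions: 58
    projection:
      population: 1.0e+6
      growth_rate: 0.015
      utilisation: 2
      coverage: 0.9
      coverage_increase: 0.05
      visits_per_episode: 6
  child:
    generator:
      n_conditions: 40
      population_group: child
    services: 250000
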