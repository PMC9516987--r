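# Example sdqmap pipeline configuration (desk scale).
# Run with: Rscript inst/scripts/run_pipeline.R --config example-config.yaml --out out/
base_seed: 1
n_wards: 21
n_children: 5000
n_preschools: 60
cohorts: [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017]
contamination:
  missing_dob: 0.02
  invalid_postcode: 0.02
  out_of_area: 0.01
  out_of_age: 0.01
  missing_score: 0.05
median_outcome_dm: true
dm:
  covariates: [prop_off_age, prop_most_deprived, prop_boys]
  n_iter: 2000
  n_burnin: 1000
  n_chains: 2
ml:
  n_iter: 800
  n_burnin: 500
  n_chains: 2
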