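# Demo pipeline configuration: simulate a small survey and run every stage
# with a reduced MCMC profile. Usage:
#   cfg <- pipeline_config(system.file("extdata", "demo_config.yaml",
#                                      package = "trailuse"))
#   run_pipeline(cfg, out_dir = "demo_run")
simulate:
  seed: 1
  n_arrays: 6
  stations_per_array: 10
  baseline_log_rate: 3.4
  recreation_lognormal_mu: 3.2
species: deer
profile: test
mcmc:
  iterations: 3000
  burn_in: 500
  thin: 2
seed: 1
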