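# full-scale study runs (1700 samples, h = 64, GWO 30 x 300) at three seeds,
# shared by the statistical-reproduction acceptance blocks; built lazily and
# memoised so the cost is paid once per test run
acceptance_runs <- function(seeds = 1:3) {
  fixture("acceptance_runs", function() {
    lapply(seeds, function(s) run_study(default_config(seed = s),
                                        verbose = FALSE))
  })
}

summary_value <- function(run, method, snr, metric) {
  s <- run$summary
  s[[metric]][s$method == method & s$snr_db == snr]
}
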