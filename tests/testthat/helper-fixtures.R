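# Shared fixtures, built once per test run. Expensive objects are memoized
# in this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# gravity-only recording: fixed arbitrary orientation, no motion or noise
gravity_recording <- function(n = 1200, fs = 10, dir = c(0.3, -0.5, 0.8)) {
  u <- dir / sqrt(sum(dir^2))
  raw_recording(rep(u[1], n), rep(u[2], n), rep(u[3], n), fs = fs)
}

# short synthetic recording with movement, for structural tests (~20 min)
short_synth <- function() memo("short_synth", function()
  generate_recording(scenario_params(duration_s = 1200, seed = 101)))

# medium recording (2 h) for distributional/property tests
medium_synth <- function() memo("medium_synth", function()
  generate_recording(scenario_params(duration_s = 7200, seed = 202)))

medium_datasets <- function() memo("medium_datasets", function()
  build_datasets(medium_synth()$recording))

# the default study cohort: 3 subjects, 12 h, master seed 1
accept_cohort <- function() memo("accept_cohort", function()
  generate_cohort(3, scenario_params(seed = 1), seed = 1))

accept_datasets <- function(i) {
  key <- sprintf("accept_ds_%d", i)
  memo(key, function() build_datasets(accept_cohort()[[i]]$recording))
}

ep60 <- epoch_params(60, fs = 10)
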