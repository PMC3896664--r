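# Shared fixtures: a session-level cache so expensive simulation runs are
# computed once and reused across test files (all runs are deterministic),
# and the standard reduced problem size used throughout the suite.

.tds_test_cache <- new.env(parent = emptyenv())

cached_eval <- function(key, expr) {
  if (!exists(key, envir = .tds_test_cache))
    assign(key, expr, envir = .tds_test_cache)
  get(key, envir = .tds_test_cache)
}

# Reduced study grid: resolves the wall boundary layer (~8 um wall cell
# against a ~27 um reaction-diffusion penetration length) while keeping a
# 10 h run to a few seconds.
test_numerics <- function(...) {
  utils::modifyList(list(nr_i = 64, nz = 12, refinement = 4, dt_s = 10,
                         t_end_h = 10, output_every_s = 3600), list(...))
}

run_cached <- function(key, params, ...) {
  cached_eval(key, run_simulation(params, ...))
}

# frequently reused full-length runs
baseline_run <- function(kind = "bistable") {
  run_cached(paste0("baseline_", kind), model_parameters(),
             numerics = test_numerics(), switch_kind = kind)
}

fractionation_run <- function(kind, S, T_h) {
  run_cached(sprintf("frac_%s_%g_%g", kind, S, T_h), model_parameters(),
             numerics = test_numerics(), switch_kind = kind,
             pulse = pulse_input(S, T_h))
}
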