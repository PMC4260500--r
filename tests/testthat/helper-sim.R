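# shared reduced-size simulation settings used across test files: full
# pipeline structure, smaller trial counts and 200 Hz sampling so the suite
# stays fast; generator signature parameters are the package defaults

small_cfg <- function(n_problems = 5) {
  study2_config(n_nback_trials = 12, n_spans = c(2, 1, 1),
                n_problems = n_problems)
}

small_model <- function(...) forward_model(rate = 200, ...)

# quiet model: no artifacts / drift / modulation, for analytic oracles
pure_model <- function(...) {
  args <- utils::modifyList(
    list(rate = 250, noise_amp = 0, mod_depth = 0, jitter_sd = 0,
         drift_amp = 0, blink_rate = 0, emg_amp = 0, eog_noise = 0),
    list(...))
  do.call(forward_model, args)
}

sim_small_session <- function(seed = 5, model = small_model(), ...) {
  sch <- build_study2_schedule(seed = seed, config = small_cfg())
  simulate_session(sch, model, seed = seed + 1, ...)
}
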