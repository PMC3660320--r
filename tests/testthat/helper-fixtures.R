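# Shared fixtures: built in code, never stored on disk.

default_cfg <- function() design_config()

# Smaller design for fast structural tests (still two contexts, ITI rule
# window intact).
quick_cfg <- function() {
  design_config(singles_per_option = 6L, peaks_per_option = 1L,
                choice_pairs_per_context_visit = 1L)
}

# Latency samples drawn from the default generator for one option.
option_draws <- function(option, n, vparams = value_params(), seed = 1) {
  opts <- default_options()
  v <- subjective_value(opts, vparams)[[option]]
  scmforage:::with_seed(seed, draw_latency(v, vparams, n = n))
}

# Paired-order helper: per-subject peak fits for one option from freshly
# simulated peak trains.
fit_option_peaks <- function(option, n_trials, tparams = timing_params(),
                             seed = 1) {
  delay <- default_options()$delay[default_options()$id == option]
  trains <- scmforage:::with_seed(seed, {
    lapply(seq_len(n_trials), function(i) {
      generate_peak_curve(delay, tparams)
    })
  })
  fit_peak(bin_responses(trains, option = option))
}
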