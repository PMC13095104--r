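# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept small so the whole suite stays fast, except where a
# statistic genuinely needs the full circuit (the acceptance file).

tiny_layout <- function(n_msn = 200, n_fsi = 10) population_layout(n_msn, n_fsi)

tiny_network <- function(n_msn = 200, n_fsi = 10, seed = 1) {
  build_striatum(tiny_layout(n_msn, n_fsi), seed = seed)
}

quick_config <- function(n_trials = 2, t_total = 600, t_warmup = 200,
                         seed = 1, ...) {
  sim_config(t_total = t_total, t_warmup = t_warmup, n_trials = n_trials,
             seed = seed, ...)
}

# Fabricate a trial_set directly from a list of per-trial spike tibbles,
# bypassing the simulator, for testing the statistics layer in isolation.
fake_trial_set <- function(spikes, n_msn = 2, n_fsi = 0,
                           window = c(0, 1000)) {
  structure(list(spikes = spikes, layout = population_layout(n_msn, n_fsi),
                 window = window,
                 config = sim_config(t_total = window[2], t_warmup = window[1],
                                     n_trials = length(spikes))),
            class = "trial_set")
}

poisson_spike_tbl <- function(ids, rate_hz, window) {
  dur <- window[2] - window[1]
  purrr::map_dfr(ids, function(id) {
    n <- stats::rpois(1, rate_hz * dur / 1000)
    tibble::tibble(neuron_id = id,
                   time_ms = sort(stats::runif(n, window[1], window[2])))
  })
}
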