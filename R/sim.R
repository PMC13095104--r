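#' Simulation configuration
#'
#' Clock-driven integration settings and the trial protocol: trials of
#' `t_total` ms at a fixed step `dt`, with the first `t_warmup` ms excluded
#' from every statistic while the network settles. Across the `n_trials`
#' repetitions the cortical input realisation and all wiring are frozen;
#' background noise and initial membrane potentials are redrawn per trial.
#'
#' @param dt Integration step, ms (default 0.1).
#' @param t_total Trial duration, ms (default 2500).
#' @param t_warmup Warm-up period excluded from analysis, ms (default 500).
#' @param n_trials Number of trials (default 100).
#' @param seed Master seed; all sub-streams derive from it via [sub_seed()].
#' @param heterogeneity Draw per-neuron parameters from
#'   [sample_heterogeneous()] instead of the homogeneous class defaults.
#' @param v_init `"uniform"` draws each initial membrane potential
#'   uniformly on `[E_L, V_th)` per neuron per trial; `"resting"` starts
#'   every neuron at `E_L`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.1, t_total = 2500, t_warmup = 500,
                       n_trials = 100, seed = 1, heterogeneity = FALSE,
                       v_init = c("uniform", "resting")) {
  stopifnot(dt > 0, t_warmup >= 0, t_warmup < t_total, n_trials >= 1)
  structure(list(dt = dt, t_total = t_total, t_warmup = t_warmup,
                 n_trials = as.integer(n_trials), seed = seed,
                 heterogeneity = isTRUE(heterogeneity),
                 v_init = match.arg(v_init)),
            class = "sim_config")
}

# Synaptic channel indices of the integrator (0-based):
# 0 background excitation, 1 cortical excitation, 2 MSN inhibition,
# 3 FSI inhibition.
CH_BKG <- 0L; CH_CTX <- 1L; CH_MSN <- 2L; CH_FSI <- 3L

delay_to_steps <- function(delay, dt) {
  # nearest grid point, ties round up; at least one step
  steps <- as.integer(floor(delay / dt + 0.5))
  if (any(steps < 1)) {
    stop("synaptic delay shorter than the integration step", call. = FALSE)
  }
  steps
}

neuron_param_table <- function(layout, config) {
  msn <- neuron_params("MSN")
  fsi <- neuron_params("FSI")
  if (config$heterogeneity) {
    spec <- heterogeneity_spec()
    dplyr::bind_rows(
      sample_heterogeneous(msn, spec, layout$n_msn,
                           seed = sub_seed(config$seed, "heterogeneity", 0L)),
      if (layout$n_fsi > 0)
        sample_heterogeneous(fsi, spec, layout$n_fsi,
                             seed = sub_seed(config$seed, "heterogeneity", 1L))
    )
  } else {
    dplyr::bind_rows(homogeneous_table(msn, layout$n_msn),
                     if (layout$n_fsi > 0) homogeneous_table(fsi, layout$n_fsi))
  }
}

# Compress the synapse list into CSR form keyed by presynaptic neuron, with
# channels resolved from the population of the source (MSN -> channel 2,
# FSI -> channel 3) and h-jump amounts normalised so conductances peak at
# the sampled weight.
assemble_recurrent <- function(network, dt) {
  syn <- network$synapses
  n <- network$layout$n_msn + network$layout$n_fsi
  if (nrow(syn) == 0) {
    return(list(ptr = integer(n + 1L), target = integer(0),
                channel = integer(0), delay = integer(0),
                amount = numeric(0)))
  }
  channel <- ifelse(syn$pre < network$layout$n_msn, CH_MSN, CH_FSI)
  ord <- order(syn$pre)
  counts <- tabulate(syn$pre + 1L, nbins = n)
  list(ptr = c(0L, cumsum(counts)),
       target = as.integer(syn$post[ord]),
       channel = as.integer(channel[ord]),
       delay = delay_to_steps(syn$delay[ord], dt),
       amount = syn$conductance[ord] * exp(1))
}

# Expand frozen cortical trains through the ctx wiring into a step-sorted
# external event list (delays already applied).
assemble_ctx_events <- function(inputs, dt, n_steps) {
  if (is.null(inputs)) {
    return(list(step = integer(0), target = integer(0),
                channel = integer(0), amount = numeric(0)))
  }
  wiring <- dplyr::bind_rows(inputs$msn_wiring, inputs$fsi_wiring)
  n_src <- inputs$pool$n_sources
  times_by_src <- split(inputs$trains$time_ms,
                        factor(inputs$trains$source_id, levels = 0:(n_src - 1L)))
  k <- lengths(times_by_src)[wiring$source + 1L]
  ev_time <- unlist(times_by_src[wiring$source + 1L], use.names = FALSE) +
    rep(wiring$delay, k)
  ev_target <- rep(as.integer(wiring$target), k)
  ev_amount <- rep(wiring$weight * exp(1), k)
  ev_step <- as.integer(ceiling(ev_time / dt - 1e-9))
  keep <- ev_step >= 0L & ev_step < n_steps
  ord <- order(ev_step[keep])
  list(step = ev_step[keep][ord], target = ev_target[keep][ord],
       channel = rep(CH_CTX, sum(keep)), amount = ev_amount[keep][ord])
}

assemble_sim <- function(network, inputs, config, background) {
  layout <- network$layout
  n <- layout$n_msn + layout$n_fsi
  params <- neuron_param_table(layout, config)
  n_steps <- as.integer(round(config$t_total / config$dt))
  lambda <- c(rep(background$msn_rate * config$dt, layout$n_msn),
              rep(background$fsi_rate * config$dt, layout$n_fsi))
  bkg_amount <- c(rep(background$msn_weight * exp(1), layout$n_msn),
                  rep(background$fsi_weight * exp(1), layout$n_fsi))
  list(
    layout = layout, params = params, n = n, n_steps = n_steps,
    tau = cbind(params$tau_e, params$tau_e, params$tau_i, params$tau_i),
    tr_steps = as.integer(ceiling(params$t_r / config$dt)),
    rec = assemble_recurrent(network, config$dt),
    ev = assemble_ctx_events(inputs, config$dt, n_steps),
    lambda = lambda, bkg_amount = bkg_amount
  )
}

run_one_trial <- function(sim, config, trial) {
  p <- sim$params
  if (config$v_init == "uniform") {
    set.seed(sub_seed(config$seed, "initial-state", trial))
    v0 <- stats::runif(sim$n, p$E_L, p$V_th)
  } else {
    v0 <- p$E_L
  }
  set.seed(sub_seed(config$seed, "background", trial))
  out <- cxx_simulate(p$C_m, p$g_L, p$E_L, p$V_th, p$V_reset, sim$tr_steps,
                      p$E_e, p$E_i, sim$tau,
                      sim$rec$ptr, sim$rec$target, sim$rec$channel,
                      sim$rec$delay, sim$rec$amount,
                      sim$ev$step, sim$ev$target, sim$ev$channel,
                      sim$ev$amount,
                      sim$lambda, sim$bkg_amount,
                      rep(0, sim$n), v0, config$dt, sim$n_steps)
  tibble::tibble(neuron_id = out$neuron_id, time_ms = out$time_ms)
}

#' Integrate a single trial
#'
#' Runs one trial of the full network: recurrent synapses from the wiring
#' realisation, frozen cortical events (if any), fresh background Poisson
#' noise and initial membrane potentials drawn from the trial's
#' sub-streams. Results are bitwise reproducible for a fixed
#' `(config$seed, trial)` pair.
#'
#' @param network A [build_striatum()] network.
#' @param inputs A [frozen_input_set()] or `NULL` for the spontaneous state.
#' @param config A [sim_config].
#' @param trial Trial index (selects the background / initial-state
#'   sub-seeds).
#' @param background A [background_config]; defaults to the rates implied
#'   by the layout.
#' @return A tibble (`neuron_id`, `time_ms`) of all spikes in the trial.
#' @export
integrate_trial <- function(network, inputs = NULL, config = sim_config(),
                            trial = 1L,
                            background = background_config(network$layout$n_fsi)) {
  sim <- assemble_sim(network, inputs, config, background)
  run_one_trial(sim, config, trial)
}

#' Run a trial set
#'
#' Executes `config$n_trials` repetitions with identical network wiring and
#' cortical input realisation; only the background noise and initial
#' membrane potentials differ between trials. The warm-up window is kept in
#' the spike records but flagged for exclusion by every statistic.
#'
#' @inheritParams integrate_trial
#' @return An object of class `trial_set`: a list with `spikes` (one spike
#'   tibble per trial), `layout`, `window` (analysis window in ms),
#'   `config` and `background`.
#' @export
run_trials <- function(network, inputs = NULL, config = sim_config(),
                       background = background_config(network$layout$n_fsi)) {
  sim <- assemble_sim(network, inputs, config, background)
  spikes <- lapply(seq_len(config$n_trials),
                   function(tr) run_one_trial(sim, config, tr))
  structure(list(spikes = spikes, layout = sim$layout,
                 window = c(config$t_warmup, config$t_total),
                 config = config, background = background),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set> ", length(x$spikes), " trials, window [",
      x$window[1], ", ", x$window[2], ") ms, ",
      x$layout$n_msn, " MSNs + ", x$layout$n_fsi, " FSIs\n", sep = "")
  invisible(x)
}

#' Mean firing rates per population
#'
#' Spikes per neuron per second over the analysis window, for the MSN and
#' FSI populations (and either MSN group), averaged across trials.
#'
#' @param trialset A [run_trials()] trial set.
#' @return A tibble (`population`, `rate_hz`).
#' @export
population_rates <- function(trialset) {
  win <- trialset$window
  dur_s <- (win[2] - win[1]) / 1000
  lay <- trialset$layout
  pops <- list(MSN = lay$msn_ids, MSN_a = lay$group_a, MSN_b = lay$group_b,
               FSI = lay$fsi_ids)
  rate_one <- function(ids) {
    if (length(ids) == 0) return(NA_real_)
    counts <- vapply(trialset$spikes, function(sp) {
      sum(sp$neuron_id %in% ids & sp$time_ms >= win[1] & sp$time_ms < win[2])
    }, numeric(1))
    mean(counts) / length(ids) / dur_s
  }
  tibble::tibble(population = names(pops),
                 rate_hz = unname(vapply(pops, rate_one, numeric(1))))
}

#' Spontaneous-state firing rates
#'
#' Simulates the network with background drive only (no cortical input) and
#' reports the mean MSN and FSI rates over the analysis window. With the
#' default parameters these sit near 1 Hz (MSN) and 7 Hz (FSI).
#'
#' @inheritParams run_trials
#' @return A one-row tibble (`msn_rate`, `fsi_rate`) in Hz.
#' @export
spontaneous_state_check <- function(network, config = sim_config(n_trials = 2),
                                    background = background_config(network$layout$n_fsi)) {
  ts <- run_trials(network, inputs = NULL, config = config,
                   background = background)
  r <- population_rates(ts)
  tibble::tibble(msn_rate = r$rate_hz[r$population == "MSN"],
                 fsi_rate = r$rate_hz[r$population == "FSI"])
}

#' Simulate a single isolated neuron
#'
#' Low-level convenience wrapper around the integrator for one neuron
#' driven by any combination of DC current, background Poisson drive, and
#' an explicit list of synaptic events. Used for F-I curve validation and
#' for the downstream pallidal readout.
#'
#' @param params A [neuron_params] object (or a one-row parameter tibble).
#' @param duration Simulation length, ms.
#' @param dt Step, ms.
#' @param I_dc DC current, pA.
#' @param bkg_rate Background Poisson rate, kHz.
#' @param bkg_weight Background peak conductance, nS.
#' @param events Optional tibble (`time_ms`, `weight`, `channel`) of
#'   synaptic events; channel 1 is excitatory (tau_e), channels 2-3
#'   inhibitory (tau_i). Weights are peak conductances in nS.
#' @param v0 Initial membrane potential (default `E_L`).
#' @param seed Optional seed for the background draw.
#' @return Numeric vector of spike times in ms.
#' @export
simulate_neuron <- function(params, duration, dt = 0.1, I_dc = 0,
                            bkg_rate = 0, bkg_weight = 0, events = NULL,
                            v0 = NULL, seed = NULL) {
  p <- if (inherits(params, "neuron_params")) {
    homogeneous_table(params, 1L)
  } else {
    tibble::as_tibble(params)[1, ]
  }
  n_steps <- as.integer(round(duration / dt))
  if (is.null(events)) {
    ev <- list(step = integer(0), target = integer(0), channel = integer(0),
               amount = numeric(0))
  } else {
    step <- as.integer(ceiling(events$time_ms / dt - 1e-9))
    keep <- step >= 0L & step < n_steps
    ord <- order(step[keep])
    ev <- list(step = step[keep][ord],
               target = integer(sum(keep)),
               channel = as.integer(events$channel[keep][ord]),
               amount = events$weight[keep][ord] * exp(1))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- cxx_simulate(p$C_m, p$g_L, p$E_L, p$V_th, p$V_reset,
                      as.integer(ceiling(p$t_r / dt)),
                      p$E_e, p$E_i,
                      cbind(p$tau_e, p$tau_e, p$tau_i, p$tau_i),
                      integer(2), integer(0), integer(0), integer(0),
                      numeric(0),
                      ev$step, ev$target, ev$channel, ev$amount,
                      bkg_rate * dt, bkg_weight * exp(1),
                      I_dc, if (is.null(v0)) p$E_L else v0,
                      dt, n_steps)
  out$time_ms
}
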