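test_that("an undriven neuron rests at E_L and never spikes", {
  msn <- neuron_params("MSN")
  sp <- simulate_neuron(msn, 1000)
  expect_length(sp, 0)
})

test_that("simulated DC rates match the closed-form F-I curve within 2%", {
  for (cls in c("MSN", "FSI", "GPE")) {
    p <- neuron_params(cls)
    for (mult in c(1.2, 2)) {
      I <- mult * rheobase(p)
      sim <- length(simulate_neuron(p, 5000, I_dc = I)) / 5
      expect_equal(sim, dc_firing_rate(p, I), tolerance = 0.02)
    }
    # below rheobase: silent
    expect_length(simulate_neuron(p, 2000, I_dc = 0.9 * rheobase(p)), 0)
  }
})

test_that("simulated rheobase agrees with the closed form within 1%", {
  for (cls in c("MSN", "FSI")) {
    p <- neuron_params(cls)
    lo <- 0.5 * rheobase(p); hi <- 2 * rheobase(p)
    for (i in 1:14) {
      mid <- (lo + hi) / 2
      fired <- length(simulate_neuron(p, 5000, I_dc = mid)) > 0
      if (fired) hi <- mid else lo <- mid
    }
    expect_equal((lo + hi) / 2, rheobase(p), tolerance = 0.01)
  }
})

test_that("trials are deterministic under seeds and sensitive to sub-streams", {
  net <- tiny_network(seed = 1)
  cfg <- quick_config(seed = 5)
  s1 <- integrate_trial(net, config = cfg, trial = 1)
  s2 <- integrate_trial(net, config = cfg, trial = 1)
  expect_identical(s1, s2)
  s3 <- integrate_trial(net, config = cfg, trial = 2)  # new background draw
  expect_false(identical(s1, s3))
})

test_that("frozen cortical input is shared across trials, background is not", {
  lay <- tiny_layout()
  net <- tiny_network(seed = 2)
  fin <- frozen_input_set(cortical_pool_config(0.2, 0.5), lay, 600, seed = 3)
  ts <- run_trials(net, fin, quick_config(n_trials = 2, seed = 4))
  expect_length(ts$spikes, 2)
  expect_false(identical(ts$spikes[[1]], ts$spikes[[2]]))
  expect_equal(ts$window, c(200, 600))
})

test_that("no neuron violates its refractory period", {
  net <- tiny_network(seed = 3)
  lay <- tiny_layout()
  fin <- frozen_input_set(cortical_pool_config(0.3, 0.5), lay, 600, seed = 3)
  sp <- integrate_trial(net, fin, quick_config(seed = 6), trial = 1)
  min_isi <- sp |>
    dplyr::group_by(neuron_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(m = min(diff(time_ms))) |>
    dplyr::pull(m)
  expect_gte(min(min_isi), 2)
  # spike times lie on the grid, within the trial
  expect_true(all(sp$time_ms > 0 & sp$time_ms <= 600))
})

test_that("removing feedforward inhibition never lowers MSN output", {
  lay <- tiny_layout(n_msn = 200, n_fsi = 10)
  net <- build_striatum(lay, seed = 4)
  fin <- frozen_input_set(cortical_pool_config(0.2, 0.5), lay, 800, seed = 5)
  cfg <- sim_config(t_total = 800, t_warmup = 200, n_trials = 1, seed = 7)
  with_ffi <- integrate_trial(net, fin, cfg, trial = 1)
  net0 <- net
  net0$synapses <- net0$synapses[net0$synapses$pre < lay$n_msn, ]
  without_ffi <- integrate_trial(net0, fin, cfg, trial = 1)
  n_msn_spikes <- function(sp) sum(sp$neuron_id < lay$n_msn & sp$time_ms >= 200)
  expect_gte(n_msn_spikes(without_ffi), n_msn_spikes(with_ffi))
})

test_that("zero background drive silences the spontaneous state", {
  net <- tiny_network(seed = 5)
  r <- spontaneous_state_check(net, quick_config(n_trials = 2),
                               background = background_config(
                                 10, msn_rate = 0, fsi_rate = 0))
  expect_equal(r$msn_rate, 0)
  expect_equal(r$fsi_rate, 0)
})

test_that("halving the step changes evoked population rates by < 3%", {
  lay <- population_layout(2500, 250)
  net <- build_striatum(lay, seed = 42)
  fin <- frozen_input_set(cortical_pool_config(0.1, 0.9), lay, 2500, seed = 7)
  rate <- function(dt) {
    ts <- run_trials(net, fin, sim_config(dt = dt, n_trials = 1, seed = 7))
    r <- population_rates(ts)
    r$rate_hz[r$population == "MSN"]
  }
  expect_equal(rate(0.1), rate(0.05), tolerance = 0.03)
})
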