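test_that("class parameter sets match the published table", {
  msn <- neuron_params("MSN")
  expect_equal(msn$C_m, 80)
  expect_equal(msn$g_L, 10)
  expect_equal(msn$E_L, -80)
  expect_equal(msn$V_th, -45)
  expect_equal(msn$V_reset, -70)
  expect_equal(msn$t_r, 2)
  expect_equal(msn$E_e, 0)
  expect_equal(msn$E_i, -85)
  expect_equal(msn$tau_e, 0.2)
  expect_equal(msn$tau_i, 15)

  fsi <- neuron_params("FSI")
  expect_equal(unlist(fsi[c("C_m", "g_L", "E_L", "V_th")]),
               c(C_m = 70, g_L = 5, E_L = -70, V_th = -40))
  gpe <- neuron_params("GPE")
  expect_equal(unlist(gpe[c("C_m", "g_L", "E_L", "V_th")]),
               c(C_m = 70, g_L = 2.5, E_L = -70, V_th = -45))
  expect_error(neuron_params("granule"), "unknown cell class")
})

test_that("rheobase follows the closed form g_L (V_th - E_L)", {
  expect_equal(rheobase(neuron_params("MSN")), 350)
  expect_equal(rheobase(neuron_params("FSI")), 150)
  expect_equal(rheobase(neuron_params("GPE")), 62.5)
})

test_that("DC firing rate matches the LIF interval formula", {
  msn <- neuron_params("MSN")
  expect_equal(dc_firing_rate(msn, 300), 0)
  expect_equal(dc_firing_rate(msn, 350), 0)  # exactly at rheobase
  # tau_m = 8 ms, V_ss = -40 mV: ISI = 2 + 8 log(6) ms
  expect_equal(dc_firing_rate(msn, 400), 1000 / (2 + 8 * log(6)),
               tolerance = 1e-10)
  # refractory-limited ceiling
  expect_lt(abs(dc_firing_rate(msn, 1e9) - 1000 / msn$t_r), 1)
  # monotone non-decreasing in current
  rates <- dc_firing_rate(msn, seq(0, 2000, by = 25))
  expect_true(all(diff(rates) >= 0))
})

test_that("alpha conductance gates, peaks and superposes correctly", {
  ev <- tibble::tibble(arrival_time = 10, peak_conductance = 0.5, tau = 15)
  expect_equal(alpha_conductance(5, ev), 0)           # before arrival
  expect_equal(alpha_conductance(10, ev), 0)          # at arrival
  expect_equal(alpha_conductance(25, ev), 0.5)        # peak at t_i + tau
  # unnormalised form peaks at gbar / e
  expect_equal(alpha_conductance(25, ev, normalize = FALSE), 0.5 / exp(1))
  # linear superposition of two identical events
  two <- dplyr::bind_rows(ev, ev)
  tt <- seq(0, 100, by = 0.5)
  expect_equal(alpha_conductance(tt, two), 2 * alpha_conductance(tt, ev))
  # decay: ~1.7% of peak at 7 tau, below 1% by 8 tau
  expect_lt(alpha_conductance(10 + 7 * 15, ev), 0.02 * 0.5)
  expect_lt(alpha_conductance(10 + 8 * 15, ev), 0.01 * 0.5)
})

test_that("heterogeneous sampling has the stated spread and is reproducible", {
  msn <- neuron_params("MSN")
  spec <- heterogeneity_spec()
  d1 <- sample_heterogeneous(msn, spec, 1e4, seed = 11)
  # sd(C_m) ~ 80/30
  expect_equal(sd(d1$C_m), 80 / 30, tolerance = 0.05)
  expect_equal(mean(d1$g_L), 10, tolerance = 0.01)
  expect_equal(mean(d1$tau_i), 15, tolerance = 0.01)
  expect_equal(var(d1$tau_i), 0.5, tolerance = 0.05)
  # nearly all draws within +/-10% of the class value (3 sigma)
  expect_gte(mean(abs(d1$C_m - 80) / 80 < 0.10), 0.995)
  expect_gte(mean(abs(d1$V_th + 45) / 45 < 0.10), 0.995)
  # invariants hold after rejection sampling
  expect_true(all(d1$C_m > 0, d1$g_L > 0, d1$t_r > 0, d1$tau_i > 0,
                  d1$V_th > d1$V_reset))
  # determinism and the degenerate case
  d2 <- sample_heterogeneous(msn, spec, 1e4, seed = 11)
  expect_identical(d1, d2)
  d0 <- sample_heterogeneous(msn, heterogeneity_spec(relative_sd = 0,
                                                     tau_i_variance = 0),
                             5, seed = 1)
  expect_true(all(d0$C_m == 80 & d0$V_th == -45 & d0$tau_i == 15))
})
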