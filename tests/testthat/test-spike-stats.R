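test_that("population binning counts, conserves and zero-fills", {
  sp <- tibble::tibble(neuron_id = 0L, time_ms = c(1001, 1003))
  ts <- fake_trial_set(list(sp), n_msn = 2, window = c(1000, 1010))
  b <- bin_population_counts(ts, neurons = 0L, bin = 2)
  expect_equal(b$count, c(1, 1, 0, 0, 0))
  expect_equal(sum(b$count), 2)
  empty <- fake_trial_set(list(tibble::tibble(neuron_id = integer(0),
                                              time_ms = numeric(0))),
                          window = c(0, 100))
  expect_true(all(bin_population_counts(empty, 0L, 2)$count == 0))
  expect_error(bin_population_counts(ts, integer(0)), "empty")
})

test_that("across-trial Fano factor is 0 for identical trials, ~1 for Poisson", {
  sp <- poisson_spike_tbl(0L, 400, c(0, 2000))
  same <- fake_trial_set(list(sp, sp, sp), window = c(0, 2000))
  expect_equal(across_trial_fano(same, 0L)$ff, 0)

  set.seed(21)
  pois <- fake_trial_set(replicate(60, poisson_spike_tbl(0L, 500, c(0, 2000)),
                                   simplify = FALSE),
                         window = c(0, 2000))
  f <- across_trial_fano(pois, 0L, bin = 2)
  expect_equal(f$ff, 1, tolerance = 0.05)
  expect_s3_class(glance(f), "tbl_df")
  expect_equal(nrow(tidy(f)) + f$n_excluded, f$n_bins)
})

test_that("Fano uses the sample variance and excludes zero-mean bins", {
  # two trials, one 2 ms bin with counts {2, 4}: var 2, mean 3
  mk <- function(n) tibble::tibble(neuron_id = 0L,
                                   time_ms = seq(0.1, 1.9, length.out = n))
  ts <- fake_trial_set(list(mk(2), mk(4)), window = c(0, 2))
  expect_equal(across_trial_fano(ts, 0L, bin = 2)$ff, 2 / 3)
  silent <- fake_trial_set(list(mk(0), mk(0)), window = c(0, 2))
  expect_error(across_trial_fano(silent, 0L), "zero mean")
})

test_that("Fano and burst index are invariant under time translation", {
  set.seed(22)
  sps <- replicate(20, poisson_spike_tbl(0L, 300, c(0, 2000)),
                   simplify = FALSE)
  ts <- fake_trial_set(sps, window = c(0, 2000))
  shifted <- fake_trial_set(
    lapply(sps, function(s) dplyr::mutate(s, time_ms = time_ms + 500)),
    window = c(500, 2500))
  expect_equal(across_trial_fano(ts, 0L)$ff, across_trial_fano(shifted, 0L)$ff)
  tr <- lapply(sps, function(s) s$time_ms)
  expect_equal(burst_index(tr)$bi,
               burst_index(lapply(tr, function(x) x + 500))$bi)
})

test_that("pairwise correlation handles identity, independence, antiphase, silence", {
  win <- c(0, 2000)
  set.seed(23)
  a <- sort(runif(150, 0, 2000))
  expect_equal(pairwise_correlation(a, a, 20, win), 1.0)
  b <- sort(runif(150, 0, 2000))
  expect_lt(abs(pairwise_correlation(a, b, 20, win)), 0.15)
  # strictly alternating occupied bins -> -1
  odd <- seq(10, 1990, by = 40)
  even <- seq(30, 1990, by = 40)
  expect_equal(pairwise_correlation(odd, even, 20, win), -1.0)
  expect_true(is.na(pairwise_correlation(a, numeric(0), 20, win)))
})

test_that("correlation transfer recovers shared-input fractions", {
  # surrogate neurons: counts = shared Poisson + private Poisson; the
  # expected pairwise count correlation equals the shared rate fraction
  win <- c(0, 2e5)
  f <- 0.3
  set.seed(24)
  shared_a <- poisson_spike_tbl(99L, 10 * f, win)$time_ms
  shared_b <- poisson_spike_tbl(99L, 10 * f, win)$time_ms
  mk_group <- function(ids, shared) {
    purrr::map_dfr(ids, function(id) {
      tibble::tibble(neuron_id = id,
                     time_ms = sort(c(shared,
                                      poisson_spike_tbl(0L, 10 * (1 - f),
                                                        win)$time_ms)))
    })
  }
  sp <- dplyr::bind_rows(mk_group(0:3, shared_a), mk_group(4:7, shared_b))
  ts <- fake_trial_set(list(sp), n_msn = 8, window = win)
  ct <- correlation_transfer(ts, bin = 20, pair_budget = Inf)
  expect_lt(abs(ct$w_out - f), 0.02)
  expect_lt(abs(ct$b_out), 0.02)
})

test_that("correlation transfer is exact on degenerate cases and relabeling", {
  win <- c(0, 2000)
  set.seed(25)
  tt <- sort(runif(300, 0, 2000))
  same <- purrr::map_dfr(0:5, ~tibble::tibble(neuron_id = .x, time_ms = tt))
  ts <- fake_trial_set(list(same), n_msn = 6, window = win)
  ct <- correlation_transfer(ts, pair_budget = Inf)
  expect_equal(ct$w_out, 1)
  expect_equal(ct$b_out, 1)

  indep <- poisson_spike_tbl(0:5, 8, win)
  ts2 <- fake_trial_set(list(indep), n_msn = 6, window = win)
  ct2 <- correlation_transfer(ts2, pair_budget = Inf)
  expect_lt(abs(ct2$w_out), 0.2)
  # relabeling neurons within groups leaves the statistics unchanged
  perm <- c(sample(0:2), sample(3:5))
  relabeled <- dplyr::mutate(indep, neuron_id = perm[neuron_id + 1L])
  ct3 <- correlation_transfer(fake_trial_set(list(relabeled), n_msn = 6,
                                             window = win),
                              pair_budget = Inf)
  expect_equal(ct2$w_out, ct3$w_out)
  expect_equal(ct2$b_out, ct3$b_out)
})

test_that("burst detection follows the >3-spike, <10 ms ISI rule", {
  expect_equal(burst_index(list(seq(0, 45, by = 5)))$bi, 1.0)
  expect_equal(burst_index(list(seq(0, 450, by = 50)))$bi, 0)
  # groups of 4 (burst), 3 (too small), 1: BI = 4/8
  tt <- c(0, 5, 10, 15, 100, 105, 110, 200)
  expect_equal(burst_index(list(tt))$bi, 0.5)
  # inclusive convention counts the size-3 group too
  expect_equal(burst_index(list(tt), min_spikes = 3)$bi, 7 / 8)
  # empty trials are excluded from the average
  b <- burst_index(list(tt, numeric(0)))
  expect_equal(b$bi, 0.5)
  expect_equal(sum(is.na(b$per_trial$bi)), 1)
})

test_that("spike-count Fano across trials matches hand-computed values", {
  mk <- function(n) seq_len(n) * 10
  expect_equal(gpe_count_fano(list(mk(5), mk(5), mk(5)), c(0, 1000))$ff, 0)
  # counts {38, 42}: sample var 8, mean 40
  expect_equal(gpe_count_fano(list(mk(38), mk(42)), c(0, 1000))$ff, 0.2)
  set.seed(26)
  pois <- lapply(stats::rpois(400, 40), mk)
  expect_equal(gpe_count_fano(pois, c(0, 1e4))$ff, 1, tolerance = 0.15)
  expect_error(gpe_count_fano(list(numeric(0), numeric(0)), c(0, 10)),
               "zero mean")
})
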