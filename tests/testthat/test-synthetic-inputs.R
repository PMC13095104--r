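test_that("pool sizes invert the sharing formulas with nearest-integer rounding", {
  expect_equal(pool_sizes_from_sharing(0.1, 0.5)[c("n_ctx", "n_ol")],
               list(n_ctx = 1000L, n_ol = 500L))
  expect_equal(pool_sizes_from_sharing(1.0, 0.0)[c("n_ctx", "n_ol")],
               list(n_ctx = 100L, n_ol = 0L))
  p <- pool_sizes_from_sharing(0.15, 0.1)
  expect_equal(p$n_ctx, 667L)
  expect_equal(p$n_ol, 67L)
  # realised fractions are reported from the rounded sizes
  expect_equal(p$w_in, 100 / 667)
  expect_error(pool_sizes_from_sharing(0, 0.5), "w_in")
})

test_that("Poisson trains have Poisson counts and are reproducible", {
  expect_equal(nrow(generate_poisson_trains(0, 10, 1000)), 0)
  tr <- generate_poisson_trains(10, 1000, 2000, seed = 5)
  counts <- tabulate(tr$source_id + 1L, nbins = 1000)
  expect_equal(mean(counts), 20, tolerance = 0.03)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.1)
  expect_identical(tr, generate_poisson_trains(10, 1000, 2000, seed = 5))
})

test_that("cortical wiring hits the fixed indegrees with multiplicity", {
  lay <- tiny_layout(n_msn = 100, n_fsi = 6)
  pool <- cortical_pool_config(0.1, 0.5)
  wm <- wire_ctx_to_msn(pool, lay, seed = 6)
  expect_true(all(table(factor(wm$target, levels = lay$msn_ids)) == 100))
  # group A targets draw only from pool A, group B only from pool B
  expect_true(all(wm$source[wm$target < 50] < pool$n_ctx))
  expect_true(all(wm$source[wm$target >= 50] >= pool$n_ctx - pool$n_ol))
  wf <- wire_ctx_to_fsi(pool, lay, seed = 6)
  expect_true(all(table(factor(wf$target, levels = lay$fsi_ids)) == 200))
  wf1 <- wire_ctx_to_fsi(pool, lay, seed = 6, per_source = FALSE)
  expect_true(all(table(factor(wf1$target, levels = lay$fsi_ids)) == 100))
  expect_equal(nrow(wire_ctx_to_fsi(pool, tiny_layout(100, 0), seed = 1)), 0)
})

test_that("multapse prevalence scales with within-group sharing", {
  lay <- tiny_layout(n_msn = 100, n_fsi = 0)
  multapse_frac <- function(w_in) {
    wm <- wire_ctx_to_msn(cortical_pool_config(w_in, 0), lay, seed = 8)
    1 - nrow(dplyr::distinct(wm, source, target)) / nrow(wm)
  }
  expect_gt(multapse_frac(1.0), 0.2)     # 100 draws from 100 sources
  expect_lt(multapse_frac(0.01), 0.01)   # 100 draws from 10^4 sources
})

test_that("overlap sources have double expected multiplicity onto FSIs", {
  lay <- population_layout(10, 200)
  pool <- cortical_pool_config(0.5, 0.5)  # n_ctx 200, n_ol 100
  wf <- wire_ctx_to_fsi(pool, lay, seed = 9)
  in_overlap <- wf$source >= pool$n_ctx - pool$n_ol & wf$source < pool$n_ctx
  per_overlap_src <- sum(in_overlap) / pool$n_ol
  per_private_src <- sum(!in_overlap) / (pool$n_sources - pool$n_ol)
  expect_equal(per_overlap_src / per_private_src, 2, tolerance = 0.1)
})

test_that("frozen input sets freeze the stimulus but not the background", {
  lay <- tiny_layout(50, 4)
  pool <- cortical_pool_config(0.2, 0.5)
  f1 <- frozen_input_set(pool, lay, 1000, seed = 3)
  f2 <- frozen_input_set(pool, lay, 1000, seed = 3)
  expect_identical(f1$trains, f2$trains)
  expect_identical(f1$msn_wiring, f2$msn_wiring)
  f3 <- frozen_input_set(pool, lay, 1000, seed = 4)
  expect_false(identical(f1$trains, f3$trains))
})

test_that("measured input correlations recover (w_in, b_in * w_in)", {
  # large-pool regime: with few multapses the count correlation equals the
  # shared source fraction
  lay <- tiny_layout(n_msn = 120, n_fsi = 0)
  for (setting in list(c(0.1, 0.9), c(0.05, 0.3))) {
    pool <- cortical_pool_config(setting[1], setting[2])
    expd <- expected_input_correlation(pool)
    expect_equal(unname(expd), c(setting[1], setting[1] * setting[2]),
                 tolerance = 0.01)
    fin <- frozen_input_set(pool, lay, 60000, seed = 13)
    m <- measure_input_correlation(fin, lay, bin = 100, n_pairs = 150,
                                   seed = 14)
    expect_lt(max(abs(m$measured - m$expected)), 0.02)
  }
})

test_that("background trains are pairwise independent", {
  tr <- generate_poisson_trains(1000, 20, 20000, seed = 15)
  counts <- matrix(tabulate(floor(tr$time_ms / 100) * 20 + tr$source_id + 1L,
                            nbins = 20 * 200), nrow = 20)
  cc <- cor(t(counts))
  off <- cc[upper.tri(cc)]
  expect_lt(max(abs(off)), 0.25)
  expect_lt(abs(mean(off)), 0.02)
})
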