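small_cfg <- function(experiment, ...) {
  experiment_config(experiment, w_in = 0.2, b_in = 0.5, n_fsi = c(10, 40),
                    n_msn = 200, n_trials = 2, t_total = 700, t_warmup = 300,
                    seed = 9, pair_budget = 300, ...)
}

test_that("the variability sweep emits the schema and is bit-reproducible", {
  cfg <- small_cfg("variability")
  r1 <- run_experiment(cfg, progress = FALSE)
  expect_true(all(c("w_in", "b_in", "n_fsi", "msn_rate", "fsi_rate",
                    "ff_msn", "seed") %in% names(r1)))
  expect_equal(nrow(r1), 2)
  r2 <- run_experiment(cfg, progress = FALSE)
  expect_identical(dplyr::select(r1, -elapsed_s), dplyr::select(r2, -elapsed_s))
})

test_that("per-point seeding is independent of grid order", {
  cfg_a <- small_cfg("variability")
  cfg_b <- small_cfg("variability")
  cfg_b$n_fsi <- rev(cfg_b$n_fsi)
  ra <- run_experiment(cfg_a, progress = FALSE) |> dplyr::arrange(n_fsi)
  rb <- run_experiment(cfg_b, progress = FALSE) |> dplyr::arrange(n_fsi)
  expect_identical(dplyr::select(ra, -elapsed_s), dplyr::select(rb, -elapsed_s))
})

test_that("the no-FSI control automatically reduces the MSN background", {
  expect_equal(background_config(0)$msn_rate, 3.2)
  expect_equal(background_config(25)$msn_rate, 5.95)
  expect_equal(background_config(250)$msn_rate, 5.95)
})

test_that("condition comparison computes per-setting deltas and signs", {
  res <- tibble::tibble(
    w_in = rep(c(0.1, 0.3), 2), b_in = 0.5,
    n_fsi = rep(c(25, 250), each = 2),
    msn_rate = c(5, 6, 5.1, 6.1), ff_msn = c(3, 4, 1, 1.5),
    w_out = c(0.03, 0.04, 0.01, 0.02))
  cmp <- compare_conditions(res, baseline = list(n_fsi = 250),
                            test = list(n_fsi = 25))
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$d_ff_msn > 0))
  expect_equal(unname(attr(cmp, "sign_summary")[["w_out"]]), 2)
  same <- compare_conditions(res, baseline = list(n_fsi = 25),
                             test = list(n_fsi = 25))
  expect_true(all(same$d_ff_msn == 0))
  bad <- res[-1, ]
  expect_error(compare_conditions(bad, list(n_fsi = 250), list(n_fsi = 25)),
               "grid")
})

test_that("sweep artifacts are written when an output directory is given", {
  out <- withr::local_tempdir()
  cfg <- experiment_config("spontaneous", n_fsi = 10, n_msn = 100,
                           n_trials = 2, t_total = 600, t_warmup = 200,
                           seed = 3, out_dir = out)
  res <- run_experiment(cfg, progress = FALSE)
  expect_true(file.exists(file.path(out, "results_spontaneous.csv")))
  expect_true(file.exists(file.path(out, "meta_spontaneous.json")))
  on_disk <- utils::read.csv(file.path(out, "results_spontaneous.csv"))
  expect_equal(nrow(on_disk), nrow(res))
})
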