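#' Configuration of a sweep experiment
#'
#' Describes one of the four experiment families over a grid of input
#' settings: `"spontaneous"` (background only), `"variability"`
#' (across-trial population Fano factor), `"correlation"` (within/between
#' group correlation transfer), `"downstream"` (pallidal readout). The
#' full-scale sweeps use `w_in` in 0.01-0.5 (11 values), `b_in` in
#' \{0.1, 0.3, 0.5, 0.7, 0.9\} and `n_fsi` from 0 to 250; the default here
#' is a reduced grid suitable for interactive use.
#'
#' @param experiment One of `"spontaneous"`, `"variability"`,
#'   `"correlation"`, `"downstream"`.
#' @param w_in,b_in Input-sharing grids (fractions).
#' @param n_fsi FSI population sizes (0 allowed only for `"correlation"`
#'   and `"spontaneous"` style baselines; it switches the MSN background to
#'   3.2 kHz automatically).
#' @param n_msn MSN count (default 2500).
#' @param n_trials Trials per grid point.
#' @param t_total,t_warmup Trial timing, ms.
#' @param dt Integration step, ms.
#' @param seed Master seed; each grid point derives its own sub-seed from
#'   the setting values, so per-point results do not depend on grid order.
#' @param heterogeneity Use heterogeneous neuron parameters.
#' @param pair_budget Sampled pairs per category for correlation transfer.
#' @param fano_bin,corr_bin Bin widths, ms.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("variability", "correlation",
                                             "downstream", "spontaneous"),
                              w_in = c(0.05, 0.25), b_in = c(0.1, 0.9),
                              n_fsi = c(25, 250), n_msn = 2500,
                              n_trials = 15, t_total = 2500, t_warmup = 500,
                              dt = 0.1, seed = 1, heterogeneity = FALSE,
                              pair_budget = 5000, fano_bin = 2,
                              corr_bin = 20, out_dir = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(length(w_in) >= 1, length(b_in) >= 1, length(n_fsi) >= 1,
            all(w_in > 0 & w_in <= 1), all(b_in >= 0 & b_in <= 1),
            all(n_fsi >= 0))
  structure(list(experiment = experiment, w_in = w_in, b_in = b_in,
                 n_fsi = n_fsi, n_msn = n_msn, n_trials = n_trials,
                 t_total = t_total, t_warmup = t_warmup, dt = dt,
                 seed = seed, heterogeneity = heterogeneity,
                 pair_budget = pair_budget, fano_bin = fano_bin,
                 corr_bin = corr_bin, out_dir = out_dir),
            class = "experiment_config")
}

#' Full-scale input grids
#'
#' Convenience constants: the full within-group sharing grid, between-group
#' sharing grid, and FSI population grid of the full published sweeps.
#'
#' @return A named list with `w_in`, `b_in`, `n_fsi`.
#' @export
full_grids <- function() {
  list(w_in = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5),
       b_in = c(0.1, 0.3, 0.5, 0.7, 0.9),
       n_fsi = c(25, 50, 100, 150, 250))
}

run_one_setting <- function(cfg, w_in, b_in, n_fsi, gpe_bkg_weight = NULL) {
  t0 <- proc.time()[["elapsed"]]
  point_seed <- sub_seed(cfg$seed,
                         paste("point", cfg$experiment, w_in, b_in, n_fsi))
  layout <- population_layout(cfg$n_msn, n_fsi)
  network <- build_striatum(layout, seed = sub_seed(point_seed, "network"))
  background <- background_config(n_fsi)
  sc <- sim_config(dt = cfg$dt, t_total = cfg$t_total,
                   t_warmup = cfg$t_warmup, n_trials = cfg$n_trials,
                   seed = point_seed, heterogeneity = cfg$heterogeneity)
  inputs <- if (cfg$experiment == "spontaneous") NULL else {
    frozen_input_set(cortical_pool_config(w_in, b_in), layout,
                     cfg$t_total, seed = point_seed)
  }
  ts <- run_trials(network, inputs, sc, background)
  rates <- population_rates(ts)
  row <- tibble::tibble(
    experiment = cfg$experiment, w_in = w_in, b_in = b_in, n_fsi = n_fsi,
    n_trials = cfg$n_trials, seed = point_seed,
    msn_rate = rates$rate_hz[rates$population == "MSN"],
    fsi_rate = rates$rate_hz[rates$population == "FSI"]
  )
  if (cfg$experiment %in% c("variability", "correlation", "downstream")) {
    row$ff_msn <- across_trial_fano(ts, "a", bin = cfg$fano_bin)$ff
  }
  if (cfg$experiment == "correlation") {
    ct <- correlation_transfer(ts, bin = cfg$corr_bin,
                               pair_budget = cfg$pair_budget,
                               seed = sub_seed(point_seed, "pairs"))
    row$w_out <- ct$w_out
    row$b_out <- ct$b_out
  }
  if (cfg$experiment == "downstream") {
    wiring <- gpe_wiring(n_msn_inputs = cfg$n_msn / 2,
                         bkg_weight = gpe_bkg_weight,
                         seed = sub_seed(point_seed, "gpe-wiring"))
    gs <- gpe_stats(run_gpe(ts, wiring, group = "a", seed = point_seed))
    row$gpe_rate <- gs$rate_hz
    row$ff_gpe <- gs$ff_gpe
    row$bi_gpe <- gs$bi_gpe
  }
  row$elapsed_s <- proc.time()[["elapsed"]] - t0
  row
}

#' Run a sweep experiment
#'
#' Runs every grid point of an [experiment_config]: builds the network,
#' generates the frozen cortical input realisation, simulates the trial
#' set, and computes the statistics of the experiment family. Each grid
#' point is seeded from its setting values, so results are independent of
#' execution order, and a rerun with the same configuration is
#' reproducible. A failure at one grid point is recorded (column `error`)
#' and the sweep continues.
#'
#' @param cfg An [experiment_config].
#' @param progress Print one line per completed setting.
#' @return A tidy tibble with one row per grid point. If `cfg$out_dir` is
#'   set, also writes `results_<experiment>.csv` and a JSON metadata file.
#' @export
run_experiment <- function(cfg, progress = interactive()) {
  grid <- if (cfg$experiment == "spontaneous") {
    tidyr::expand_grid(w_in = cfg$w_in[1], b_in = cfg$b_in[1],
                       n_fsi = cfg$n_fsi)
  } else {
    tidyr::expand_grid(w_in = cfg$w_in, b_in = cfg$b_in, n_fsi = cfg$n_fsi)
  }
  gpe_w <- NULL
  if (cfg$experiment == "downstream") {
    gpe_w <- as.numeric(calibrate_background(seed = sub_seed(cfg$seed,
                                                             "gpe-calib")))
  }
  rows <- purrr::pmap(grid, function(w_in, b_in, n_fsi) {
    res <- tryCatch(
      run_one_setting(cfg, w_in, b_in, n_fsi, gpe_bkg_weight = gpe_w),
      error = function(e) {
        tibble::tibble(experiment = cfg$experiment, w_in = w_in,
                       b_in = b_in, n_fsi = n_fsi,
                       n_trials = cfg$n_trials, error = conditionMessage(e))
      })
    if (progress) {
      message(sprintf("[%s] w_in=%.3g b_in=%.3g n_fsi=%d done (%.1f s)",
                      cfg$experiment, w_in, b_in, n_fsi,
                      res$elapsed_s[1] %||% NA))
    }
    res
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(cfg$out_dir,
                                    paste0("results_", cfg$experiment, ".csv")),
                     row.names = FALSE)
    meta <- unclass(cfg)
    meta$out_dir <- NULL
    meta$gpe_bkg_weight <- gpe_w
    jsonlite::write_json(meta,
                         file.path(cfg$out_dir,
                                   paste0("meta_", cfg$experiment, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Compare two conditions of a sweep
#'
#' Per-setting differences (test minus baseline) of every shared statistic
#' between two conditions of one results table, matched on the input
#' settings. The attached sign summary counts, per statistic, the settings
#' with a positive difference — e.g. `w_out` deltas are positive for every
#' setting when comparing 25 against 250 FSIs, and negative when comparing
#' 250 FSIs against the no-FSI control.
#'
#' @param results A [run_experiment()] table (possibly several conditions
#'   row-bound together).
#' @param baseline,test Named lists selecting the two conditions, e.g.
#'   `list(n_fsi = 250)` and `list(n_fsi = 25)`.
#' @return A tibble of per-setting deltas (columns `d_<stat>`), with a
#'   `sign_summary` attribute.
#' @export
compare_conditions <- function(results, baseline, test) {
  pick <- function(cond) {
    out <- results
    for (nm in names(cond)) out <- out[out[[nm]] == cond[[nm]], ]
    out
  }
  b <- pick(baseline); t <- pick(test)
  keys <- setdiff(c("w_in", "b_in", "n_fsi"), names(baseline))
  if (nrow(b) == 0 || nrow(t) == 0) {
    stop("baseline or test condition not present in results", call. = FALSE)
  }
  stats_cols <- intersect(c("msn_rate", "fsi_rate", "ff_msn", "w_out",
                            "b_out", "gpe_rate", "ff_gpe", "bi_gpe"),
                          names(results))
  j <- dplyr::inner_join(b[, c(keys, stats_cols)], t[, c(keys, stats_cols)],
                         by = keys, suffix = c("_base", "_test"))
  if (nrow(j) != nrow(b) || nrow(j) != nrow(t)) {
    stop("conditions do not share the same input-setting grid", call. = FALSE)
  }
  for (s in stats_cols) {
    j[[paste0("d_", s)]] <- j[[paste0(s, "_test")]] - j[[paste0(s, "_base")]]
  }
  sign_summary <- vapply(stats_cols, function(s) {
    sum(j[[paste0("d_", s)]] > 0, na.rm = TRUE)
  }, numeric(1))
  attr(j, "sign_summary") <- sign_summary
  attr(j, "n_settings") <- nrow(j)
  j
}
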