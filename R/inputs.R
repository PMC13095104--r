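#' Background Poisson drive configuration
#'
#' Every neuron receives an independent high-rate Poisson excitatory drive
#' standing in for uncorrelated cortical background. Rates are aggregate
#' generator rates in kHz; weights are the fixed background peak
#' conductances. In the no-FSI control (`n_fsi = 0`) the MSN background is
#' reduced to 3.2 kHz so the MSN firing rate stays comparable with the
#' conditions that include feedforward inhibition.
#'
#' @param n_fsi FSI count of the simulated network (switches the MSN rate).
#' @param msn_rate,fsi_rate,gpe_rate Generator rates, kHz.
#' @param msn_weight,fsi_weight Peak conductances, nS.
#' @return An object of class `background_config`.
#' @export
background_config <- function(n_fsi = 250,
                              msn_rate = if (n_fsi == 0) 3.2 else 5.95,
                              fsi_rate = 5.75, gpe_rate = 7.0,
                              msn_weight = 2.0, fsi_weight = 1.0) {
  stopifnot(msn_rate >= 0, fsi_rate >= 0, gpe_rate >= 0)
  structure(list(msn_rate = msn_rate, fsi_rate = fsi_rate,
                 gpe_rate = gpe_rate, msn_weight = msn_weight,
                 fsi_weight = fsi_weight),
            class = "background_config")
}

#' Cortical source-pool sizes from sharing fractions
#'
#' Each MSN group is driven by its own pool of cortical Poisson sources;
#' within-group sharing is `w_in = k_ctx / n_ctx` and between-group sharing
#' is `b_in = n_ol / n_ctx` where `n_ol` sources are common to the two
#' pools. Inverting for the pool sizes at a fixed indegree `k_ctx` gives
#' `n_ctx = round(k_ctx / w_in)` and `n_ol = round(b_in * n_ctx)`; the
#' realised fractions implied by the rounded sizes are reported alongside.
#'
#' @param w_in Requested within-group sharing, in (0, 1].
#' @param b_in Requested between-group sharing, in `[0, 1]`.
#' @param k_ctx Cortical indegree per MSN (default 100).
#' @return A list with `n_ctx`, `n_ol`, and the realised `w_in`, `b_in`.
#' @examples
#' pool_sizes_from_sharing(0.1, 0.5)   # n_ctx 1000, n_ol 500
#' @export
pool_sizes_from_sharing <- function(w_in, b_in, k_ctx = 100) {
  if (w_in <= 0 || w_in > 1) stop("w_in must lie in (0, 1]", call. = FALSE)
  stopifnot(b_in >= 0, b_in <= 1, k_ctx >= 1)
  n_ctx <- as.integer(round(k_ctx / w_in))
  n_ol <- as.integer(round(b_in * n_ctx))
  list(n_ctx = n_ctx, n_ol = n_ol,
       w_in = k_ctx / n_ctx, b_in = n_ol / n_ctx)
}

#' Cortical pool configuration
#'
#' Bundles the sharing fractions, pool sizes and drive parameters of the
#' two overlapping cortical source pools. Sources are 0-based and laid out
#' contiguously: pool A is `[0, n_ctx)`, pool B is
#' `[n_ctx - n_ol, 2 n_ctx - n_ol)`, so the `n_ol` overlap sources sit in
#' both pools.
#'
#' @inheritParams pool_sizes_from_sharing
#' @param source_rate Rate of each cortical source, Hz (default 10).
#' @param ctx_msn_weight Mean ctx-to-MSN peak conductance, nS (default 4.8).
#' @param ctx_fsi_weight Mean ctx-to-FSI peak conductance, nS (default
#'   0.25, half-strength because FSIs sample both pools).
#' @param weight_log_sd Lognormal log-scale sd for cortical weights.
#' @param delay_mean,delay_halfwidth Cortical delay distribution, ms. The
#'   nominal excitatory delay is 1 ms with +/-1 ms jitter; the default
#'   halfwidth is trimmed to 0.9 ms so every delay stays a positive
#'   multiple of the integration step.
#' @return An object of class `cortical_pool_config`.
#' @export
cortical_pool_config <- function(w_in, b_in, k_ctx = 100, source_rate = 10,
                                 ctx_msn_weight = 4.8, ctx_fsi_weight = 0.25,
                                 weight_log_sd = 0.5, delay_mean = 1,
                                 delay_halfwidth = 0.9) {
  sizes <- pool_sizes_from_sharing(w_in, b_in, k_ctx)
  structure(list(
    w_in_requested = w_in, b_in_requested = b_in,
    w_in = sizes$w_in, b_in = sizes$b_in,
    k_ctx = as.integer(k_ctx), n_ctx = sizes$n_ctx, n_ol = sizes$n_ol,
    n_sources = 2L * sizes$n_ctx - sizes$n_ol,
    source_rate = source_rate,
    ctx_msn_weight = ctx_msn_weight, ctx_fsi_weight = ctx_fsi_weight,
    weight_log_sd = weight_log_sd,
    delay_mean = delay_mean, delay_halfwidth = delay_halfwidth
  ), class = "cortical_pool_config")
}

#' @export
print.cortical_pool_config <- function(x, ...) {
  cat("<cortical_pool_config> w_in = ", signif(x$w_in, 3), ", b_in = ",
      signif(x$b_in, 3), " (n_ctx = ", x$n_ctx, ", n_ol = ", x$n_ol,
      ", ", x$n_sources, " sources at ", x$source_rate, " Hz)\n", sep = "")
  invisible(x)
}

pool_a_ids <- function(pool) 0:(pool$n_ctx - 1L)
pool_b_ids <- function(pool) (pool$n_ctx - pool$n_ol):(pool$n_sources - 1L)

#' Independent homogeneous Poisson spike trains
#'
#' @param rate Rate per source, Hz.
#' @param n_sources Number of sources (0-based ids).
#' @param duration Train length, ms.
#' @param seed Optional seed.
#' @return A tibble (`source_id`, `time_ms`) sorted by source then time.
#' @export
generate_poisson_trains <- function(rate, n_sources, duration, seed = NULL) {
  stopifnot(rate >= 0, n_sources >= 0, duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || n_sources == 0 || duration == 0) {
    return(tibble::tibble(source_id = integer(0), time_ms = numeric(0)))
  }
  counts <- stats::rpois(n_sources, rate * duration / 1000)
  times <- stats::runif(sum(counts), 0, duration)
  src <- rep(0:(n_sources - 1L), counts)
  ord <- order(src, times)
  tibble::tibble(source_id = src[ord], time_ms = times[ord])
}

draw_pool_wiring <- function(sources, targets, k, weight_mean, weight_log_sd,
                             delay_mean, delay_halfwidth) {
  n_syn <- k * length(targets)
  tibble::tibble(
    source = sample(sources, n_syn, replace = TRUE),
    target = rep(targets, each = k),
    weight = sample_weights(weight_mean, weight_log_sd, n_syn),
    delay = sample_delays(delay_mean, delay_halfwidth, n_syn)
  )
}

#' Wire cortical sources to MSNs
#'
#' Every MSN of group M_a receives `k_ctx` synapses drawn uniformly with
#' replacement from pool A, and every M_b neuron from pool B (multapses
#' counted with multiplicity), so the overlap sources drive both groups.
#' Weights are lognormal around the ctx-to-MSN mean; delays uniform.
#'
#' @param pool A [cortical_pool_config].
#' @param layout A [population_layout].
#' @param seed Optional seed.
#' @return A tibble (`source`, `target`, `weight`, `delay`).
#' @export
wire_ctx_to_msn <- function(pool, layout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(
    draw_pool_wiring(pool_a_ids(pool), layout$group_a, pool$k_ctx,
                     pool$ctx_msn_weight, pool$weight_log_sd,
                     pool$delay_mean, pool$delay_halfwidth),
    draw_pool_wiring(pool_b_ids(pool), layout$group_b, pool$k_ctx,
                     pool$ctx_msn_weight, pool$weight_log_sd,
                     pool$delay_mean, pool$delay_halfwidth)
  )
}

#' Wire cortical sources to FSIs
#'
#' FSIs sample the cortical drive of both MSN groups: by default each FSI
#' receives `k_ctx` synapses from each pool (200 at defaults) at
#' half-strength relative to the ctx-to-MSN projection; sources in the
#' overlap appear in both pools and so have double the expected
#' multiplicity. With `per_source = FALSE` each FSI instead receives
#' `k_ctx` synapses in total, drawn from the union of the two pools.
#'
#' @inheritParams wire_ctx_to_msn
#' @param per_source Draw `k_ctx` synapses from each pool (default) rather
#'   than `k_ctx` in total from the union.
#' @return A tibble (`source`, `target`, `weight`, `delay`); empty when
#'   the layout has no FSIs.
#' @export
wire_ctx_to_fsi <- function(pool, layout, seed = NULL, per_source = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (layout$n_fsi == 0) {
    return(tibble::tibble(source = integer(0), target = integer(0),
                          weight = numeric(0), delay = numeric(0)))
  }
  if (per_source) {
    dplyr::bind_rows(
      draw_pool_wiring(pool_a_ids(pool), layout$fsi_ids, pool$k_ctx,
                       pool$ctx_fsi_weight, pool$weight_log_sd,
                       pool$delay_mean, pool$delay_halfwidth),
      draw_pool_wiring(pool_b_ids(pool), layout$fsi_ids, pool$k_ctx,
                       pool$ctx_fsi_weight, pool$weight_log_sd,
                       pool$delay_mean, pool$delay_halfwidth)
    )
  } else {
    draw_pool_wiring(0:(pool$n_sources - 1L), layout$fsi_ids, pool$k_ctx,
                     pool$ctx_fsi_weight, pool$weight_log_sd,
                     pool$delay_mean, pool$delay_halfwidth)
  }
}

#' Expected input spike-count correlations
#'
#' For summed cortical input counts in large bins, the expected pairwise
#' correlation is the shared fraction of sources: `w_in` for two MSNs of
#' the same group and `b_in * w_in` across groups. Used as the closed-form
#' oracle when validating a wiring realisation.
#'
#' The shared-fraction values hold when multapses are rare (small `w_in`,
#' hence large pools). Sampling with replacement inflates each neuron's
#' private count variance by a factor `1 + (k_ctx - 1) / n_ctx`, which
#' divides the realised correlation; at `w_in = 0.1` the bias is about
#' 10% of the value, and it grows with `w_in`. Validate against the oracle
#' in the large-pool regime.
#'
#' @param pool A [cortical_pool_config].
#' @return Named vector `c(within = , between = )`.
#' @export
expected_input_correlation <- function(pool) {
  c(within = pool$w_in, between = pool$b_in * pool$w_in)
}

#' Frozen cortical input set for one trial set
#'
#' One stimulus realisation: the cortical source spike trains plus the
#' ctx-to-MSN and ctx-to-FSI wiring, all drawn once and then held identical
#' across every trial of a trial set (only the background noise and initial
#' states are redrawn per trial).
#'
#' @param pool A [cortical_pool_config].
#' @param layout A [population_layout].
#' @param duration Trial duration, ms.
#' @param seed Master seed; the trains and wiring use the `"ctx-trains"`
#'   and `"ctx-wiring"` sub-streams (see [sub_seed()]).
#' @param per_source_fsi Passed to [wire_ctx_to_fsi()].
#' @return An object of class `frozen_input_set`.
#' @export
frozen_input_set <- function(pool, layout, duration, seed,
                             per_source_fsi = TRUE) {
  trains <- generate_poisson_trains(pool$source_rate, pool$n_sources,
                                    duration, seed = sub_seed(seed, "ctx-trains"))
  msn_wiring <- wire_ctx_to_msn(pool, layout,
                                seed = sub_seed(seed, "ctx-wiring"))
  fsi_wiring <- wire_ctx_to_fsi(pool, layout,
                                seed = sub_seed(seed, "ctx-wiring", 1L),
                                per_source = per_source_fsi)
  structure(list(pool = pool, trains = trains, msn_wiring = msn_wiring,
                 fsi_wiring = fsi_wiring, duration = duration, seed = seed),
            class = "frozen_input_set")
}

#' Measured input-count correlations of a wiring realisation
#'
#' Empirical check of [expected_input_correlation()]: bins the summed
#' cortical input trains (with multiplicity) of randomly sampled MSN pairs
#' and returns the mean Pearson correlation within and between groups.
#'
#' @param inputs A [frozen_input_set].
#' @param layout The matching [population_layout].
#' @param bin Bin width, ms (default 100).
#' @param n_pairs Sampled pairs per category.
#' @param seed Optional seed for the pair draw.
#' @return A tibble with columns `kind`, `measured`, `expected`, `n_pairs`.
#' @export
measure_input_correlation <- function(inputs, layout, bin = 100,
                                      n_pairs = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- inputs$pool
  n_bins <- floor(inputs$duration / bin)
  n_src <- pool$n_sources
  tr <- inputs$trains[inputs$trains$time_ms < n_bins * bin, ]
  src_counts <- matrix(
    tabulate(floor(tr$time_ms / bin) * n_src + tr$source_id + 1L,
             nbins = n_src * n_bins),
    nrow = n_src, ncol = n_bins)
  # summed input counts (with multiplicity) per sampled MSN
  input_counts <- function(ids) {
    w <- inputs$msn_wiring[inputs$msn_wiring$target %in% ids, ]
    srcs_by_target <- split(w$source, w$target)
    t(vapply(as.character(ids), function(id) {
      colSums(src_counts[srcs_by_target[[id]] + 1L, , drop = FALSE])
    }, numeric(n_bins)))
  }
  sample_pair_ids <- function(ids_i, ids_j) {
    cbind(sample(ids_i, n_pairs, replace = TRUE),
          sample(ids_j, n_pairs, replace = TRUE))
  }
  pw <- sample_pair_ids(layout$group_a, layout$group_a)
  pw <- pw[pw[, 1] != pw[, 2], , drop = FALSE]
  pb <- sample_pair_ids(layout$group_a, layout$group_b)
  ids <- unique(c(pw, pb))
  cm <- input_counts(ids)
  rownames(cm) <- as.character(ids)
  pair_cor <- function(p) {
    mean(vapply(seq_len(nrow(p)), function(r) {
      stats::cor(cm[as.character(p[r, 1]), ], cm[as.character(p[r, 2]), ])
    }, numeric(1)), na.rm = TRUE)
  }
  expd <- expected_input_correlation(pool)
  tibble::tibble(
    kind = c("within", "between"),
    measured = c(pair_cor(pw), pair_cor(pb)),
    expected = as.numeric(expd),
    n_pairs = c(nrow(pw), nrow(pb))
  )
}
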