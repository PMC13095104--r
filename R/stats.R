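resolve_subset <- function(trialset, neurons) {
  lay <- trialset$layout
  if (is.null(neurons)) return(lay$group_a)
  if (is.character(neurons)) {
    return(switch(neurons,
                  a = lay$group_a, b = lay$group_b, all = lay$msn_ids,
                  fsi = lay$fsi_ids,
                  stop("unknown neuron subset '", neurons, "'", call. = FALSE)))
  }
  as.integer(neurons)
}

bin_counts_one_trial <- function(sp, ids, bin, win) {
  n_bins <- floor((win[2] - win[1]) / bin)
  keep <- sp$neuron_id %in% ids & sp$time_ms >= win[1] &
    sp$time_ms < win[1] + n_bins * bin
  b <- floor((sp$time_ms[keep] - win[1]) / bin) + 1L
  tabulate(b, nbins = n_bins)
}

# neurons x bins count matrix for one trial
neuron_count_matrix <- function(sp, ids, bin, win) {
  n_bins <- floor((win[2] - win[1]) / bin)
  keep <- sp$neuron_id %in% ids & sp$time_ms >= win[1] &
    sp$time_ms < win[1] + n_bins * bin
  row <- match(sp$neuron_id[keep], ids)
  col <- floor((sp$time_ms[keep] - win[1]) / bin) + 1L
  m <- matrix(tabulate((col - 1L) * length(ids) + row,
                       nbins = length(ids) * n_bins),
              nrow = length(ids), ncol = n_bins)
  rownames(m) <- as.character(ids)
  m
}

#' Binned population spike counts
#'
#' Total spike count of a neuron subset per time bin per trial, over the
#' analysis window (warm-up excluded; a trailing partial bin is dropped).
#'
#' @param trialset A [run_trials()] trial set.
#' @param neurons Subset: `"a"` (default, first MSN group), `"b"`, `"all"`
#'   (all MSNs), `"fsi"`, or a vector of 0-based neuron ids.
#' @param bin Bin width, ms (default 2).
#' @return A tibble (`trial`, `bin`, `t_start`, `count`).
#' @export
bin_population_counts <- function(trialset, neurons = NULL, bin = 2) {
  ids <- resolve_subset(trialset, neurons)
  if (length(ids) == 0) stop("empty neuron subset", call. = FALSE)
  win <- trialset$window
  n_bins <- floor((win[2] - win[1]) / bin)
  purrr::map_dfr(seq_along(trialset$spikes), function(tr) {
    counts <- bin_counts_one_trial(trialset$spikes[[tr]], ids, bin, win)
    tibble::tibble(trial = tr, bin = seq_len(n_bins),
                   t_start = win[1] + (seq_len(n_bins) - 1) * bin,
                   count = counts)
  })
}

#' Across-trial Fano factor of the population rate
#'
#' For each time bin, the Fano factor of the binned population spike count
#' across trials, `F_i = var(count_i) / mean(count_i)` (sample variance);
#' bins with zero mean count are excluded, and the variability index is the
#' mean of the remaining `F_i`. Since the population count is the
#' population-averaged rate times a constant, the index is identical to the
#' rate-based definition up to that constant, which cancels in the ratio.
#' An index near 1 indicates Poisson-like trial-to-trial variability of the
#' population trajectory; values above 1 indicate shared (correlated)
#' fluctuations across the population.
#'
#' @inheritParams bin_population_counts
#' @return An object of class `fano_result` with elements `ff` (the
#'   index), `per_bin` (tibble of valid `F_i`), `bin`, `n_trials`,
#'   `n_bins`, `n_excluded`.
#' @export
across_trial_fano <- function(trialset, neurons = NULL, bin = 2) {
  if (length(trialset$spikes) < 2) {
    stop("at least two trials are required", call. = FALSE)
  }
  ids <- resolve_subset(trialset, neurons)
  if (length(ids) == 0) stop("empty neuron subset", call. = FALSE)
  win <- trialset$window
  n_bins <- floor((win[2] - win[1]) / bin)
  counts <- vapply(trialset$spikes, bin_counts_one_trial, ids = ids,
                   bin = bin, win = win, FUN.VALUE = numeric(n_bins))
  counts <- if (n_bins == 1) matrix(counts, ncol = 1) else t(counts)
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  valid <- mu > 0
  if (!any(valid)) {
    stop("all bins have zero mean count; Fano factor undefined",
         call. = FALSE)
  }
  f_i <- v[valid] / mu[valid]
  structure(list(
    ff = mean(f_i),
    per_bin = tibble::tibble(bin = which(valid),
                             t_start = win[1] + (which(valid) - 1) * bin,
                             mean_count = mu[valid], var_count = v[valid],
                             fano = f_i),
    bin = bin, n_trials = nrow(counts), n_bins = ncol(counts),
    n_excluded = sum(!valid)
  ), class = "fano_result")
}

#' @export
print.fano_result <- function(x, ...) {
  cat("<fano_result> FF = ", signif(x$ff, 4), " (", x$n_trials,
      " trials, ", x$bin, " ms bins, ", x$n_excluded,
      " zero-mean bins excluded)\n", sep = "")
  invisible(x)
}

#' Pairwise spike-count correlation of two trains
#'
#' Pearson correlation of the binned spike counts of two trains over a
#' window. If either train has zero count variance the correlation is
#' undefined and `NA` is returned (not 0).
#'
#' @param times_i,times_j Spike time vectors, ms.
#' @param bin Bin width, ms (default 20).
#' @param window `c(t0, t1)` analysis window, ms.
#' @return A correlation in `[-1, 1]`, or `NA` for a zero-variance pair.
#' @export
pairwise_correlation <- function(times_i, times_j, bin = 20, window) {
  n_bins <- floor((window[2] - window[1]) / bin)
  cnt <- function(tt) {
    tt <- tt[tt >= window[1] & tt < window[1] + n_bins * bin]
    tabulate(floor((tt - window[1]) / bin) + 1L, nbins = n_bins)
  }
  ci <- cnt(times_i); cj <- cnt(times_j)
  if (stats::var(ci) == 0 || stats::var(cj) == 0) return(NA_real_)
  stats::cor(ci, cj)
}

sample_pairs <- function(ids_i, ids_j, budget) {
  p1 <- sample(ids_i, budget, replace = TRUE)
  p2 <- sample(ids_j, budget, replace = TRUE)
  keep <- p1 != p2
  cbind(p1[keep], p2[keep])
}

#' Correlation transfer: within- and between-group output correlations
#'
#' Mean pairwise Pearson correlation of 20 ms binned MSN spike counts,
#' within each MSN group (`w_out`, the mean of the two group means, which
#' coincides with the normalised sum over ordered pairs for equal group
#' sizes) and between the groups (`b_out`). Correlations are computed per
#' trial over the analysis window and then averaged across trials; pairs
#' where either neuron has zero count variance in a trial are excluded
#' from that trial's mean. For tractability pairs are subsampled uniformly
#' (the same pairs in every trial); set `pair_budget = Inf` to enumerate
#' all pairs.
#'
#' @param trialset A [run_trials()] trial set.
#' @param bin Bin width, ms (default 20).
#' @param pair_budget Number of sampled pairs per category (default 5000).
#' @param seed Seed for the pair draw.
#' @return An object of class `corr_transfer` with trial-averaged `w_out`
#'   and `b_out` and a `per_trial` tibble.
#' @export
correlation_transfer <- function(trialset, bin = 20, pair_budget = 5000,
                                 seed = 1) {
  lay <- trialset$layout
  win <- trialset$window
  set.seed(seed)
  half <- function(ids) {
    n <- length(ids)
    n_all <- n * (n - 1) / 2
    if (!is.finite(pair_budget) || pair_budget >= n_all) {
      idx <- utils::combn(ids, 2)
      cbind(idx[1, ], idx[2, ])
    } else {
      sample_pairs(ids, ids, ceiling(pair_budget))
    }
  }
  pairs_a <- half(lay$group_a)
  pairs_b <- half(lay$group_b)
  n_ab <- length(lay$group_a) * length(lay$group_b)
  pairs_ab <- if (!is.finite(pair_budget) || pair_budget >= n_ab) {
    as.matrix(expand.grid(lay$group_a, lay$group_b))
  } else {
    cbind(sample(lay$group_a, pair_budget, replace = TRUE),
          sample(lay$group_b, pair_budget, replace = TRUE))
  }

  per_trial <- purrr::map_dfr(seq_along(trialset$spikes), function(tr) {
    m <- neuron_count_matrix(trialset$spikes[[tr]], lay$msn_ids, bin, win)
    mc <- m - rowMeans(m)
    ss <- sqrt(rowSums(mc^2))
    pc <- function(p) {
      i <- p[, 1] + 1L; j <- p[, 2] + 1L
      denom <- ss[i] * ss[j]
      r <- rowSums(mc[i, , drop = FALSE] * mc[j, , drop = FALSE]) / denom
      r[denom == 0] <- NA_real_
      r
    }
    ra <- pc(pairs_a); rb <- pc(pairs_b); rab <- pc(pairs_ab)
    tibble::tibble(
      trial = tr,
      w_out = mean(c(mean(ra, na.rm = TRUE), mean(rb, na.rm = TRUE))),
      b_out = mean(rab, na.rm = TRUE),
      n_pairs_within = sum(!is.na(ra)) + sum(!is.na(rb)),
      n_pairs_between = sum(!is.na(rab)),
      n_excluded = sum(is.na(ra)) + sum(is.na(rb)) + sum(is.na(rab))
    )
  })
  structure(list(w_out = mean(per_trial$w_out, na.rm = TRUE),
                 b_out = mean(per_trial$b_out, na.rm = TRUE),
                 per_trial = per_trial, bin = bin,
                 pair_budget = pair_budget),
            class = "corr_transfer")
}

#' @export
print.corr_transfer <- function(x, ...) {
  cat("<corr_transfer> w_out = ", signif(x$w_out, 4), ", b_out = ",
      signif(x$b_out, 4), " (", nrow(x$per_trial), " trials, ",
      x$bin, " ms bins)\n", sep = "")
  invisible(x)
}

#' Burst index of a spike train across trials
#'
#' Maximal runs of consecutive interspike intervals shorter than `isi_max`
#' define spike groups; a group is a burst when it contains at least
#' `min_spikes` spikes (default 4, the strict reading of "size larger than
#' three"). The burst index of a trial is the fraction of its spikes that
#' belong to bursts, and the index is averaged over trials; trials without
#' spikes are excluded.
#'
#' @param trains A list of per-trial spike time vectors (ms, sorted), or a
#'   single numeric vector for one trial.
#' @param isi_max Maximal intra-burst interspike interval, ms (default 10).
#' @param min_spikes Minimal burst size in spikes (default 4; set 3 for
#'   the inclusive convention).
#' @return An object of class `burst_stats` with the trial-averaged `bi`
#'   and a `per_trial` tibble.
#' @export
burst_index <- function(trains, isi_max = 10, min_spikes = 4) {
  if (is.numeric(trains)) trains <- list(trains)
  per_trial <- purrr::map_dfr(seq_along(trains), function(tr) {
    tt <- sort(trains[[tr]])
    n <- length(tt)
    if (n == 0) {
      return(tibble::tibble(trial = tr, n_spikes = 0L, n_burst_spikes = 0L,
                            bi = NA_real_))
    }
    if (n == 1) {
      return(tibble::tibble(trial = tr, n_spikes = 1L, n_burst_spikes = 0L,
                            bi = 0))
    }
    r <- rle(diff(tt) < isi_max)
    sizes <- r$lengths + 1L           # spikes per maximal run of short ISIs
    burst_spikes <- sum(sizes[r$values & sizes >= min_spikes])
    tibble::tibble(trial = tr, n_spikes = n,
                   n_burst_spikes = as.integer(burst_spikes),
                   bi = burst_spikes / n)
  })
  structure(list(bi = mean(per_trial$bi, na.rm = TRUE),
                 per_trial = per_trial, isi_max = isi_max,
                 min_spikes = min_spikes),
            class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat("<burst_stats> BI = ", signif(x$bi, 4), " over ",
      sum(!is.na(x$per_trial$bi)), " trials\n", sep = "")
  invisible(x)
}

#' Across-trial Fano factor of the total spike count
#'
#' Variance-to-mean ratio (sample variance) of the total spike count in the
#' analysis window across trials — the spike-count variability measure used
#' for the downstream readout neuron.
#'
#' @param trains A list of per-trial spike time vectors, ms.
#' @param window `c(t0, t1)` analysis window, ms.
#' @return An object of class `count_fano` with `ff` and the per-trial
#'   counts.
#' @export
gpe_count_fano <- function(trains, window) {
  if (length(trains) < 2) stop("at least two trials required", call. = FALSE)
  counts <- vapply(trains, function(tt) {
    sum(tt >= window[1] & tt < window[2])
  }, numeric(1))
  if (mean(counts) == 0) {
    stop("zero mean spike count; Fano factor undefined", call. = FALSE)
  }
  structure(list(ff = stats::var(counts) / mean(counts), counts = counts,
                 window = window),
            class = "count_fano")
}

#' @export
print.count_fano <- function(x, ...) {
  cat("<count_fano> FF = ", signif(x$ff, 4), " over ", length(x$counts),
      " trials (mean count ", signif(mean(x$counts), 4), ")\n", sep = "")
  invisible(x)
}

#' Per-trial spike trains of one unit
#'
#' @param trialset A [run_trials()] trial set.
#' @param id 0-based neuron id.
#' @return A list of numeric spike-time vectors, one per trial.
#' @export
unit_trains <- function(trialset, id) {
  lapply(trialset$spikes, function(sp) sp$time_ms[sp$neuron_id == id])
}
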