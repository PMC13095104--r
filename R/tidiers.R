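#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname across_trial_fano
#' @param x A `fano_result`.
#' @param ... Unused.
#' @export
tidy.fano_result <- function(x, ...) x$per_bin

#' @rdname across_trial_fano
#' @export
glance.fano_result <- function(x, ...) {
  tibble::tibble(ff = x$ff, bin_ms = x$bin, n_trials = x$n_trials,
                 n_bins = x$n_bins, n_excluded = x$n_excluded)
}

#' @rdname correlation_transfer
#' @param x A `corr_transfer`.
#' @param ... Unused.
#' @export
tidy.corr_transfer <- function(x, ...) x$per_trial

#' @rdname correlation_transfer
#' @export
glance.corr_transfer <- function(x, ...) {
  tibble::tibble(w_out = x$w_out, b_out = x$b_out,
                 n_trials = nrow(x$per_trial), bin_ms = x$bin)
}

#' @rdname burst_index
#' @param x A `burst_stats`.
#' @param ... Unused.
#' @export
tidy.burst_stats <- function(x, ...) x$per_trial

#' @rdname burst_index
#' @export
glance.burst_stats <- function(x, ...) {
  tibble::tibble(bi = x$bi,
                 n_trials = sum(!is.na(x$per_trial$bi)),
                 isi_max_ms = x$isi_max, min_spikes = x$min_spikes)
}

#' @rdname gpe_count_fano
#' @param x A `count_fano`.
#' @param ... Unused.
#' @export
glance.count_fano <- function(x, ...) {
  tibble::tibble(ff = x$ff, mean_count = mean(x$counts),
                 n_trials = length(x$counts))
}
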