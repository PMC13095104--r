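#' Population layout of the striatal circuit
#'
#' The modelled striatum holds `n_msn` medium spiny neurons split into two
#' equal groups (M_a and M_b, distinguished by their cortical source pools)
#' and `n_fsi` fast-spiking interneurons. Neuron ids are 0-based and
#' contiguous: MSNs occupy `[0, n_msn)` with M_a the first half, and FSIs
#' occupy `[n_msn, n_msn + n_fsi)`.
#'
#' @param n_msn Number of MSNs (even; default 2500).
#' @param n_fsi Number of FSIs (default 250; 0 is the no-FFI control).
#' @return An object of class `population_layout`.
#' @examples
#' population_layout(2500, 25)
#' @export
population_layout <- function(n_msn = 2500, n_fsi = 250) {
  stopifnot(n_msn >= 2, n_msn %% 2 == 0, n_fsi >= 0)
  structure(list(
    n_msn = as.integer(n_msn),
    n_fsi = as.integer(n_fsi),
    msn_ids = 0:(n_msn - 1L),
    group_a = 0:(n_msn / 2 - 1L),
    group_b = (n_msn / 2):(n_msn - 1L),
    fsi_ids = if (n_fsi > 0) n_msn + 0:(n_fsi - 1L) else integer(0)
  ), class = "population_layout")
}

#' @export
print.population_layout <- function(x, ...) {
  cat("<population_layout> ", x$n_msn, " MSNs (two groups of ",
      x$n_msn / 2, "), ", x$n_fsi, " FSIs\n", sep = "")
  invisible(x)
}

#' A fixed-indegree connection rule
#'
#' Describes one projection: every neuron of the target population receives
#' exactly `indegree` synapses whose presynaptic partners are drawn
#' uniformly with replacement from the source population (multapses
#' permitted; autapses only where allowed). Peak conductances are lognormal
#' with the stated arithmetic mean and log-scale sd; delays are uniform on
#' `mean +/- halfwidth`.
#'
#' @param source,target Population names (`"MSN"` or `"FSI"`).
#' @param indegree Synapses per target neuron.
#' @param weight_mean Arithmetic mean peak conductance, nS.
#' @param weight_log_sd Log-scale standard deviation (default 0.5).
#' @param delay_mean,delay_halfwidth Delay distribution, ms (default
#'   halfwidth 1).
#' @param type `"excitatory"` or `"inhibitory"`.
#' @param allow_autapse Permit self-connections (only meaningful when
#'   source and target coincide).
#' @return An object of class `connection_rule`.
#' @export
connection_rule <- function(source, target, indegree, weight_mean,
                            weight_log_sd = 0.5, delay_mean,
                            delay_halfwidth = 1, type, allow_autapse = FALSE) {
  stopifnot(indegree >= 0, weight_mean >= 0, weight_log_sd >= 0,
            delay_mean - delay_halfwidth > 0,
            type %in% c("excitatory", "inhibitory"))
  structure(list(source = source, target = target,
                 indegree = as.integer(indegree),
                 weight_mean = weight_mean, weight_log_sd = weight_log_sd,
                 delay_mean = delay_mean, delay_halfwidth = delay_halfwidth,
                 type = type, allow_autapse = allow_autapse),
            class = "connection_rule")
}

#' Default striatal connection rules
#'
#' Recurrent MSN inhibition (indegree 250, mean 0.03 nS, 2 ms delay,
#' autapses allowed) and feedforward FSI inhibition onto MSNs (indegree 15,
#' mean 0.5 nS, 2 ms delay). There are no MSN to FSI and no FSI to FSI
#' connections in the circuit.
#'
#' @return A named list of [connection_rule]s.
#' @export
default_rules <- function() {
  list(
    msn_msn = connection_rule("MSN", "MSN", indegree = 250,
                              weight_mean = 0.03, delay_mean = 2,
                              type = "inhibitory", allow_autapse = TRUE),
    fsi_msn = connection_rule("FSI", "MSN", indegree = 15,
                              weight_mean = 0.5, delay_mean = 2,
                              type = "inhibitory", allow_autapse = FALSE)
  )
}

#' Lognormal synaptic weights with a fixed arithmetic mean
#'
#' Draws `n` peak conductances from a lognormal distribution whose
#' log-scale standard deviation is `log_sd` and whose arithmetic mean is
#' `mean`, i.e. log-mean `log(mean) - log_sd^2 / 2`. With `log_sd = 0` all
#' draws equal `mean`.
#'
#' @param mean Arithmetic mean, nS (> 0).
#' @param log_sd Log-scale sd (>= 0).
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of positive conductances.
#' @export
sample_weights <- function(mean, log_sd = 0.5, n, seed = NULL) {
  stopifnot(mean > 0, log_sd >= 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (log_sd == 0) return(rep(mean, n))
  stats::rlnorm(n, meanlog = log(mean) - log_sd^2 / 2, sdlog = log_sd)
}

#' Uniform synaptic delays
#'
#' Delays drawn uniformly on `[mean - halfwidth, mean + halfwidth]` ms; the
#' lower bound must be positive.
#'
#' @param mean Mean delay, ms.
#' @param halfwidth Half-range, ms.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of delays in ms.
#' @export
sample_delays <- function(mean, halfwidth = 1, n, seed = NULL) {
  if (mean - halfwidth <= 0) {
    stop("delay distribution must have a positive lower bound", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (halfwidth == 0) return(rep(mean, n))
  stats::runif(n, mean - halfwidth, mean + halfwidth)
}

#' Sharing fraction of feedforward inhibition
#'
#' With a fixed FSI indegree per MSN, the expected fraction of the FSI
#' population seen by any one MSN is `ffi_indegree / n_fsi`: 60% with 25
#' FSIs, 6% with 250 FSIs at the default indegree of 15.
#'
#' @param ffi_indegree FSI inputs per MSN (default 15).
#' @param n_fsi FSI population size (> 0).
#' @return Sharing fraction.
#' @export
ffi_sharing_fraction <- function(ffi_indegree = 15, n_fsi) {
  if (n_fsi == 0) {
    stop("FFI sharing is undefined when n_fsi = 0 (control condition)",
         call. = FALSE)
  }
  stopifnot(n_fsi > 0, ffi_indegree >= 0)
  ffi_indegree / n_fsi
}

pop_ids <- function(layout, pop) {
  switch(pop,
         MSN = layout$msn_ids,
         FSI = layout$fsi_ids,
         stop("unknown population '", pop, "'", call. = FALSE))
}

draw_rule_edges <- function(rule, layout) {
  src <- pop_ids(layout, rule$source)
  tgt <- pop_ids(layout, rule$target)
  if (rule$indegree == 0 || length(tgt) == 0) {
    return(tibble::tibble(pre = integer(0), post = integer(0),
                          type = character(0), conductance = numeric(0),
                          delay = numeric(0)))
  }
  if (length(src) == 0) {
    stop("rule ", rule$source, "->", rule$target,
         " has positive indegree but an empty source population",
         call. = FALSE)
  }
  n_syn <- rule$indegree * length(tgt)
  post <- rep(tgt, each = rule$indegree)
  pre <- sample(src, n_syn, replace = TRUE)
  if (!rule$allow_autapse && rule$source == rule$target) {
    bad <- which(pre == post)
    while (length(bad) > 0) {
      pre[bad] <- sample(src, length(bad), replace = TRUE)
      bad <- bad[pre[bad] == post[bad]]
    }
  }
  tibble::tibble(
    pre = pre, post = post, type = rule$type,
    conductance = sample_weights(rule$weight_mean, rule$weight_log_sd, n_syn),
    delay = sample_delays(rule$delay_mean, rule$delay_halfwidth, n_syn)
  )
}

#' Build the striatal network
#'
#' Draws an explicit synapse list realising every [connection_rule] with
#' exact per-target indegrees: presynaptic partners are sampled uniformly
#' with replacement (multapses allowed; autapses only for the recurrent MSN
#' projection), weights are lognormal, delays uniform. With `n_fsi = 0` the
#' FSI rule produces no synapses and the network is the no-FFI control.
#'
#' @param layout A [population_layout].
#' @param rules A list of [connection_rule]s (default [default_rules()]).
#' @param seed Integer seed for the wiring draw.
#' @return An object of class `striatum_network`: the layout, a synapse
#'   tibble (`pre`, `post`, `type`, `conductance` nS, `delay` ms), the
#'   rules and the seed.
#' @examples
#' net <- build_striatum(population_layout(100, 10), seed = 1)
#' nrow(net$synapses)  # 100 * 250 + 100 * 15
#' @export
build_striatum <- function(layout, rules = default_rules(), seed = 1) {
  stopifnot(inherits(layout, "population_layout"))
  has_fsi_rule <- any(vapply(rules, function(r) r$source == "FSI", logical(1)))
  if (layout$n_fsi > 0 && !has_fsi_rule) {
    stop("layout has FSIs but no FSI connection rule was given", call. = FALSE)
  }
  set.seed(seed)
  use <- rules[vapply(rules, function(r) {
    !(r$source == "FSI" && layout$n_fsi == 0)
  }, logical(1))]
  synapses <- dplyr::bind_rows(lapply(use, draw_rule_edges, layout = layout))
  structure(list(layout = layout, synapses = synapses, rules = rules,
                 seed = seed),
            class = "striatum_network")
}

#' @export
print.striatum_network <- function(x, ...) {
  cat("<striatum_network> ", x$layout$n_msn, " MSNs + ", x$layout$n_fsi,
      " FSIs, ", nrow(x$synapses), " synapses (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a network edge list
#'
#' The synapse table is written as plain CSV (`pre_id`, `post_id`, `type`,
#' `conductance_nS`, `delay_ms`) with a JSON sidecar holding the layout and
#' seed, so a wiring realisation can be archived or inspected outside R.
#'
#' @param network A `striatum_network`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(network, path) {
  syn <- network$synapses
  utils::write.csv(
    data.frame(pre_id = syn$pre, post_id = syn$post, type = syn$type,
               conductance_nS = syn$conductance, delay_ms = syn$delay),
    path, row.names = FALSE)
  meta <- list(n_msn = network$layout$n_msn, n_fsi = network$layout$n_fsi,
               seed = network$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
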