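#' Neuron parameters for one cell class
#'
#' Returns the conductance-based leaky integrate-and-fire parameter set for
#' one of the three modelled cell classes: striatal medium spiny neurons
#' (`"MSN"`), fast-spiking interneurons (`"FSI"`), or the downstream pallidal
#' readout neuron (`"GPE"`).
#'
#' All units follow the common convention for point-neuron simulators:
#' capacitance in pF, conductances in nS, potentials in mV, times in ms.
#' With these units currents come out in pA.
#'
#' @param cell_class One of `"MSN"`, `"FSI"`, `"GPE"` (case-insensitive).
#'
#' @return An object of class `neuron_params`: a named list with fields
#'   `C_m` (pF), `g_L` (nS), `E_L` (mV), `V_th` (mV), `V_reset` (mV),
#'   `t_r` (ms), `E_e` (mV), `E_i` (mV), `tau_e` (ms), `tau_i` (ms), and
#'   `cell_class`.
#'
#' @examples
#' p <- neuron_params("MSN")
#' rheobase(p)  # 350 pA
#' @export
neuron_params <- function(cell_class = c("MSN", "FSI", "GPE")) {
  cls <- toupper(cell_class[1])
  tab <- list(
    MSN = list(C_m = 80, g_L = 10,  E_L = -80, V_th = -45, V_reset = -70),
    FSI = list(C_m = 70, g_L = 5,   E_L = -70, V_th = -40, V_reset = -60),
    GPE = list(C_m = 70, g_L = 2.5, E_L = -70, V_th = -45, V_reset = -60)
  )
  if (!cls %in% names(tab)) {
    stop("unknown cell class '", cell_class[1],
         "'; expected one of MSN, FSI, GPE", call. = FALSE)
  }
  p <- c(tab[[cls]],
         list(t_r = 2, E_e = 0, E_i = -85, tau_e = 0.2, tau_i = 15,
              cell_class = cls))
  structure(p, class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params: ", x$cell_class, ">\n", sep = "")
  flds <- setdiff(names(x), "cell_class")
  cat(paste0("  ", flds, " = ", unlist(x[flds])), sep = "\n")
  invisible(x)
}

validate_neuron_params <- function(p) {
  stopifnot(p$C_m > 0, p$g_L > 0, p$tau_e > 0, p$tau_i > 0,
            p$t_r >= 0, p$V_reset < p$V_th, p$E_L < p$V_th)
  invisible(p)
}

#' Rheobase current of a LIF neuron
#'
#' The minimal DC current for which the steady-state membrane potential
#' reaches threshold: `g_L * (V_th - E_L)` (nS x mV = pA).
#'
#' @param params A [neuron_params] object.
#' @return Current in pA.
#' @examples
#' rheobase(neuron_params("FSI"))  # 150 pA
#' @export
rheobase <- function(params) {
  validate_neuron_params(params)
  params$g_L * (params$V_th - params$E_L)
}

#' Closed-form firing rate of a LIF neuron under DC current
#'
#' The stationary firing rate of a leaky integrate-and-fire neuron driven by
#' a constant current `I`, from the deterministic interspike interval
#' `t_r + tau_m * log((V_ss - V_reset) / (V_ss - V_th))` with
#' `tau_m = C_m / g_L` and `V_ss = E_L + I / g_L`. Zero at or below rheobase.
#' Serves as an independent oracle for the simulated F-I curve.
#'
#' @param params A [neuron_params] object.
#' @param I DC current in pA (vectorised).
#' @return Firing rate in Hz.
#' @examples
#' dc_firing_rate(neuron_params("MSN"), c(300, 400))
#' @export
dc_firing_rate <- function(params, I) {
  validate_neuron_params(params)
  tau_m <- params$C_m / params$g_L
  v_ss <- params$E_L + I / params$g_L
  rate <- numeric(length(I))
  above <- I > rheobase(params)
  isi <- params$t_r +
    tau_m * log((v_ss[above] - params$V_reset) / (v_ss[above] - params$V_th))
  rate[above] <- 1000 / isi  # ms -> Hz
  rate
}

#' Alpha-function synaptic conductance
#'
#' Summed conductance at times `t` produced by a set of synaptic events,
#' each contributing an alpha kernel
#' `gbar * e * ((t - t_i)/tau) * exp(-(t - t_i)/tau)` for `t >= t_i`
#' (zero before arrival). The factor `e` normalises the kernel so that it
#' peaks at exactly `peak_conductance` one `tau` after arrival, matching the
#' usual simulator convention for alpha synapses; set `normalize = FALSE`
#' for the bare form peaking at `gbar / e`.
#'
#' @param t Query times in ms (vectorised).
#' @param events A data frame with columns `arrival_time` (ms),
#'   `peak_conductance` (nS) and `tau` (ms), one row per event.
#' @param normalize Include the factor `e` so each kernel peaks at its
#'   `peak_conductance` (default `TRUE`).
#' @return Conductance in nS, one value per element of `t`.
#' @examples
#' ev <- tibble::tibble(arrival_time = 10, peak_conductance = 0.5, tau = 15)
#' alpha_conductance(25, ev)  # 0.5 at the peak
#' @export
alpha_conductance <- function(t, events, normalize = TRUE) {
  stopifnot(all(c("arrival_time", "peak_conductance", "tau") %in% names(events)))
  stopifnot(all(events$peak_conductance >= 0), all(events$tau > 0))
  scale <- if (normalize) exp(1) else 1
  vapply(t, function(tt) {
    dt <- tt - events$arrival_time
    on <- dt > 0
    sum(scale * events$peak_conductance[on] * (dt[on] / events$tau[on]) *
          exp(-dt[on] / events$tau[on]))
  }, numeric(1))
}

#' Specification of neuron-to-neuron parameter heterogeneity
#'
#' In the heterogeneous variant of the model, `C_m`, `g_L`, `V_th` and `t_r`
#' are drawn per neuron from normal distributions centred on the class
#' defaults with standard deviation `relative_sd` times the absolute mean,
#' and the inhibitory synaptic time constant is drawn from
#' `Normal(tau_i_mean, tau_i_variance)`. At the default `relative_sd = 1/30`
#' nearly all draws (3 sigma) lie within +/-10% of the class value.
#'
#' @param relative_sd Relative standard deviation applied to `C_m`, `g_L`,
#'   `V_th`, `t_r` (default `1/30`).
#' @param tau_i_mean Mean inhibitory time constant, ms (default 15).
#' @param tau_i_variance Variance of the inhibitory time constant, ms^2
#'   (default 0.5).
#' @return An object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(relative_sd = 1 / 30, tau_i_mean = 15,
                               tau_i_variance = 0.5) {
  stopifnot(relative_sd >= 0, tau_i_mean > 0, tau_i_variance >= 0)
  structure(list(relative_sd = relative_sd, tau_i_mean = tau_i_mean,
                 tau_i_variance = tau_i_variance),
            class = "heterogeneity_spec")
}

#' Sample heterogeneous neuron parameter sets
#'
#' Draws `n` parameter sets around a base [neuron_params]. `C_m`, `g_L`,
#' `V_th` and `t_r` are sampled independently as
#' `Normal(base, (|base| * relative_sd)^2)`; `tau_i` as
#' `Normal(tau_i_mean, tau_i_variance)`. Draws violating the parameter
#' invariants (positivity where required, `V_reset < V_th`) are rejected and
#' redrawn rather than clipped, so no probability mass accumulates at the
#' bounds.
#'
#' @param base A [neuron_params] object.
#' @param spec A [heterogeneity_spec].
#' @param n Number of parameter sets.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `n` rows and the columns of [neuron_params].
#' @export
sample_heterogeneous <- function(base, spec = heterogeneity_spec(), n,
                                 seed = NULL) {
  validate_neuron_params(base)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)

  draw <- function(mean, sd, lower = -Inf, upper = Inf) {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= lower | x >= upper)
    guard <- 0L
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= lower | x[bad] >= upper]
      guard <- guard + 1L
      if (guard > 1000L) stop("rejection sampling failed to converge")
    }
    x
  }

  rs <- spec$relative_sd
  tibble::tibble(
    C_m   = draw(base$C_m, abs(base$C_m) * rs, lower = 0),
    g_L   = draw(base$g_L, abs(base$g_L) * rs, lower = 0),
    E_L   = rep(base$E_L, n),
    V_th  = draw(base$V_th, abs(base$V_th) * rs, lower = base$V_reset),
    V_reset = rep(base$V_reset, n),
    t_r   = if (base$t_r > 0) draw(base$t_r, abs(base$t_r) * rs, lower = 0)
            else rep(0, n),
    E_e   = rep(base$E_e, n),
    E_i   = rep(base$E_i, n),
    tau_e = rep(base$tau_e, n),
    tau_i = draw(spec$tau_i_mean, sqrt(spec$tau_i_variance), lower = 0)
  )
}

# Replicate a homogeneous parameter set into the same tabular layout as
# sample_heterogeneous(), so the simulation assembly has one code path.
homogeneous_table <- function(base, n) {
  flds <- c("C_m", "g_L", "E_L", "V_th", "V_reset", "t_r",
            "E_e", "E_i", "tau_e", "tau_i")
  tibble::as_tibble(lapply(stats::setNames(flds, flds),
                           function(f) rep(base[[f]], n)))
}
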