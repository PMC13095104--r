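#' Derive a named sub-seed from a master seed
#'
#' One master seed spawns independent, reproducible sub-streams for the
#' network wiring, the cortical spike trains, the cortical wiring, and the
#' per-trial background and initial-state draws, so any component of an
#' experiment can be regenerated in isolation. The derivation is a small
#' deterministic integer hash of `(master, stream, index)` kept strictly
#' below 2^31.
#'
#' @param master Master integer seed.
#' @param stream Stream name, e.g. `"network"`, `"ctx-trains"`,
#'   `"ctx-wiring"`, `"background"`, `"initial-state"`.
#' @param index Optional index within the stream (e.g. trial number).
#' @return A positive integer seed.
#' @export
sub_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1)
  m <- 2147483647  # 2^31 - 1
  h <- (as.numeric(master) %% m)
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 131 + as.numeric(index) %% m) %% m
  as.integer(h %% (m - 1L) + 1L)
}
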