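#' @keywords internal
"_PACKAGE"

# Internal validation helper: stop with a clean message, no call.
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a master seed
#'
#' One master integer seed governs every source of randomness in a run;
#' per-stage substreams are derived deterministically from it so that partial
#' reruns of a stage reproduce exactly. The derived seed is kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param label Character stage label (e.g. "cohort", "flow").
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  .check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
         "seed must be a single finite number")
  codes <- utf8ToInt(as.character(label))
  h <- (sum(codes * seq_along(codes) * 2654435) + 97) %% 1000003
  as.integer((abs(seed) * 1009 + h) %% .Machine$integer.max)
}

# Wrap phase values to the half-open interval (-pi, pi].
.wrap_phase <- function(phi) {
  w <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  w[w == -pi] <- pi   # exact boundary: v = VENC maps to +pi, not -pi
  w
}
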