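# internal helpers shared across modules

#' Logistic gating steady state
#'
#' Standard Hodgkin--Huxley-style logistic steady-state activation,
#' \eqn{x_\infty(V) = 1 / (1 + \exp(-(V - V_{half}) / slope))}. With a positive
#' slope the gate opens as \code{V} increases; a negative slope gives a gate
#' that opens on hyperpolarization.
#'
#' @param V membrane potential (mV); may be a vector. Must be finite.
#' @param V_half half-activation voltage (mV).
#' @param slope slope factor (mV); must be nonzero. Sign sets the direction.
#' @return activation in (0, 1), same length as \code{V}.
#' @examples
#' gate_steady_state(-50, V_half = -50, slope = 10)  # 0.5 at midpoint
#' @export
gate_steady_state <- function(V, V_half, slope) {
  if (!is.numeric(V) || any(!is.finite(V))) {
    stop("gate_steady_state(): 'V' must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0) {
    stop("gate_steady_state(): 'slope' must be a single nonzero number", call. = FALSE)
  }
  stats::plogis((V - V_half) / slope)
}

# plain logistic on an already-scaled argument
sigmoid <- function(x) stats::plogis(x)

#' Derive a per-stream seed from a master seed
#'
#' Counter-based seed fan-out: every module draws its random stream from a
#' sub-seed derived from the single user-facing seed and a stream label, so
#' adding a pipeline stage never perturbs another stage's stream. The
#' derivation is a small integer hash folded into [1, 2^31 - 2].
#'
#' @param seed master seed (single integer-like value).
#' @param stream stream label: a string or a non-negative integer counter.
#' @return a single integer seed suitable for \code{set.seed()}.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  stopifnot(is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647  # 2^31 - 1 (Mersenne prime), Lehmer-style fold
  x <- (abs(seed) %% m)
  x <- (x * 48271 + 2 * stream + 1) %% m
  x <- (x * 69621 + 7919) %% m
  as.integer(x %% (m - 1L) + 1L)
}

# stop() with sprintf formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("'%s' must be a single positive finite number", name)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stopf("'%s' must be a single non-negative finite number", name)
  }
  invisible(x)
}
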