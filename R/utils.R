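#' Convert between molar concentrations and pK values
#'
#' Affinity constants are stored internally in molar units and reported as
#' negative decadic logarithms (pK), the convention used throughout
#' pharmacology tables.
#'
#' @param K concentration in molar (for `to_pK`) or pK value (for `from_pK`).
#' @return numeric vector of the converted quantity.
#' @export
to_pK <- function(K) {
  stopifnot(is.numeric(K))
  if (any(K <= 0, na.rm = TRUE)) stop("K must be positive to take -log10")
  -log10(K)
}

#' @rdname to_pK
#' @export
from_pK <- function(K) 10^(-K)

# Deterministic per-stream seed derivation from one user-facing seed.
# Keeps derived seeds inside the 32-bit integer range.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 7919 + stream * 104729) %% .Machine$integer.max)
}

# Multiplicative Gaussian noise truncated at zero: counts-type signals
# cannot go negative and their error scales with magnitude.
apply_cv_noise <- function(y, cv) {
  if (cv < 0) stop("noise cv must be non-negative")
  if (cv == 0) return(y)
  pmax(0, y * (1 + stats::rnorm(length(y), 0, cv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(errorCondition(paste0(...),
  class = c("tandemsite_parameter_error", "error")))

stop_numeric <- function(...) stop(errorCondition(paste0(...),
  class = c("tandemsite_numerical_error", "error")))

stop_validation <- function(...) stop(errorCondition(paste0(...),
  class = c("tandemsite_validation_error", "error")))

stop_fit <- function(...) stop(errorCondition(paste0(...),
  class = c("tandemsite_fit_error", "error")))
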