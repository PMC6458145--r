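#' Run an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded package functions do not disturb the
#' global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of sub-seeds from a master seed; keeps every derived seed
# a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Quantile function of a normal truncated to [lower, upper].
qtruncnorm <- function(p, mean, sd, lower, upper) {
  stopifnot(all(p >= 0 & p <= 1), sd >= 0, lower < upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), length(p)))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  q <- stats::qnorm(plo + p * (phi - plo), mean, sd)
  pmin(pmax(q, lower), upper)
}

# Overflow-safe logistic: sigmoid(x) = 1 / (1 + exp(-x)).
sigmoid <- function(x) stats::plogis(x)

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
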