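#' @keywords internal
"_PACKAGE"

#' Logistic (sigmoid) function
#'
#' Numerically stable logistic transform used throughout the package for
#' risk outputs and gate activations.
#'
#' @param x Numeric vector or matrix.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  # stable in both tails
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Logit (inverse logistic)
#'
#' @param p Probabilities in (0, 1).
#' @return Log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

#' Stable softplus
#'
#' `log(1 + exp(x))` computed without overflow; used as the positivity
#' transform for decay rates and variational scale parameters.
#'
#' @param x Numeric vector or matrix.
#' @return Non-negative values, same shape as `x`.
#' @export
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Derive a component seed from a master seed
#'
#' All randomness in the package flows from one user-supplied integer seed;
#' independent components (cohort generation, weight initialisation,
#' dropout, bootstrap, posterior sampling) draw from seeds derived
#' deterministically from it so that fixing the master seed fixes every
#' stream. Derived seeds stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param offset Integer component offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) * 48271 + as.double(offset) * 8191 + 12345) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fail fast with the caller-facing message style used across the package
stop2 <- function(...) stop(..., call. = FALSE)

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}
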