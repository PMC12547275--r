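#' Numerically stable softmax
#'
#' Maps a vector of real-valued scores to a probability vector proportional
#' to the exponentiated scores. Used throughout the transfer sub-models:
#' the probability of each audience member receiving meat is
#' `softmax(slope * affinity + ...)`. The maximum score is subtracted
#' before exponentiation so arbitrarily large scores do not overflow.
#'
#' @param x Numeric vector of scores (finite, non-empty).
#' @param slope Optional scalar multiplier applied to `x` first
#'   (default 1). Supplying `softmax(a, slope = b)` is the common idiom
#'   for a choice model with slope `b` over predictor vector `a`.
#' @return Numeric vector of the same length as `x`, strictly positive,
#'   summing to 1.
#' @examples
#' softmax(c(-1, 1), slope = 0.28) # c(0.36, 0.64) to 2 d.p.
#' @export
softmax <- function(x, slope = 1) {
  if (length(x) == 0) stop("softmax: empty predictor vector", call. = FALSE)
  if (!all(is.finite(x))) stop("softmax: non-finite predictor values", call. = FALSE)
  z <- slope * x
  e <- exp(z - max(z))
  e / sum(e)
}

#' Zero-truncated Poisson distribution
#'
#' Density, distribution function and random generation for the Poisson
#' distribution conditioned on strictly positive outcomes, used to model
#' audience sizes (there is always at least one individual present).
#' The truncated pmf is `P(k | lambda) = lambda^k e^-lambda / (k! (1 - e^-lambda))`
#' for `k >= 1`; its mean is `lambda / (1 - e^-lambda)`.
#'
#' The normalising term `log(1 - exp(-lambda))` is computed through
#' `log(-expm1(-lambda))`, which stays accurate for very small rates.
#'
#' @param x,q Vector of counts (>= 1).
#' @param n Number of random values.
#' @param lambda Positive rate of the untruncated Poisson.
#' @param log,log.p Return log-probabilities.
#' @return `dztpois` the pmf, `ztpois_mean` the analytic mean,
#'   `rztpois` random draws (all >= 1).
#' @name ztpois
NULL

#' @rdname ztpois
#' @export
dztpois <- function(x, lambda, log = FALSE) {
  lp <- ifelse(x >= 1,
    stats::dpois(x, lambda, log = TRUE) - log(-expm1(-lambda)),
    -Inf
  )
  if (log) lp else exp(lp)
}

#' @rdname ztpois
#' @export
ztpois_mean <- function(lambda) lambda / (-expm1(-lambda))

#' @rdname ztpois
#' @export
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  # inverse-cdf on the conditional distribution: draw U in (P(0), 1] and
  # invert the untruncated Poisson cdf
  p0 <- exp(-lambda)
  u <- p0 + stats::runif(n) * (1 - p0)
  stats::qpois(u, lambda)
}

#' Summarize posterior draws as median and equal-tailed credible interval
#'
#' The headline summary convention throughout the package: posterior
#' median plus an equal-tailed quantile interval (default mass 0.89, i.e.
#' the 5.5% and 94.5% quantiles).
#'
#' @param draws Numeric vector of posterior draws.
#' @param interval_mass Probability mass of the interval, in (0, 1).
#' @return A tibble with columns `median`, `lower`, `upper`, `mass`, `n_draws`.
#' @export
summarize_posterior <- function(draws, interval_mass = 0.89) {
  stopifnot(length(draws) > 0, is.numeric(draws))
  if (!(interval_mass > 0 && interval_mass < 1)) {
    stop("interval_mass must be in (0, 1)", call. = FALSE)
  }
  qs <- stats::quantile(draws, c((1 - interval_mass) / 2, 1 - (1 - interval_mass) / 2),
    names = FALSE, na.rm = FALSE
  )
  tibble::tibble(
    median = stats::median(draws),
    lower = qs[1],
    upper = qs[2],
    mass = interval_mass,
    n_draws = length(draws)
  )
}

logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) stats::plogis(x)

#' Canonical unordered dyad key
#'
#' Joins two identifier vectors into order-independent dyad keys
#' (`"A|B"` with members sorted), the key convention used for affinities
#' throughout the package.
#'
#' @param a,b Identifier vectors.
#' @return Character vector of dyad keys.
#' @examples
#' dyad_key("b", "a") == dyad_key("a", "b")
#' @export
dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
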