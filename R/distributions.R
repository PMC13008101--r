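#' Specify an uncertainty distribution for a model parameter
#'
#' Distributions are parameterised by their mean and standard error, the two
#' quantities the model's evidence base reports, and converted to natural
#' parameters by the method of moments. Supported families:
#' \describe{
#'   \item{beta}{probabilities (test accuracy, transition probabilities,
#'     prevalences, utilities); requires mean in (0,1).}
#'   \item{gamma}{costs; requires mean > 0.}
#'   \item{lognormal_rr}{the relative risk reduction (RRR) of a treatment
#'     effect: the relative risk RR = 1 - RRR is sampled log-normally with
#'     moments matched to mean 1 - mean(RRR) and the given se, then mapped
#'     back and truncated to [0, 1). Keeps the progression multiplier 1 - RRR
#'     strictly positive.}
#'   \item{uniform_range}{parameters reported only as a plausible range
#'     (screening uptake rates); sampled uniformly on [low, high].}
#'   \item{fixed}{no uncertainty; every draw equals the mean.}
#' }
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal_rr"`,
#'   `"uniform_range"`, `"fixed"`.
#' @param mean Base-case value.
#' @param se Standard error (>= 0). Must be 0 for `"fixed"`.
#' @param low,high Range bounds, required for `"uniform_range"`.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("gamma", mean = 2000, se = 500)
dist_spec <- function(family, mean, se = 0, low = NULL, high = NULL) {
  family <- match.arg(family,
                      c("beta", "gamma", "lognormal_rr", "uniform_range", "fixed"))
  if (!is.finite(mean)) stop("dist_spec: mean must be finite", call. = FALSE)
  if (se < 0) stop("dist_spec: se must be >= 0", call. = FALSE)
  if (family == "beta" && (mean <= 0 || mean >= 1))
    stop("dist_spec: beta requires mean in (0,1), got ", mean, call. = FALSE)
  if (family == "gamma" && mean <= 0)
    stop("dist_spec: gamma requires mean > 0, got ", mean, call. = FALSE)
  if (family == "fixed" && se != 0)
    stop("dist_spec: fixed requires se = 0", call. = FALSE)
  if (family == "uniform_range") {
    if (is.null(low) || is.null(high) || low > high || mean < low || mean > high)
      stop("dist_spec: uniform_range requires low <= mean <= high", call. = FALSE)
  }
  structure(list(family = family, mean = mean, se = se,
                 low = low, high = high),
            class = "dist_spec")
}

#' Build a sampler from a distribution specification
#'
#' Method-of-moments parameterisation: beta uses
#' `alpha = m * (m(1-m)/s^2 - 1)`, `beta = (1-m) * (m(1-m)/s^2 - 1)`;
#' gamma uses `shape = m^2/s^2`, `scale = s^2/m`. A spec with `se = 0` (or
#' family `"fixed"`) yields a degenerate sampler returning the mean.
#'
#' @param spec A [dist_spec()].
#' @return A function `f(n)` returning `n` independent draws.
#' @export
#' @examples
#' s <- build_distribution(dist_spec("gamma", 2000, 500))
#' set.seed(1); mean(s(1e4))
build_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  m <- spec$mean; s <- spec$se
  if (spec$family == "fixed" || s == 0)
    return(function(n) rep(m, n))
  switch(spec$family,
    beta = {
      v <- s^2
      if (v >= m * (1 - m))
        stop("beta spec infeasible: se^2 >= mean(1-mean) for mean ", m,
             call. = FALSE)
      k <- m * (1 - m) / v - 1
      a <- m * k; b <- (1 - m) * k
      function(n) rbeta(n, a, b)
    },
    gamma = {
      shape <- m^2 / s^2
      scale <- s^2 / m
      function(n) rgamma(n, shape = shape, scale = scale)
    },
    lognormal_rr = {
      # sample RR = 1 - RRR on the log scale, moment-matched
      m_rr <- 1 - m
      if (m_rr <= 0) stop("lognormal_rr requires mean < 1", call. = FALSE)
      sigma2 <- log(1 + (s / m_rr)^2)
      mu <- log(m_rr) - sigma2 / 2
      function(n) {
        rrr <- 1 - rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
        pmin(pmax(rrr, 0), 1 - 1e-12)
      }
    },
    uniform_range = {
      lo <- spec$low; hi <- spec$high
      function(n) runif(n, lo, hi)
    })
}

#' Convert an event rate to an annual transition probability
#'
#' Uses the standard exponential-hazard relation `p = 1 - exp(-rate)` for a
#' one-year cycle.
#'
#' @param rate Events per person-year (>= 0); vectorised.
#' @return Annual probability in `[0, 1)`.
#' @export
#' @examples
#' rate_to_annual_probability(54.9 / 1000)
rate_to_annual_probability <- function(rate) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  1 - exp(-rate)
}

#' Convert an annual probability back to an event rate
#' @param p Annual probability in `[0, 1)`; vectorised.
#' @return Events per person-year.
#' @export
probability_to_rate <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must be in [0, 1)", call. = FALSE)
  -log(1 - p)
}

#' Convert Thai baht to US dollars at the model's fixed exchange rate
#'
#' @param amount Amount in THB; vectorised.
#' @param thb_per_usd Exchange rate, default 34.64 THB per USD (2023).
#' @return Amount in USD.
#' @export
#' @examples
#' thb_to_usd(160000)
thb_to_usd <- function(amount, thb_per_usd = 34.64) {
  amount / thb_per_usd
}
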