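# Fecundity likelihood from brood surveys, with a hierarchical year effect.

#' Log-likelihood of the fledgling counts
#'
#' The total number of fledglings in year t is Poisson around the number of
#' surveyed broods times the year-specific fecundity:
#' `J_t ~ Poisson(R_t * f_t)`.  Fecundity is parameterized per breeding
#' pair (the full brood); it is halved only where it enters the female
#' population model.
#'
#' @param productivity Data.frame with columns `year`, `n_broods` (R) and
#'   `n_fledglings` (J).  Years with `n_broods = 0` contribute nothing.
#' @param f Year-specific fecundity, a vector aligned with the rows of
#'   `productivity` or a scalar.
#' @return Scalar log-likelihood; `-Inf` if fledglings were recorded in a
#'   year with zero expected production.
#' @export
fecundity_loglik <- function(productivity, f) {
  f <- rep_len(f, nrow(productivity))
  sum(dpois(productivity$n_fledglings, productivity$n_broods * f,
            log = TRUE))
}

#' Hierarchical prior on year-specific fecundity
#'
#' Annual fecundities are exchangeable draws from a common log-normal
#' process: `log f_t ~ Normal(mu, sigma2)`, with `mu` the mean
#' log-fecundity and `sigma2` its temporal variance.
#'
#' @param f Vector of year-specific fecundities (positive).
#' @param mu Mean of log-fecundity.
#' @param sigma2 Temporal variance of log-fecundity (strictly positive).
#' @return Scalar log-density of `log(f)` under the Normal(mu, sigma2) law.
#' @export
fecundity_hyperprior <- function(f, mu, sigma2) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (any(f <= 0)) stop("fecundities must be positive")
  sum(dnorm(log(f), mu, sqrt(sigma2), log = TRUE))
}
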