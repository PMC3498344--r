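# State-space model for counts of breeding pairs.
#
# The female population is tracked in three age classes: N1 (1-year-olds),
# N2 (2-year-olds) and N3 (older than 2 years).  Its stochastic dynamics
# mirror a pre-breeding Leslie projection: recruitment is Poisson with mean
# phi * (f/2) * B_t (fecundity halved because only females are modelled),
# survival to the next class is binomial, and the observed count of
# breeding pairs is Poisson around the expected number of breeding females.

#' Expected number of breeding females
#'
#' `B_t = beta2 * N2 + gamma * N3`: a fixed fraction `beta2` (about 10% in
#' this population) of 2-year-old females breed, and a latent fraction
#' `gamma` of the older females.
#'
#' @param trajectory A data.frame with columns `N2` and `N3` (one row per
#'   year), or a single-row population state.
#' @param gamma Breeding proportion of females older than 2 years, in
#'   \[0.5, 1\].
#' @param beta2 Breeding propensity of 2-year-olds (default 0.1).
#' @return Numeric vector of expected breeding females, one per row.
#' @export
breeders <- function(trajectory, gamma, beta2 = 0.1) {
  beta2 * trajectory$N2 + gamma * trajectory$N3
}

#' Log-density of the latent population trajectory
#'
#' Sums, over successive years, the Poisson log-density of recruitment and
#' the binomial log-densities of survival:
#' `N1[t+1] ~ Poisson(phi * (f_t / 2) * B_t)`,
#' `N2[t+1] ~ Binomial(N1[t], phi)`,
#' `N3[t+1] ~ Binomial(N2[t] + N3[t], phi)`.
#'
#' @param trajectory Data.frame with columns `year`, `N1`, `N2`, `N3`
#'   (non-negative integers, one row per year in order).
#' @param phi Annual survival probability.
#' @param gamma Breeding proportion of 3+ females.
#' @param f Fecundity per breeding pair, a vector with one value per year
#'   (the value for the final year is unused) or a scalar.
#' @param beta2 Breeding propensity of 2-year-olds.
#' @return Scalar log-density; `-Inf` if a binomial count exceeds its
#'   number of trials.
#' @export
state_loglik <- function(trajectory, phi, gamma, f, beta2 = 0.1) {
  n <- nrow(trajectory)
  if (n < 2) return(0)
  f <- rep_len(f, n)
  B <- breeders(trajectory, gamma, beta2)
  i <- seq_len(n - 1)
  N1 <- trajectory$N1; N2 <- trajectory$N2; N3 <- trajectory$N3
  sum(dpois(N1[i + 1], phi * (f[i] / 2) * B[i], log = TRUE)) +
    sum(dbinom(N2[i + 1], N1[i], phi, log = TRUE)) +
    sum(dbinom(N3[i + 1], N2[i] + N3[i], phi, log = TRUE))
}

#' Log-likelihood of the breeding-pair counts
#'
#' Observed annual counts of breeding pairs (identified with breeding
#' females under monogamy) are Poisson around the expected number of
#' breeding females, `y_t ~ Poisson(B_t)`.
#'
#' @param counts Data.frame with columns `year` and `breeding_pairs`.
#' @param trajectory Latent trajectory as in [state_loglik()]; must contain
#'   every year in `counts`.
#' @inheritParams state_loglik
#' @return Scalar log-likelihood.
#' @export
count_loglik <- function(counts, trajectory, gamma, beta2 = 0.1) {
  i <- match(counts$year, trajectory$year)
  if (anyNA(i)) stop("count years missing from the trajectory")
  B <- breeders(trajectory[i, , drop = FALSE], gamma, beta2)
  sum(dpois(counts$breeding_pairs, B, log = TRUE))
}
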