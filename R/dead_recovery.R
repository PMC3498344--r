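# Likelihood for unmarked birds recovered dead, by cause.
#
# Each year the population of size Ntot splits multinomially into birds
# dying of poison, dying of other causes, and surviving, using the average
# (across age classes) cause-specific death probabilities.  The recovered
# counts are binomial thinnings of the latent deaths with the same
# cause-specific reporting rates as the multistate model - the linkage that
# sharpens those reporting rates in the integrated model.

#' Average proportion of deaths due to poisoning
#'
#' Arithmetic mean of the three age-specific proportions.
#'
#' @param m_juv,m_1y,m_2my Age-specific probabilities that a death was
#'   caused by poison.
#' @return Scalar mean proportion.
#' @export
mean_poison_fraction <- function(m_juv, m_1y, m_2my) {
  (m_juv + m_1y + m_2my) / 3
}

#' Multinomial cell probabilities for annual fates
#'
#' The probability vector (die of poison, die of other causes, survive)
#' for an average bird: `((1 - phi) * mbar, (1 - phi) * (1 - mbar), phi)`.
#'
#' @param phi Annual survival probability.
#' @param mbar Average proportion of deaths due to poisoning, from
#'   [mean_poison_fraction()].
#' @return Named numeric vector of length 3 summing to 1.
#' @export
death_cell_probs <- function(phi, mbar) {
  c(poison = (1 - phi) * mbar,
    other = (1 - phi) * (1 - mbar),
    survive = phi)
}

#' Log-likelihood of dead-recovery counts (augmented form)
#'
#' Per year: the multinomial log-density of the latent deaths
#' `(xP, xO, Ntot - xP - xO)` given `Ntot` and [death_cell_probs()], plus
#' binomial reporting `RP ~ Binomial(xP, rP)` and `RO ~ Binomial(xO, rO)`.
#' The latent deaths are data-augmentation variables sampled by the MCMC
#' engine; marginally `(RP, RO)` is a thinned multinomial.
#'
#' @param recoveries Data.frame with columns `year`, `n_dead_poison` (RP)
#'   and `n_dead_other` (RO).
#' @param latent Data.frame with columns `year`, `xP`, `xO`: latent yearly
#'   numbers of unmarked birds dying by poison / other causes.
#' @param Ntot Total population size per year, aligned with the rows of
#'   `latent`.
#' @param params Named vector or list with `phi`, `m_juv`, `m_1y`, `m_2my`,
#'   `rP`, `rO`.
#' @return Scalar log-likelihood; `-Inf` when a recovered count exceeds its
#'   latent deaths or the latent deaths exceed the population.
#' @export
recovery_loglik <- function(recoveries, latent, Ntot, params) {
  params <- as.list(params)
  i <- match(recoveries$year, latent$year)
  if (anyNA(i)) stop("recovery years missing from the latent series")
  xP <- latent$xP[i]; xO <- latent$xO[i]; N <- Ntot[i]
  RP <- recoveries$n_dead_poison; RO <- recoveries$n_dead_other
  if (any(xP < 0 | xO < 0 | xP + xO > N)) return(-Inf)
  if (any(RP > xP | RO > xO)) return(-Inf)
  mbar <- mean_poison_fraction(params$m_juv, params$m_1y, params$m_2my)
  pr <- death_cell_probs(params$phi, mbar)
  xS <- N - xP - xO
  # multinomial log-pmf with the 0 * log(0) = 0 convention
  xlogp <- function(x, p) ifelse(x == 0, 0, x * log(p))
  lmult <- lgamma(N + 1) - lgamma(xP + 1) - lgamma(xO + 1) - lgamma(xS + 1) +
    xlogp(xP, pr[[1]]) + xlogp(xO, pr[[2]]) + xlogp(xS, pr[[3]])
  sum(lmult) +
    sum(dbinom(RP, xP, params$rP, log = TRUE)) +
    sum(dbinom(RO, xO, params$rO, log = TRUE))
}
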