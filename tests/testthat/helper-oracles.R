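# Shared fixtures and independent oracles for the test suite.

# reference posterior-mean parameter set used throughout the tests
ref_params <- function() {
  ms_params(phi = 0.808, m_juv = 0.428, m_1y = 0.764, m_2my = 0.764,
            rho1 = 0.862, rho2 = 0.333, rho3 = 0.045,
            p = 0.990, pA = 0.328, rP = 0.461, rO = 0.075)
}

ref_vital_rates <- function() {
  vital_rates_from_estimates(0.808, c(0.428, 0.764, 0.764),
                             f = 1.825, gamma = 0.631)
}

# brute-force likelihood of one post-release event sequence by exhaustive
# enumeration over all latent paths (independent of the forward algorithm)
enum_ch_loglik <- function(events_post, params) {
  TT <- transition_matrix(params)
  OO <- observation_matrix(params)
  L <- length(events_post)
  paths <- as.matrix(expand.grid(rep(list(1:16), L)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- 1
    prev <- 1L                          # release state: alive, radio, juv
    for (t in seq_len(L)) {
      s <- paths[r, t]
      pr <- pr * TT[prev, s] * OO[s, events_post[t]]
      if (pr == 0) break
      prev <- s
    }
    tot <- tot + pr
  }
  log(tot)
}

# build a one-bird histories data.frame from a post-release event vector
one_history <- function(events_post, release_year = 2000) {
  yrs <- release_year + 0:length(events_post)
  h <- data.frame(id = "b1", sex = "F", release_year = release_year)
  h[paste0("y", yrs)] <- as.list(c(1L, as.integer(events_post)))
  h
}

# closed-form marginal of the recovery counts: thinning a multinomial
# gives (RP, RO) ~ Multinomial(N, (pP rP, pO rO, rest))
marginal_recovery_logpmf <- function(RP, RO, Ntot, phi, mbar, rP, rO) {
  pr <- death_cell_probs(phi, mbar)
  pP <- pr[[1]] * rP
  pO <- pr[[2]] * rO
  dmultinom(c(RP, RO, Ntot - RP - RO), prob = c(pP, pO, 1 - pP - pO),
            log = TRUE)
}
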