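# Synthetic-data generator: the generative mirror of every likelihood.
#
# Defaults emulate a 12-year survey of a small insular red kite population:
# roughly 8 breeding pairs at the start growing past 18, eleven annual
# cohorts of ~13 birds radio-tagged at fledging (~143 in total, half of
# them males that contribute only to the multistate stream), tag batteries
# failing after 3-4 years, and sparse recoveries of unmarked dead birds.

#' Scenario configuration for the generator
#'
#' The default parameter values are the reference posterior means for this
#' population under the full integrated model: they define the study
#' conditions every pipeline test runs under.
#'
#' @param phi Annual survival.
#' @param m Length-3 vector of poison fractions (juv, 1y, 2+).
#' @param rho Length-3 vector of annual radio-retention probabilities.
#' @param p,pA Encounter probabilities with / without a functioning radio.
#' @param rP,rO Reporting probabilities of unradioed birds dead by poison /
#'   other causes.
#' @param gamma Breeding proportion of 3+ females.
#' @param mu Mean log-fecundity (default `log(1.825)`).
#' @param sigma2 Temporal variance of log-fecundity.
#' @param beta2 Breeding propensity of 2-year-olds.
#' @param n_years Number of survey years.
#' @param start_year First survey year.
#' @param tagged_per_year Birds radio-tagged per cohort; cohorts span years
#'   2 to `n_years` (tagging began one year after the surveys).
#' @param initial_N Length-3 vector of initial female numbers (1y, 2y, 3+);
#'   the default gives about 8 expected breeding pairs in year 1.
#' @param scale Integer multiplier applied to `tagged_per_year` and
#'   `initial_N` for power studies; rates are untouched.
#' @param prop_male Proportion of tagged birds that are male.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(phi = 0.808,
                            m = c(juv = 0.428, `1y` = 0.764, `2my` = 0.764),
                            rho = c(0.862, 0.333, 0.045),
                            p = 0.990, pA = 0.328, rP = 0.461, rO = 0.075,
                            gamma = 0.631, mu = log(1.825), sigma2 = 0.110,
                            beta2 = 0.1,
                            n_years = 12L, start_year = 1999L,
                            tagged_per_year = 13L,
                            initial_N = c(5L, 4L, 12L),
                            scale = 1L, prop_male = 0.5) {
  cfg <- list(phi = phi, m = setNames(as.numeric(m), c("juv", "1y", "2my")),
              rho = as.numeric(rho), p = p, pA = pA, rP = rP, rO = rO,
              gamma = gamma, mu = mu, sigma2 = sigma2, beta2 = beta2,
              n_years = as.integer(n_years),
              start_year = as.integer(start_year),
              tagged_per_year = as.integer(tagged_per_year),
              initial_N = as.integer(initial_N),
              scale = as.integer(scale), prop_male = prop_male)
  stopifnot(all(unlist(cfg[c("phi", "p", "pA", "rP", "rO", "gamma",
                             "beta2", "prop_male")]) >= 0),
            all(unlist(cfg[c("phi", "p", "pA", "rP", "rO", "gamma",
                             "beta2", "prop_male")]) <= 1),
            all(cfg$m >= 0 & cfg$m <= 1), all(cfg$rho >= 0 & cfg$rho <= 1),
            cfg$sigma2 >= 0, cfg$n_years >= 2, cfg$scale >= 1)
  class(cfg) <- "scenario_config"
  cfg
}

#' Scale a scenario up
#'
#' Multiplies cohort sizes and the initial population by `factor`, leaving
#' all rates untouched.  Used for power / parameter-recovery studies.
#'
#' @param config A [scenario_config()].
#' @param factor Integer factor >= 1.
#' @return The scaled configuration.
#' @export
scale_scenario <- function(config, factor) {
  stopifnot(inherits(config, "scenario_config"), factor >= 1)
  config$scale <- as.integer(config$scale * factor)
  config
}

# The ms_params implied by a scenario.
.scenario_ms_params <- function(cfg) {
  ms_params(cfg$phi, cfg$m[["juv"]], cfg$m[["1y"]], cfg$m[["2my"]],
            cfg$rho[1], cfg$rho[2], cfg$rho[3],
            cfg$p, cfg$pA, cfg$rP, cfg$rO)
}

# Walk n birds released at occasion `rel` through the 16-state chain and
# observation process, vectorized by grouping birds in the same state.
.simulate_histories <- function(n, rel, n_years, TT, OO) {
  states <- rep(1L, n)
  events <- matrix(0L, n, n_years)
  events[, rel] <- 1L
  if (rel < n_years) {
    for (t in (rel + 1L):n_years) {
      new_states <- states
      for (s in unique(states)) {
        i <- which(states == s)
        new_states[i] <- sample.int(16L, length(i), replace = TRUE,
                                    prob = TT[s, ])
      }
      states <- new_states
      for (s in unique(states)) {
        i <- which(states == s)
        events[i, t] <- sample.int(16L, length(i), replace = TRUE,
                                   prob = OO[s, ])
      }
    }
  }
  events
}

#' Generate a complete synthetic dataset bundle
#'
#' Simulates, from known parameters, the four data streams consumed by the
#' integrated model: the latent three-age-class female trajectory and
#' Poisson counts of breeding pairs; brood surveys with log-normal yearly
#' fecundity; radio-tagged cohorts walked through the 16-state chain and
#' observed through the event matrix; and multinomial unmarked deaths
#' thinned binomially into recoveries.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (mandatory: every bundle is reproducible).
#' @return A list with elements `bundle` (a [kite_bundle()]) and `truth`
#'   (parameter values and realized latent trajectories, serialized
#'   alongside every generated bundle).  If the population goes extinct
#'   before the end, the bundle is flagged via `truth$extinct` rather than
#'   discarded.
#' @export
generate_bundle <- function(config = scenario_config(), seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  cfg <- config
  Tn <- cfg$n_years
  years <- cfg$start_year + seq_len(Tn) - 1L
  k <- cfg$scale

  # yearly fecundity
  f <- exp(rnorm(Tn, cfg$mu, sqrt(cfg$sigma2)))

  # latent female trajectory
  N <- matrix(0L, Tn, 3, dimnames = list(years, c("N1", "N2", "N3")))
  N[1, ] <- cfg$initial_N * k
  for (t in seq_len(Tn - 1)) {
    B_t <- cfg$beta2 * N[t, 2] + cfg$gamma * N[t, 3]
    N[t + 1, 1] <- rpois(1, cfg$phi * (f[t] / 2) * B_t)
    N[t + 1, 2] <- rbinom(1, N[t, 1], cfg$phi)
    N[t + 1, 3] <- rbinom(1, N[t, 2] + N[t, 3], cfg$phi)
  }
  trajectory <- data.frame(year = years, N1 = N[, 1], N2 = N[, 2],
                           N3 = N[, 3])
  B <- breeders(trajectory, cfg$gamma, cfg$beta2)
  extinct <- any(rowSums(N) == 0)

  counts <- data.frame(year = years, breeding_pairs = rpois(Tn, B))

  # brood surveys: all active nests are monitored
  R <- counts$breeding_pairs
  productivity <- data.frame(year = years, n_broods = R,
                             n_fledglings = rpois(Tn, R * f))

  # unmarked dead recoveries
  pr <- death_cell_probs(cfg$phi, mean_poison_fraction(
    cfg$m[["juv"]], cfg$m[["1y"]], cfg$m[["2my"]]))
  Ntot <- rowSums(N)
  x <- t(vapply(Ntot, function(nn) {
    as.integer(rmultinom(1, nn, pr)[1:2])
  }, integer(2)))
  recoveries <- data.frame(year = years,
                           n_dead_poison = rbinom(Tn, x[, 1], cfg$rP),
                           n_dead_other = rbinom(Tn, x[, 2], cfg$rO))

  # radio-tagged cohorts, years 2..Tn
  pm <- .scenario_ms_params(cfg)
  TT <- transition_matrix(pm)
  OO <- observation_matrix(pm)
  n_per <- cfg$tagged_per_year * k
  hist_list <- lapply(2:Tn, function(rel) {
    ev <- .simulate_histories(n_per, rel, Tn, TT, OO)
    data.frame(id = sprintf("%d_%03d", years[rel], seq_len(n_per)),
               sex = sample(c("F", "M"), n_per, replace = TRUE,
                            prob = c(1 - cfg$prop_male, cfg$prop_male)),
               release_year = years[rel], ev,
               stringsAsFactors = FALSE)
  })
  histories <- do.call(rbind, hist_list)
  names(histories)[-(1:3)] <- paste0("y", years)

  bundle <- kite_bundle(counts, productivity, recoveries, histories)
  truth <- list(config = unclass(cfg), seed = seed, f = f,
                trajectory = trajectory, latent_deaths = data.frame(
                  year = years, xP = x[, 1], xO = x[, 2]),
                extinct = extinct)
  list(bundle = bundle, truth = truth)
}
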