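# Small-scale checks of the joint posterior and the MCMC engine.  Fits
# here are deliberately tiny; full-scale recovery is exercised in the
# acceptance suite.

truth_params <- function(g) {
  cfg <- g$truth$config
  list(ms = ms_params(cfg$phi, cfg$m[["juv"]], cfg$m[["1y"]],
                      cfg$m[["2my"]], cfg$rho[1], cfg$rho[2], cfg$rho[3],
                      cfg$p, cfg$pA, cfg$rP, cfg$rO),
       gamma = cfg$gamma, f = g$truth$f, mu = cfg$mu,
       sigma2 = cfg$sigma2, trajectory = g$truth$trajectory,
       latent_deaths = g$truth$latent_deaths)
}

test_that("the joint posterior decomposes exactly over its components", {
  g <- generate_bundle(scenario_config(), seed = 13)
  pars <- truth_params(g)
  lj_ms <- log_joint(pars, g$bundle, "MS")
  lj_1 <- log_joint(pars, g$bundle, "IPM1")
  lj_2 <- log_joint(pars, g$bundle, "IPM2")
  expect_true(is.finite(lj_2))          # finite at the generating truth
  comp2 <- attr(lj_2, "components")
  # MS is exactly the capture-recapture term (flat priors contribute 0)
  expect_equal(as.numeric(lj_ms), comp2[["ch"]])
  # adding the recovery stream adds exactly its component
  expect_equal(as.numeric(lj_2 - lj_1), comp2[["recovery"]])
  expect_equal(as.numeric(lj_2), sum(comp2))
})

test_that("out-of-support latent states void the posterior", {
  g <- generate_bundle(scenario_config(), seed = 13)
  pars <- truth_params(g)
  pars$latent_deaths$xP[2] <- -1
  expect_identical(as.numeric(log_joint(pars, g$bundle, "IPM2")), -Inf)
  pars2 <- truth_params(g)
  pars2$trajectory$N2[3] <- pars2$trajectory$N1[2] + 5  # binomial support
  expect_identical(as.numeric(log_joint(pars2, g$bundle, "IPM1")), -Inf)
})

test_that("chains are bit-reproducible under a fixed seed", {
  g <- generate_bundle(scenario_config(n_years = 8, tagged_per_year = 8),
                       seed = 3)
  f1 <- run_mcmc(g$bundle, "MS", chains = 2, iter = 300, burnin = 100,
                 thin = 2, seed = 17)
  f2 <- run_mcmc(g$bundle, "MS", chains = 2, iter = 300, burnin = 100,
                 thin = 2, seed = 17)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(g$bundle, "MS", chains = 1, iter = 300, burnin = 100,
                 thin = 2, seed = 18)
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("the convergence diagnostic behaves on constructed chains", {
  set.seed(6)
  base <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  same <- list(base, base)
  r_same <- gelman_rubin(same)
  expect_equal(as.numeric(r_same), c(1, 1), tolerance = 5e-3,
               ignore_attr = TRUE)
  shifted <- list(base, base + 5)       # disjoint chains must be flagged
  r_shift <- gelman_rubin(shifted, threshold = 1.1)
  expect_true(all(r_shift > 1.1))
  expect_equal(sort(attr(r_shift, "flagged")), c("a", "b"))
  expect_error(gelman_rubin(list(base)), "at least 2 chains")
  # agreement with a from-scratch textbook computation
  chains <- list(matrix(rnorm(500, 0, 1), ncol = 1,
                        dimnames = list(NULL, "x")),
                 matrix(rnorm(500, 0.3, 1.2), ncol = 1,
                        dimnames = list(NULL, "x")))
  n <- 500
  W <- mean(c(var(chains[[1]][, 1]), var(chains[[2]][, 1])))
  B_n <- var(c(mean(chains[[1]][, 1]), mean(chains[[2]][, 1])))
  expect_equal(unname(gelman_rubin(chains)["x"]),
               sqrt(((n - 1) / n * W + B_n) / W), tolerance = 1e-12)
})

test_that("derived quantities satisfy their defining identities", {
  g <- generate_bundle(scenario_config(n_years = 8, tagged_per_year = 8),
                       seed = 23)
  fit <- run_mcmc(g$bundle, "IPM2", chains = 2, iter = 400, burnin = 150,
                  thin = 2, seed = 29)
  d <- pooled_draws(fit)
  der <- derived_quantities(fit)
  for (a in c("juv", "1y", "2my")) {
    ps <- der$draws[, paste0("phi_star_", a)]
    dd <- der$draws[, paste0("delta_", a)]
    expect_equal(ps, d[, "phi"] + (1 - d[, "phi"]) * d[, paste0("m_", a)],
                 tolerance = 1e-12)
    expect_equal(ps * (1 - dd), unname(d[, "phi"]), tolerance = 1e-12)
  }
  # m = 0 would leave survival untouched
  expect_equal(poison_free_survival(0.808, 0), 0.808)
  # yearly growth rates are ratios of successive totals
  yrs <- fit$years
  Ntot1 <- rowSums(d[, paste0(c("N1_", "N2_", "N3_"), yrs[1])])
  Ntot2 <- rowSums(d[, paste0(c("N1_", "N2_", "N3_"), yrs[2])])
  expect_equal(der$draws[, paste0("lambda_", yrs[1])], Ntot2 / Ntot1,
               tolerance = 1e-12)
})

test_that("projection propagates uncertainty forward", {
  g <- generate_bundle(scenario_config(n_years = 8, tagged_per_year = 8),
                       seed = 41)
  fit <- run_mcmc(g$bundle, "IPM1", chains = 2, iter = 400, burnin = 150,
                  thin = 2, seed = 43)
  pr <- project(fit, horizon = 3, seed = 1)
  expect_equal(pr$year, max(fit$years) + 0:3)
  width <- pr$upper - pr$lower
  expect_true(all(diff(width) >= 0))    # intervals widen with horizon
  # horizon 0 is the filtered final state
  pr0 <- project(fit, horizon = 0)
  d <- pooled_draws(fit)
  Nfin <- rowSums(d[, paste0(c("N1_", "N2_", "N3_"), max(fit$years))])
  expect_equal(pr0$median, median(Nfin))
  expect_error(project(fit, horizon = -1), "horizon")
  fms <- run_mcmc(g$bundle, "MS", chains = 1, iter = 200, burnin = 100,
                  thin = 2, seed = 2)
  expect_error(project(fms), "population-based")
})

test_that("projection means track the deterministic matrix projection", {
  # with parameters fixed (degenerate draws), the projected mean follows
  # A^h N within Monte-Carlo error
  cfg <- scenario_config()
  v <- vital_rates_from_estimates(cfg$phi, cfg$m, exp(cfg$mu), cfg$gamma)
  A <- leslie_matrix(v)
  N0 <- c(60, 50, 150)
  set.seed(3)
  ndraw <- 4000
  N <- matrix(rep(N0, each = ndraw), ndraw, 3)
  for (h in 1:3) {
    B <- 0.1 * N[, 2] + cfg$gamma * N[, 3]
    f_new <- exp(rnorm(ndraw, cfg$mu, sqrt(cfg$sigma2)))
    N <- cbind(rpois(ndraw, cfg$phi * (f_new / 2) * B),
               rbinom(ndraw, N[, 1], cfg$phi),
               rbinom(ndraw, N[, 2] + N[, 3], cfg$phi))
  }
  expected <- as.vector(A %*% A %*% A %*% N0)
  # log-normal year effects lift the mean slightly above exp(mu)
  expect_equal(colMeans(N), expected, tolerance = 0.12)
})
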