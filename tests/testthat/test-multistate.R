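test_that("transition matrix cells match their closed forms", {
  pm <- ref_params()
  TT <- transition_matrix(pm)
  # death by poison, radio retained, juvenile interval
  expect_equal(TT["juv.t", "DP.t"], (1 - 0.808) * 0.428 * 0.862,
               tolerance = 1e-12)
  # survival with radio to the next age class
  expect_equal(TT["juv.t", "1y.t"], 0.808 * 0.862, tolerance = 1e-12)
  expect_equal(TT["3y.t", "4y.t"], 0.808 * 0.333, tolerance = 1e-12)
  # no-radio birds stay radio-less
  expect_equal(TT["1y.nt", "2y.nt"], 0.808, tolerance = 1e-12)
  expect_equal(TT["1y.nt", "DP.nt"], (1 - 0.808) * 0.764,
               tolerance = 1e-12)
  # recently dead states collapse to unobserved dead; UD is absorbing
  expect_equal(unname(TT[c("DP.t", "DO.t", "DP.nt", "DO.nt"), "UD"]),
               rep(1, 4))
  expect_equal(TT["UD", "UD"], 1)
})

test_that("rows of both matrices are stochastic for random parameters", {
  set.seed(42)
  for (i in 1:200) {
    pm <- do.call(ms_params, as.list(runif(11)))
    expect_equal(rowSums(transition_matrix(pm)), setNames(rep(1, 16),
                 latent_states()$label), tolerance = 1e-12)
    expect_equal(unname(rowSums(observation_matrix(pm))), rep(1, 16),
                 tolerance = 1e-12)
  }
})

test_that("certain retention or detection degenerate as expected", {
  pl <- as.list(unclass(ref_params()))
  pl[c("rho1", "rho2", "rho3")] <- 1
  TT <- transition_matrix(do.call(ms_params, pl))
  noradio_cols <- c(paste0(age_classes()[-1], ".nt"), "DP.nt", "DO.nt")
  alive_rows <- paste0(age_classes(), ".t")
  expect_equal(sum(TT[alive_rows, noradio_cols]), 0)
  pl2 <- as.list(unclass(ref_params()))
  pl2$p <- 1
  OO <- observation_matrix(do.call(ms_params, pl2))
  expect_equal(unname(diag(OO[1:6, 1:6])), rep(1, 6))
})

test_that("observation matrix encodes the reporting process", {
  pm <- ref_params()
  OO <- observation_matrix(pm)
  expect_equal(OO["DP.nt", "dead.poison.nt"], 0.461)
  expect_equal(OO["DP.nt", "not.seen"], 1 - 0.461)
  expect_equal(OO["DP.t", "dead.poison.t"], 1)
  expect_equal(OO["UD", "not.seen"], 1)
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(7)
  seqs <- list(16L, 7L, c(2L, 16L), c(16L, 16L), c(2L, 3L, 16L),
               c(16L, 10L, 16L), c(2L, 3L, 8L), c(2L, 16L, 16L, 16L),
               c(2L, 3L, 4L, 14L))
  for (i in 1:6) {
    pm <- do.call(ms_params, as.list(runif(11, 0.05, 0.95)))
    for (ev in seqs) {
      expect_equal(ch_loglik(one_history(ev), pm),
                   enum_ch_loglik(ev, pm), tolerance = 1e-10)
    }
  }
})

test_that("single-path histories have closed-form likelihoods", {
  pm <- ref_params()
  # found dead by poison with radio one year after release
  expect_equal(ch_loglik(one_history(7L), pm),
               log((1 - 0.808) * 0.428 * 0.862), tolerance = 1e-12)
  # seen alive with radio one year after release
  expect_equal(ch_loglik(one_history(2L), pm),
               log(0.808 * 0.862 * 0.990), tolerance = 1e-12)
})

test_that("likelihood is additive over individuals and order-invariant", {
  set.seed(11)
  g <- generate_bundle(scenario_config(n_years = 6, tagged_per_year = 8),
                       seed = 5)
  h <- g$bundle$histories
  pm <- ref_params()
  ll_all <- ch_loglik(h, pm)
  ll_parts <- sum(vapply(seq_len(nrow(h)),
                         function(i) ch_loglik(h[i, ], pm), numeric(1)))
  expect_equal(ll_all, ll_parts, tolerance = 1e-9)
  expect_equal(ch_loglik(h[sample(nrow(h)), ], pm), ll_all,
               tolerance = 1e-9)
})

test_that("equal poison fractions collapse to a plain dead-recovery model", {
  pm <- ms_params(0.75, 0.4, 0.4, 0.4, 0.8, 0.5, 0.2, 0.9, 0.3, 0.5, 0.1)
  TT <- transition_matrix(pm)
  dead_cols <- c("DP.t", "DO.t", "DP.nt", "DO.nt")
  for (row in paste0(age_classes(), ".t"))
    expect_equal(sum(TT[row, dead_cols]), 1 - 0.75, tolerance = 1e-12)
  # and the poison share of dead mass equals m in every age class
  for (row in paste0(age_classes(), ".t"))
    expect_equal(sum(TT[row, c("DP.t", "DP.nt")]) /
                   sum(TT[row, dead_cols]), 0.4, tolerance = 1e-12)
})

test_that("impossible events give -Inf with a usable diagnostic", {
  pl <- as.list(unclass(ref_params()))
  # certain retention and detection make 'not seen' impossible while the
  # bird is alive, and certain survival removes the dead states
  pl[c("rho1", "rho2", "rho3", "p", "phi")] <- 1
  pm <- do.call(ms_params, pl)
  expect_warning(ll <- ch_loglik(one_history(16L), pm),
                 "impossible event for individual b1")
  expect_identical(ll, -Inf)
})

test_that("simulated event frequencies match the matrix-product marginal", {
  pm <- ref_params()
  TT <- transition_matrix(pm)
  OO <- observation_matrix(pm)
  n <- 30000
  set.seed(99)
  ev <- kiteIPM:::.simulate_histories(n, 1L, 3L, TT, OO)
  # marginal distribution of the event two occasions after release:
  # delta_release T T O
  pev <- as.vector((diag(16)[1, , drop = FALSE] %*% TT %*% TT) %*% OO)
  emp <- tabulate(ev[, 3], 16) / n
  mc_se <- sqrt(pmax(pev * (1 - pev), 1e-12) / n)
  expect_true(all(abs(emp - pev) <= 3.5 * mc_se + 1e-12))
})
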