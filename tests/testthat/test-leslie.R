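test_that("poison-free survival and proportional reduction are inverses", {
  expect_equal(poison_free_survival(0.808, 0.428), 0.890, tolerance = 5e-4)
  expect_equal(poison_free_survival(0.808, 0.764), 0.955, tolerance = 5e-4)
  expect_equal(poison_free_survival(0.808, 1), 1)
  expect_equal(proportional_reduction(0.808, 0.955), 0.154,
               tolerance = 5e-4)
  expect_equal(proportional_reduction(0.808, 0.890), 0.092,
               tolerance = 2e-3)
  expect_equal(proportional_reduction(0.5, 0.5), 0)
  set.seed(2)
  for (i in 1:100) {
    phi <- runif(1); m <- runif(1)
    ps <- poison_free_survival(phi, m)
    d <- proportional_reduction(phi, ps)
    # algebraic identities: phi* (1 - Delta) = phi and the closed form of
    # Delta in terms of (phi, m)
    expect_equal(ps * (1 - d), phi, tolerance = 1e-12)
    expect_equal(d, m * (1 - phi) / (phi + (1 - phi) * m),
                 tolerance = 1e-12)
  }
  expect_error(poison_free_survival(1.2, 0.5), "probabilities")
})

test_that("the projection matrix has the pre-breeding structure", {
  v <- ref_vital_rates()
  A <- leslie_matrix(v)
  expect_equal(A[1, 3], 0.631 * (1.825 / 2) * 0.808, tolerance = 1e-9)
  expect_equal(A[1, 2], 0.1 * (1.825 / 2) * 0.808, tolerance = 1e-9)
  expect_equal(A[2, 1], 0.808, tolerance = 1e-9)
  expect_equal(A[3, 2], 0.808, tolerance = 1e-9)
  expect_equal(A[3, 3], 0.808, tolerance = 1e-9)
  expect_equal(A[1, 1], 0)
  # zero fecundity empties the fertility row; zero reductions restore the
  # poison-free survivals
  v0 <- vital_rates(v$phi_star, v$delta, f = 0, gamma = v$gamma)
  expect_equal(unname(leslie_matrix(v0)[1, ]), rep(0, 3))
  vp <- vital_rates(v$phi_star, rep(0, 3), f = v$f, gamma = v$gamma)
  expect_equal(leslie_matrix(vp)[2, 1], v$phi_star[["1y"]])
})

test_that("the dominant eigenvalue matches its characteristic polynomial", {
  v <- ref_vital_rates()
  A <- leslie_matrix(v)
  g <- growth_rate(A)
  lam <- g$lambda
  # lambda^2 (s2 - lambda) - a12 s1 (s2 - lambda) + a13 s1 s2 = 0 with
  # s1 = a21, s2 = a33 (survival entries), a12/a13 the fertility cells
  s1 <- A[2, 1]; s2 <- A[3, 3]
  expect_equal(lam^2 * (s2 - lam) - A[1, 2] * s1 * (s2 - lam) +
                 A[1, 3] * s1 * s2, 0, tolerance = 1e-10)
  expect_equal(sum(g$stable_age), 1)
  expect_equal(sum(g$reproductive_value * g$stable_age), 1)
  # a fecundity-free matrix declines at the adult survival rate
  v0 <- vital_rates(v$phi_star, v$delta, f = 0, gamma = v$gamma)
  expect_equal(growth_rate(leslie_matrix(v0))$lambda,
               v$phi_star[["2my"]] * (1 - v$delta[["2my"]]),
               tolerance = 1e-9)
})

test_that("matrix sensitivities match central finite differences", {
  v <- ref_vital_rates()
  A <- leslie_matrix(v)
  S <- matrix_sensitivity(A)
  h <- 1e-6
  for (i in 1:3) for (j in 1:3) {
    Ap <- A; Am <- A
    Ap[i, j] <- A[i, j] + h
    Am[i, j] <- A[i, j] - h
    fd <- (growth_rate(Ap)$lambda - growth_rate(Am)$lambda) / (2 * h)
    expect_equal(S[i, j], fd, tolerance = 1e-6)
  }
  expect_true(all(S > 0))               # primitive matrix
})

test_that("matrix-element elasticities sum to one", {
  v <- ref_vital_rates()
  expect_equal(sum(matrix_elasticity(v)), 1, tolerance = 1e-10)
  set.seed(4)
  for (i in 1:20) {
    vr <- vital_rates(runif(3, 0.5, 1), runif(3, 0, 0.4),
                      f = runif(1, 0.5, 2.5), gamma = runif(1, 0.5, 1))
    expect_equal(sum(matrix_elasticity(vr)), 1, tolerance = 1e-10)
  }
})

test_that("vital-rate perturbations match finite differences via chain rule", {
  v <- ref_vital_rates()
  tab <- vital_rate_perturbation(v)
  lam0 <- growth_rate(v)$lambda
  h <- 1e-6
  fd_sens <- function(pn) {
    nudge <- function(delta) {
      ps <- v$phi_star; dd <- v$delta; f <- v$f; g <- v$gamma
      switch(pn,
        phi_star_juv = ps[["juv"]] <- ps[["juv"]] + delta,
        phi_star_1y = ps[["1y"]] <- ps[["1y"]] + delta,
        phi_star_2my = ps[["2my"]] <- ps[["2my"]] + delta,
        delta_juv = dd[["juv"]] <- dd[["juv"]] + delta,
        delta_1y = dd[["1y"]] <- dd[["1y"]] + delta,
        delta_2my = dd[["2my"]] <- dd[["2my"]] + delta,
        f = f <- f + delta,
        gamma = g <- g + delta)
      growth_rate(vital_rates(ps, dd, f, g, v$beta2))$lambda
    }
    (nudge(h) - nudge(-h)) / (2 * h)
  }
  for (pn in vital_rate_names()) {
    row <- tab[tab$parameter == pn, ]
    fd <- fd_sens(pn)
    expect_equal(row$sensitivity, abs(fd), tolerance = 1e-6)
    expect_equal(row$elasticity,
                 abs(kiteIPM:::.vr_value(v, pn) / lam0 * fd),
                 tolerance = 1e-6)
  }
  # the fecundity elasticity equals the elasticity of the composite
  # fertility coefficient (f scales both fertility cells)
  E <- matrix_elasticity(v)
  expect_equal(tab$elasticity[tab$parameter == "f"], E[1, 2] + E[1, 3],
               tolerance = 1e-9)
})

test_that("growth is most sensitive to the adult class", {
  tab <- vital_rate_perturbation(ref_vital_rates())
  # the two largest sensitivities both belong to the 2+ class (its
  # poison-free survival and its poisoning reduction, which differ only
  # by the factor phi*/(1 - Delta)), and among the poison-free survivals
  # the adult one dominates
  top2 <- tab$parameter[order(tab$sensitivity, decreasing = TRUE)][1:2]
  expect_setequal(top2, c("phi_star_2my", "delta_2my"))
  surv <- tab[grep("^phi_star", tab$parameter), ]
  expect_equal(surv$parameter[which.max(surv$sensitivity)],
               "phi_star_2my")
})

test_that("break-even reductions cross lambda = 1 and poison never helps", {
  v <- ref_vital_rates()
  for (a in c("juv", "1y", "2my")) {
    d_star <- breakeven_reduction(v, a)
    dd <- v$delta
    dd[[a]] <- d_star
    expect_equal(growth_rate(vital_rates(v$phi_star, dd, v$f,
                                         v$gamma))$lambda, 1,
                 tolerance = 1e-7)
  }
  # lambda at current reductions is below the poison-free lambda
  v0 <- vital_rates(v$phi_star, rep(0, 3), v$f, v$gamma)
  expect_lt(growth_rate(v)$lambda, growth_rate(v0)$lambda)
  # a population already declining at zero poisoning never crosses 1
  vdown <- vital_rates(rep(0.8, 3), rep(0, 3), f = 0.5, gamma = 0.6)
  expect_message(b <- breakeven_reduction(vdown, "1y"), "does not cross")
  expect_true(is.na(b))
})

test_that("lambda surfaces are monotone and consistent with break-evens", {
  v <- ref_vital_rates()
  surf <- lambda_surfaces(v, delta_grid = seq(0, 1, by = 0.05),
                          f_grid = c(1, 1.825, 2.2))
  for (a in unique(surf$curves$age)) {
    lam <- surf$curves$lambda[surf$curves$age == a]
    expect_true(all(diff(lam) <= 1e-12))
  }
  # the lambda = 1 contour at the baseline fecundity passes through the
  # break-even reduction
  for (a in c("juv", "1y", "2my")) {
    d_star <- breakeven_reduction(v, a)
    cur <- surf$curves[surf$curves$age == a, ]
    below <- max(cur$delta[cur$lambda >= 1])
    expect_lt(abs(below - d_star), 0.05 + 1e-9)
  }
  # even the maximum recorded fecundity cannot compensate survival at
  # 55% of its poison-free level
  d55 <- 1 - 0.55
  v55 <- vital_rates(v$phi_star, rep(d55, 3), f = 2.2, gamma = v$gamma)
  expect_lt(growth_rate(v55)$lambda, 1)
  expect_error(lambda_surfaces(v, delta_grid = numeric(0)), "empty grid")
})
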