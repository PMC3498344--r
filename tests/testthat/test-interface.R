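test_that("bundles round-trip through CSV byte-identically", {
  g <- generate_bundle(scenario_config(n_years = 6, tagged_per_year = 5),
                       seed = 55)
  dir <- withr::local_tempdir()
  write_bundle(g$bundle, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$counts, g$bundle$counts)
  expect_equal(b2$productivity, g$bundle$productivity)
  expect_equal(b2$recoveries, g$bundle$recoveries)
  expect_equal(b2$histories, g$bundle$histories)
  # and writing again reproduces the same files
  dir2 <- withr::local_tempdir()
  write_bundle(b2, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("validation rejects malformed inputs with located messages", {
  g <- generate_bundle(scenario_config(n_years = 6, tagged_per_year = 5),
                       seed = 55)
  b <- g$bundle
  h <- b$histories
  h[3, "y2002"] <- 17L
  expect_error(kite_bundle(b$counts, b$productivity, b$recoveries, h),
               "invalid event code.*row 3")
  h2 <- b$histories
  h2[2, paste0("y", h2$release_year[2])] <- 2L
  expect_error(kite_bundle(b$counts, b$productivity, b$recoveries, h2),
               "release-year event must be 1")
  counts_bad <- b$counts
  counts_bad$breeding_pairs[4] <- -2
  expect_error(kite_bundle(counts_bad, b$productivity, b$recoveries,
                           b$histories), "non-negative integer")
  prod_bad <- b$productivity
  prod_bad$n_broods[1] <- 0
  prod_bad$n_fledglings[1] <- 3
  expect_error(kite_bundle(b$counts, prod_bad, b$recoveries, b$histories),
               "zero broods")
})

test_that("a missing recoveries file is tolerated for non-recovery fits", {
  g <- generate_bundle(scenario_config(n_years = 6, tagged_per_year = 5),
                       seed = 56)
  dir <- withr::local_tempdir()
  write_bundle(g$bundle, dir)
  file.remove(file.path(dir, "recoveries.csv"))
  b <- read_bundle(dir)
  expect_null(b$recoveries)
  fit <- run_mcmc(b, "IPM1", chains = 1, iter = 150, burnin = 50,
                  thin = 2, seed = 1)
  expect_s3_class(fit, "kite_fit")
  expect_error(run_mcmc(b, "IPM2", chains = 1, iter = 150, burnin = 50,
                        thin = 2, seed = 1), "requires the recoveries")
})

test_that("the pipeline produces the full report from a config list", {
  dir <- withr::local_tempdir()
  rep <- run_pipeline(list(
    scenario = list(n_years = 8, tagged_per_year = 8),
    variant = "IPM2", chains = 2, iter = 500, burnin = 200, thin = 3,
    seed = 12, horizon = 2, out_dir = dir))
  expect_s3_class(rep, "kite_report")
  # 11 estimated rows plus gamma, sigma2, three poison-free survivals,
  # mean fecundity and mean growth
  expect_equal(nrow(rep$summary), 18)
  expect_setequal(
    rep$summary$parameter,
    c("phi", "m_juv", "m_1y", "m_2my", "rho1", "rho2", "rho3", "p", "pA",
      "rP", "rO", "gamma", "sigma2", "phi_star_juv", "phi_star_1y",
      "phi_star_2my", "f_mean", "lambda_geo"))
  expect_equal(nrow(rep$projection), 3)
  expect_named(rep$perturbation$breakeven, c("juv", "1y", "2my"))
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "run.json")))
  echo <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(echo$config$seed, 12)
})

test_that("an MS-only report omits the population-level quantities", {
  g <- generate_bundle(scenario_config(n_years = 6, tagged_per_year = 6),
                       seed = 58)
  dir <- withr::local_tempdir()
  write_bundle(g$bundle, dir)
  rep <- run_pipeline(list(data_dir = dir, variant = "MS", chains = 2,
                           iter = 300, burnin = 100, thin = 2, seed = 5))
  expect_equal(nrow(rep$summary), 11)
  expect_false(any(grepl("gamma|lambda", rep$summary$parameter)))
  expect_null(rep$projection)
  expect_null(rep$perturbation)
})
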