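# Joint posterior and MCMC engine for the integrated population model.
#
# The joint likelihood is the product of the four component likelihoods
# (radio-tracking, counts, productivity, dead recoveries), which share the
# survival, cause-of-death and reporting parameters.  Three nested model
# variants are supported: MS (radio-tracking only), IPM1 (adds counts and
# productivity) and IPM2 (adds the dead-recovery stream).  Sampling is by
# adaptive random-walk Metropolis-within-Gibbs: the continuous parameters
# move on transformed scales in small blocks, the latent integer population
# states and latent death counts by integer random-walk proposals.

#' Default prior specification
#'
#' All probability parameters get Uniform(0, 1) priors.  The latent
#' breeding proportion `gamma` gets, by default, Uniform(0.5, 1); two
#' truncated-normal alternatives are available for sensitivity checks.
#' The fecundity hyper-parameters get `mu ~ Normal(0, sd 10)` and
#' `sigma ~ Uniform(0, sigma_max)`.  Initial population sizes get
#' independent Poisson(`N1_mean`) priors truncated at `N_max`.
#'
#' @param gamma_prior One of `"uniform"`, `"tnorm_wide"` (Normal(0.75,
#'   var 1000) truncated to \[0.5, 1\]) or `"tnorm_tight"` (Normal(0.5,
#'   var 0.25) truncated to \[0.5, 1\]).
#' @param mu_mean,mu_sd Normal prior on mean log-fecundity.
#' @param sigma_max Upper bound of the uniform prior on the temporal sd of
#'   log-fecundity.
#' @param initN_prior Prior family for the initial age-class counts:
#'   `"poisson"` (independent Poisson(`N1_mean`) truncated at `N_max`) or
#'   `"uniform"` (discrete uniform on 0..`N_max`).  The Poisson default
#'   suits a population of the surveyed size; a Poisson prior is fairly
#'   informative (sd equals the square root of its mean), so for larger
#'   populations, or whenever the initial sizes are genuinely unknown,
#'   the uniform family is the neutral choice.
#' @param N1_mean,N_max Poisson mean and truncation bound of the initial
#'   population priors.
#' @return A list of prior settings.
#' @export
default_priors <- function(gamma_prior = c("uniform", "tnorm_wide",
                                           "tnorm_tight"),
                           mu_mean = 0, mu_sd = 10, sigma_max = 10,
                           initN_prior = c("poisson", "uniform"),
                           N1_mean = 10, N_max = 100) {
  list(gamma_prior = match.arg(gamma_prior), mu_mean = mu_mean,
       mu_sd = mu_sd, sigma_max = sigma_max,
       initN_prior = match.arg(initN_prior), N1_mean = N1_mean,
       N_max = N_max)
}

.log_prior_gamma <- function(g, priors) {
  if (g < 0.5 || g > 1) return(-Inf)
  switch(priors$gamma_prior,
    uniform = log(2),
    tnorm_wide = dnorm(g, 0.75, sqrt(1000), log = TRUE) -
      log(pnorm(1, 0.75, sqrt(1000)) - pnorm(0.5, 0.75, sqrt(1000))),
    tnorm_tight = dnorm(g, 0.5, sqrt(0.25), log = TRUE) -
      log(pnorm(1, 0.5, sqrt(0.25)) - pnorm(0.5, 0.5, sqrt(0.25))))
}

.log_prior_initN <- function(N1row, priors) {
  if (any(N1row > priors$N_max)) return(-Inf)
  if (identical(priors$initN_prior, "uniform"))
    return(-3 * log(priors$N_max + 1))
  sum(dpois(N1row, priors$N1_mean, log = TRUE))
}

#' Joint log-posterior density of the integrated model
#'
#' Sum of the component log-likelihoods selected by the variant, plus the
#' log-priors.  The components are independent given the shared
#' parameters, so the joint factorizes exactly; the returned value carries
#' the per-component breakdown as attribute `"components"`.
#'
#' @param params A list with elements `ms` (an [ms_params()] vector),
#'   `gamma`, `f` (year-specific fecundities aligned with the trajectory),
#'   `mu`, `sigma2`, `trajectory` (data.frame `year`, `N1`, `N2`, `N3`)
#'   and `latent_deaths` (data.frame `year`, `xP`, `xO`).  `MS` only needs
#'   `ms`.
#' @param bundle A [kite_bundle()].
#' @param variant `"MS"`, `"IPM1"` or `"IPM2"`.
#' @param priors From [default_priors()].
#' @param beta2 Breeding propensity of 2-year-olds.
#' @param recovery_popscale Multiplier converting the female trajectory
#'   total into the population exposed to recovery (default 1: recovered
#'   unmarked birds are attributed to the female-based total).
#' @return Scalar log-posterior (up to a constant), with attribute
#'   `"components"`.
#' @export
log_joint <- function(params, bundle, variant = c("IPM2", "IPM1", "MS"),
                      priors = default_priors(), beta2 = 0.1,
                      recovery_popscale = 1) {
  variant <- match.arg(toupper(variant[1]), c("IPM2", "IPM1", "MS"))
  ms <- .as_ms_params(params$ms)
  comp <- c(ch = ch_loglik(bundle$histories, ms), prior = 0)
  if (variant != "MS") {
    traj <- params$trajectory
    if (!setequal(intersect(bundle$counts$year, traj$year),
                  bundle$counts$year))
      stop("count years not covered by the trajectory")
    ip <- match(bundle$productivity$year, traj$year)
    if (anyNA(ip)) stop("productivity years not covered by the trajectory")
    comp["state"] <- state_loglik(traj, ms[["phi"]], params$gamma,
                                  params$f, beta2)
    comp["count"] <- count_loglik(bundle$counts, traj, params$gamma, beta2)
    comp["productivity"] <- fecundity_loglik(bundle$productivity,
                                             params$f[ip])
    comp["hyper"] <- fecundity_hyperprior(params$f, params$mu,
                                          params$sigma2)
    sigma <- sqrt(params$sigma2)
    comp["prior"] <- .log_prior_gamma(params$gamma, priors) +
      dnorm(params$mu, priors$mu_mean, priors$mu_sd, log = TRUE) +
      dunif(sigma, 0, priors$sigma_max, log = TRUE) +
      .log_prior_initN(unlist(traj[1, c("N1", "N2", "N3")]), priors)
  }
  if (variant == "IPM2") {
    Ntot <- round(recovery_popscale *
                    (traj$N1 + traj$N2 + traj$N3))
    comp["recovery"] <- recovery_loglik(bundle$recoveries,
                                        params$latent_deaths, Ntot, ms)
  }
  structure(sum(comp), components = comp)
}

# ---------------------------------------------------------------------------
# MCMC internals

.MS_NAMES <- c("phi", "m_juv", "m_1y", "m_2my", "rho1", "rho2", "rho3",
               "p", "pA", "rP", "rO")

# aligned data pre-computation shared by all chains
.prep_data <- function(bundle, variant) {
  years <- seq(min(bundle$years), max(bundle$years))
  Tn <- length(years)
  hm <- .history_matrix(bundle$histories)
  al <- function(d, col) {
    v <- rep(NA_real_, Tn)
    v[match(d$year, years)] <- d[[col]]
    v
  }
  pre <- list(years = years, Tn = Tn,
              comp = .compress_histories(hm),
              y = al(bundle$counts, "breeding_pairs"),
              R = al(bundle$productivity, "n_broods"),
              J = al(bundle$productivity, "n_fledglings"))
  if (variant == "IPM2") {
    if (is.null(bundle$recoveries))
      stop("variant IPM2 requires the recoveries stream")
    pre$RP <- al(bundle$recoveries, "n_dead_poison")
    pre$RO <- al(bundle$recoveries, "n_dead_other")
  }
  pre
}

.ch_from_z <- function(z, pre) {
  th <- plogis(z)
  .ch_loglik_compressed(pre$comp,
                        .tmat_fast(th[1], th[2:4], th[5:7]),
                        .omat_fast(th[8], th[9], th[10], th[11]))
}

# logit-scale Jacobian of a flat prior on a probability
.ljac <- function(z) sum(z - 2 * log1p(exp(z)))

# MAP of the multistate sub-model on the logit scale: starting point and
# proposal covariance for the samplers.
.ms_map <- function(pre) {
  z0 <- qlogis(c(0.85, 0.5, 0.5, 0.5, 0.8, 0.3, 0.1, 0.9, 0.3, 0.3, 0.1))
  obj <- function(z) {
    ll <- suppressWarnings(.ch_from_z(z, pre))
    if (!is.finite(ll)) return(1e10)
    -(ll + .ljac(z))
  }
  opt <- optim(z0, obj, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-7))
  V <- tryCatch({
    H <- optimHess(opt$par, obj)
    V <- solve(H)
    if (!all(is.finite(V)) || any(diag(V) <= 0)) stop("bad hessian")
    V
  }, error = function(e) diag(0.05, 11))
  list(z = opt$par, V = V)
}

.popscale <- function(pre) if (is.null(pre$popscale)) 1 else pre$popscale

# vectorized augmented recovery log density (one element per year)
.rec_vec_logdens <- function(xP, xO, Ntot, pr, rP, rO, RP, RO) {
  xS <- Ntot - xP - xO
  bad <- xP < 0 | xO < 0 | xS < 0 | RP > xP | RO > xO
  xPc <- pmax(xP, 0L); xOc <- pmax(xO, 0L); xSc <- pmax(xS, 0L)
  # cell probabilities are strictly interior along the sampling path
  out <- lgamma(Ntot + 1) - lgamma(xPc + 1) - lgamma(xOc + 1) -
    lgamma(xSc + 1) + xPc * log(pr[[1]]) + xOc * log(pr[[2]]) +
    xSc * log(pr[[3]]) +
    dbinom(pmin(RP, xPc), xPc, rP, log = TRUE) +
    dbinom(pmin(RO, xOc), xOc, rO, log = TRUE)
  out[bad] <- -Inf
  out
}

# local state/count/recovery log density for a set of non-adjacent years
# (their local terms are then disjoint in the proposed coordinates)
.batch_N_logdens <- function(ts, N, f, phi, gamma, beta2, pre, priors,
                             use_rec, pr, x, rP, rO) {
  Tn <- pre$Tn
  B <- beta2 * N[, 2] + gamma * N[, 3]
  lp <- numeric(length(ts))
  in1 <- ts > 1
  tp <- ts[in1]
  if (length(tp))
    lp[in1] <- dpois(N[tp, 1], phi * (f[tp - 1] / 2) * B[tp - 1],
                     log = TRUE) +
      dbinom(N[tp, 2], N[tp - 1, 1], phi, log = TRUE) +
      dbinom(N[tp, 3], N[tp - 1, 2] + N[tp - 1, 3], phi, log = TRUE)
  if (any(!in1)) lp[!in1] <- .log_prior_initN(N[1, ], priors)
  inT <- ts < Tn
  tn <- ts[inT]
  if (length(tn))
    lp[inT] <- lp[inT] +
      dpois(N[tn + 1, 1], phi * (f[tn] / 2) * B[tn], log = TRUE) +
      dbinom(N[tn + 1, 2], N[tn, 1], phi, log = TRUE) +
      dbinom(N[tn + 1, 3], N[tn, 2] + N[tn, 3], phi, log = TRUE)
  oky <- !is.na(pre$y[ts])
  lp[oky] <- lp[oky] + dpois(pre$y[ts][oky], B[ts][oky], log = TRUE)
  if (use_rec) {
    okr <- !is.na(pre$RP[ts])
    tr <- ts[okr]
    if (length(tr)) {
      Ntot <- round(.popscale(pre) * (N[tr, 1] + N[tr, 2] + N[tr, 3]))
      lp[okr] <- lp[okr] +
        .rec_vec_logdens(x[tr, 1], x[tr, 2], Ntot, pr, rP, rO,
                         pre$RP[tr], pre$RO[tr])
    }
  }
  lp
}

# one year's augmented recovery log density
.rec_year_logdens <- function(xP, xO, Ntot, pr, rP, rO, RP, RO) {
  xS <- Ntot - xP - xO
  if (xP < 0 || xO < 0 || xS < 0 || RP > xP || RO > xO) return(-Inf)
  xlogp <- function(x, p) if (x == 0) 0 else x * log(p)
  lgamma(Ntot + 1) - lgamma(xP + 1) - lgamma(xO + 1) - lgamma(xS + 1) +
    xlogp(xP, pr[[1]]) + xlogp(xO, pr[[2]]) + xlogp(xS, pr[[3]]) +
    dbinom(RP, xP, rP, log = TRUE) + dbinom(RO, xO, rO, log = TRUE)
}

# total of the state + count terms (used by the phi and gamma blocks);
# matrix arithmetic mirror of state_loglik/count_loglik, kept free of
# data.frame construction for speed in the sampler's inner loop
.state_count_logdens <- function(N, f, phi, gamma, beta2, pre, priors) {
  Tn <- pre$Tn
  B <- beta2 * N[, 2] + gamma * N[, 3]
  i <- seq_len(Tn - 1)
  ok <- !is.na(pre$y)
  sum(dpois(N[i + 1, 1], phi * (f[i] / 2) * B[i], log = TRUE)) +
    sum(dbinom(N[i + 1, 2], N[i, 1], phi, log = TRUE)) +
    sum(dbinom(N[i + 1, 3], N[i, 2] + N[i, 3], phi, log = TRUE)) +
    sum(dpois(pre$y[ok], B[ok], log = TRUE)) +
    .log_prior_initN(N[1, ], priors)
}

.rec_total_logdens <- function(x, N, th, pre) {
  pr <- death_cell_probs(th[["phi"]],
                         mean_poison_fraction(th[["m_juv"]], th[["m_1y"]],
                                              th[["m_2my"]]))
  tr <- which(!is.na(pre$RP))
  Ntot <- round(.popscale(pre) * (N[tr, 1] + N[tr, 2] + N[tr, 3]))
  sum(.rec_vec_logdens(x[tr, 1], x[tr, 2], Ntot, pr, th[["rP"]],
                       th[["rO"]], pre$RP[tr], pre$RO[tr]))
}

# initial values: data-driven so that short chains start near the posterior
.init_state <- function(pre, variant, map, priors, jitter = 0) {
  z <- map$z + jitter * rnorm(11)
  st <- list(z = z)
  if (variant == "MS") return(st)
  Tn <- pre$Tn
  st$gamma <- 0.72
  y_fill <- pre$y
  if (anyNA(y_fill)) y_fill[is.na(y_fill)] <- round(mean(pre$y, na.rm = TRUE))
  N3 <- pmax(1L, round(y_fill / st$gamma))
  N2 <- pmax(1L, round(0.2 * N3))
  N1 <- pmax(1L, round(0.3 * N3))
  # repair binomial support (N2[t+1] <= N1[t], N3[t+1] <= N2[t] + N3[t]);
  # raising one count can break an earlier constraint, so iterate to a
  # fixed point (counts only grow, so this terminates)
  repeat {
    changed <- FALSE
    for (t in seq_len(Tn - 1)) {
      if (N3[t + 1] > N2[t] + N3[t]) {
        N2[t] <- N3[t + 1] - N3[t]; changed <- TRUE
      }
      if (N2[t + 1] > N1[t]) {
        N1[t] <- N2[t + 1]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  st$N <- cbind(N1, N2, N3)
  lf <- ifelse(!is.na(pre$R) & pre$R > 0, log(pmax(0.25, pre$J / pre$R)),
               log(1.5))
  st$lf <- lf + jitter * rnorm(Tn, 0, 0.05)
  st$mu <- mean(st$lf)
  st$lsig <- log(0.3)
  if (variant == "IPM2") {
    xP <- ifelse(is.na(pre$RP), 0, pre$RP)
    xO <- ifelse(is.na(pre$RO), 0, pre$RO)
    st$x <- cbind(pmax(xP, 1L), pmax(xO, 1L))
  }
  st
}

# single chain of adaptive Metropolis-within-Gibbs
.mcmc_chain <- function(pre, variant, priors, beta2, map, n_iter, burnin,
                        thin, jitter = 0.15) {
  Tn <- pre$Tn
  st <- .init_state(pre, variant, map, priors, jitter)
  b1 <- 1:4                         # phi and the poison fractions
  b2 <- 5:11                        # retention, detection, reporting
  L1 <- t(chol(map$V[b1, b1] + diag(1e-8, 4)))
  L2 <- t(chol(map$V[b2, b2] + diag(1e-8, 7)))
  ls1 <- ls2 <- 0; ls_g <- log(0.15); ls_f <- log(0.25); ls_s <- log(0.5)
  # fixed half-width of the adult-level shift in the joint gamma move
  K3 <- max(1L, round(0.05 * mean(pre$y, na.rm = TRUE) / 0.65))
  acc <- c(b1 = 0, b2 = 0, g = 0, f = 0, s = 0, N = 0, x = 0)
  att <- acc

  th <- setNames(plogis(st$z), .MS_NAMES)
  ll_ch <- suppressWarnings(.ch_from_z(st$z, pre))

  use_pop <- variant != "MS"
  use_rec <- variant == "IPM2"
  sc_cur <- if (use_pop)
    .state_count_logdens(st$N, exp(st$lf), th[["phi"]], st$gamma, beta2,
                         pre, priors) else 0
  rec_cur <- if (use_rec) .rec_total_logdens(st$x, st$N, th, pre) else 0
  if (!is.finite(sc_cur) || !is.finite(rec_cur) || !is.finite(ll_ch))
    stop("non-finite log-posterior at the initial state (ch = ", ll_ch,
         ", state/count = ", sc_cur, ", recovery = ", rec_cur, ")")

  keep <- seq(burnin + thin, n_iter, by = thin)
  par_names <- .MS_NAMES
  if (use_pop)
    par_names <- c(par_names, "gamma", "mu", "sigma2",
                   paste0("f_", pre$years),
                   paste0("N1_", pre$years), paste0("N2_", pre$years),
                   paste0("N3_", pre$years))
  if (use_rec)
    par_names <- c(par_names, paste0("xP_", pre$years),
                   paste0("xO_", pre$years))
  draws <- matrix(NA_real_, length(keep), length(par_names),
                  dimnames = list(NULL, par_names))
  k_out <- 0L

  for (i in seq_len(n_iter)) {
    ## block 1: survival + poison fractions (touches all components)
    zp <- st$z
    zp[b1] <- zp[b1] + exp(ls1) * as.vector(L1 %*% rnorm(4))
    thp <- setNames(plogis(zp), .MS_NAMES)
    llp <- suppressWarnings(.ch_from_z(zp, pre))
    scp <- if (use_pop)
      .state_count_logdens(st$N, exp(st$lf), thp[["phi"]], st$gamma,
                           beta2, pre, priors) else 0
    recp <- if (use_rec) .rec_total_logdens(st$x, st$N, thp, pre) else 0
    lr <- (llp + scp + recp + .ljac(zp[b1])) -
      (ll_ch + sc_cur + rec_cur + .ljac(st$z[b1]))
    att["b1"] <- att["b1"] + 1
    if (is.finite(lr) && log(runif(1)) < lr) {
      st$z <- zp; th <- thp; ll_ch <- llp; sc_cur <- scp; rec_cur <- recp
      acc["b1"] <- acc["b1"] + 1
    }

    ## block 2: retention / detection / reporting
    zp <- st$z
    zp[b2] <- zp[b2] + exp(ls2) * as.vector(L2 %*% rnorm(7))
    thp <- setNames(plogis(zp), .MS_NAMES)
    llp <- suppressWarnings(.ch_from_z(zp, pre))
    recp <- if (use_rec) .rec_total_logdens(st$x, st$N, thp, pre) else 0
    lr <- (llp + recp + .ljac(zp[b2])) -
      (ll_ch + rec_cur + .ljac(st$z[b2]))
    att["b2"] <- att["b2"] + 1
    if (is.finite(lr) && log(runif(1)) < lr) {
      st$z <- zp; th <- thp; ll_ch <- llp; rec_cur <- recp
      acc["b2"] <- acc["b2"] + 1
    }

    if (use_pop) {
      f_cur <- exp(st$lf)

      ## gamma (logit scale on (0.5, 1))
      zg <- qlogis((st$gamma - 0.5) / 0.5)
      zgp <- zg + exp(ls_g) * rnorm(1)
      gp <- 0.5 + 0.5 * plogis(zgp)
      scp <- .state_count_logdens(st$N, f_cur, th[["phi"]], gp, beta2,
                                  pre, priors)
      lr <- (scp + .log_prior_gamma(gp, priors) + .ljac(zgp)) -
        (sc_cur + .log_prior_gamma(st$gamma, priors) + .ljac(zg))
      att["g"] <- att["g"] + 1
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$gamma <- gp; sc_cur <- scp; acc["g"] <- acc["g"] + 1
      }

      ## joint (gamma, adult-class level) move: the posterior couples
      ## gamma with the whole N3 trajectory through B_t = beta2 N2 +
      ## gamma N3, creating a ridge that single-site updates traverse
      ## slowly.  Draw an integer level shift k for N3, then propose
      ## gamma around the value that keeps gamma * mean(N3) unchanged,
      ## with the Hastings correction for the shifted proposal centre.
      ## Repeated a few times per sweep: it is cheap and it is the only
      ## move that travels along the ridge.
      for (rep_g in 1:3) {
      k <- sample(seq(-K3, K3), 1)
      Np <- st$N
      Np[, 3] <- Np[, 3] + k
      if (k != 0L && all(Np[, 3] >= 0L)) {
        S3 <- mean(st$N[, 3])
        zg <- qlogis((st$gamma - 0.5) / 0.5)
        g_c <- min(0.999, max(0.501, st$gamma * S3 / (S3 + k)))
        tau <- 0.05
        zgp <- qlogis((g_c - 0.5) / 0.5) + tau * rnorm(1)
        gp <- 0.5 + 0.5 * plogis(zgp)
        # reverse-move centre: from (gp, N3 + k) back with shift -k
        g_cr <- min(0.999, max(0.501, gp * (S3 + k) / S3))
        lq_fwd <- dnorm(zgp, qlogis((g_c - 0.5) / 0.5), tau, log = TRUE)
        lq_rev <- dnorm(zg, qlogis((g_cr - 0.5) / 0.5), tau, log = TRUE)
        scp <- .state_count_logdens(Np, f_cur, th[["phi"]], gp, beta2,
                                    pre, priors)
        recp <- if (use_rec) .rec_total_logdens(st$x, Np, th, pre)
                else rec_cur
        lr <- (scp + recp + .log_prior_gamma(gp, priors) + .ljac(zgp)) -
          (sc_cur + rec_cur + .log_prior_gamma(st$gamma, priors) +
             .ljac(zg)) + lq_rev - lq_fwd
        if (is.finite(lr) && log(runif(1)) < lr) {
          st$gamma <- gp; st$N <- Np; sc_cur <- scp; rec_cur <- recp
        }
      }
      }

      ## year-specific log-fecundities (independent one-year updates)
      sig <- exp(st$lsig)
      B <- beta2 * st$N[, 2] + st$gamma * st$N[, 3]
      lf_p <- st$lf + exp(ls_f) * rnorm(Tn)
      lp_one <- function(lf_t, t) {
        lp <- dnorm(lf_t, st$mu, sig, log = TRUE)
        if (t < Tn)
          lp <- lp + dpois(st$N[t + 1, 1],
                           th[["phi"]] * (exp(lf_t) / 2) * B[t], log = TRUE)
        if (!is.na(pre$R[t]) && pre$R[t] > 0)
          lp <- lp + dpois(pre$J[t], pre$R[t] * exp(lf_t), log = TRUE)
        lp
      }
      for (t in seq_len(Tn)) {
        att["f"] <- att["f"] + 1
        lr <- lp_one(lf_p[t], t) - lp_one(st$lf[t], t)
        if (is.finite(lr) && log(runif(1)) < lr) {
          st$lf[t] <- lf_p[t]; acc["f"] <- acc["f"] + 1
        }
      }
      f_cur <- exp(st$lf)
      sc_cur <- .state_count_logdens(st$N, f_cur, th[["phi"]], st$gamma,
                                     beta2, pre, priors)

      ## mu: conjugate normal draw
      prec <- Tn / sig^2 + 1 / priors$mu_sd^2
      mn <- (sum(st$lf) / sig^2 + priors$mu_mean / priors$mu_sd^2) / prec
      st$mu <- rnorm(1, mn, sqrt(1 / prec))

      ## log sigma: random walk (uniform prior on sigma + Jacobian)
      lsp <- st$lsig + exp(ls_s) * rnorm(1)
      att["s"] <- att["s"] + 1
      if (exp(lsp) < priors$sigma_max) {
        lr <- (sum(dnorm(st$lf, st$mu, exp(lsp), log = TRUE)) + lsp) -
          (sum(dnorm(st$lf, st$mu, exp(st$lsig), log = TRUE)) + st$lsig)
        if (is.finite(lr) && log(runif(1)) < lr) {
          st$lsig <- lsp; acc["s"] <- acc["s"] + 1
        }
      }

      ## latent population states: joint 3-class integer proposals,
      ## alternating over odd/even years so local terms are disjoint
      pr_cells <- if (use_rec)
        death_cell_probs(th[["phi"]],
                         mean_poison_fraction(th[["m_juv"]], th[["m_1y"]],
                                              th[["m_2my"]])) else NULL
      rPrO <- c(th[["rP"]], th[["rO"]])
      for (parity in 0:1) {
        ts <- which(seq_len(Tn) %% 2L == parity)
        nb <- length(ts)
        eps <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), 3L * nb,
                             replace = TRUE), nb, 3)
        big <- runif(nb) < 0.2           # occasional larger level moves
        eps[big, ] <- eps[big, , drop = FALSE] * 4L
        live <- rowSums(eps != 0L) > 0L
        Np <- st$N
        Np[ts, ] <- Np[ts, ] + eps
        neg <- rowSums(Np[ts, , drop = FALSE] < 0L) > 0L
        Np[ts[neg], ] <- st$N[ts[neg], ]
        lp_cur <- .batch_N_logdens(ts, st$N, f_cur, th[["phi"]], st$gamma,
                                   beta2, pre, priors, use_rec, pr_cells,
                                   st$x, rPrO[1], rPrO[2])
        lp_prop <- .batch_N_logdens(ts, Np, f_cur, th[["phi"]], st$gamma,
                                    beta2, pre, priors, use_rec, pr_cells,
                                    st$x, rPrO[1], rPrO[2])
        lp_prop[neg] <- -Inf
        ok <- live & is.finite(lp_prop) &
          log(runif(nb)) < lp_prop - lp_cur
        st$N[ts[ok], ] <- Np[ts[ok], , drop = FALSE]
        att["N"] <- att["N"] + sum(live)
        acc["N"] <- acc["N"] + sum(ok)
      }
      sc_cur <- .state_count_logdens(st$N, f_cur, th[["phi"]], st$gamma,
                                     beta2, pre, priors)
      if (use_rec) rec_cur <- .rec_total_logdens(st$x, st$N, th, pre)

      ## latent death counts (years independent given the rest)
      if (use_rec) {
        tr <- which(!is.na(pre$RP))
        nb <- length(tr)
        eps <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), 2L * nb,
                             replace = TRUE), nb, 2)
        live <- rowSums(eps != 0L) > 0L
        xp <- st$x[tr, , drop = FALSE] + eps
        Ntot <- round(.popscale(pre) *
                        (st$N[tr, 1] + st$N[tr, 2] + st$N[tr, 3]))
        lp_cur <- .rec_vec_logdens(st$x[tr, 1], st$x[tr, 2], Ntot,
                                   pr_cells, rPrO[1], rPrO[2],
                                   pre$RP[tr], pre$RO[tr])
        lp_prop <- .rec_vec_logdens(xp[, 1], xp[, 2], Ntot, pr_cells,
                                    rPrO[1], rPrO[2], pre$RP[tr],
                                    pre$RO[tr])
        ok <- live & is.finite(lp_prop) &
          log(runif(nb)) < lp_prop - lp_cur
        st$x[tr[ok], ] <- xp[ok, , drop = FALSE]
        att["x"] <- att["x"] + sum(live)
        acc["x"] <- acc["x"] + sum(ok)
        rec_cur <- .rec_total_logdens(st$x, st$N, th, pre)
      }
    }

    ## proposal-scale adaptation during burn-in only
    if (i <= burnin && i %% 50 == 0) {
      step <- min(0.15, 2 / sqrt(i))
      tune <- function(ls, a, n, target) {
        if (n == 0) return(ls)
        unname(ls + step * sign(a / n - target))
      }
      ls1 <- tune(ls1, acc["b1"], att["b1"], 0.234)
      ls2 <- tune(ls2, acc["b2"], att["b2"], 0.234)
      if (use_pop) {
        ls_g <- tune(ls_g, acc["g"], att["g"], 0.44)
        ls_f <- tune(ls_f, acc["f"], att["f"], 0.44)
        ls_s <- tune(ls_s, acc["s"], att["s"], 0.44)
      }
      acc[] <- 0; att[] <- 0
    }

    if (i > burnin && (i - burnin) %% thin == 0) {
      k_out <- k_out + 1L
      row <- setNames(plogis(st$z), .MS_NAMES)
      if (use_pop)
        row <- c(row, gamma = st$gamma, mu = st$mu,
                 sigma2 = exp(2 * st$lsig),
                 setNames(exp(st$lf), paste0("f_", pre$years)),
                 setNames(st$N[, 1], paste0("N1_", pre$years)),
                 setNames(st$N[, 2], paste0("N2_", pre$years)),
                 setNames(st$N[, 3], paste0("N3_", pre$years)))
      if (use_rec)
        row <- c(row, setNames(st$x[, 1], paste0("xP_", pre$years)),
                 setNames(st$x[, 2], paste0("xO_", pre$years)))
      draws[k_out, ] <- row[par_names]
    }
  }
  list(draws = draws,
       acceptance = ifelse(att > 0, acc / att, NA_real_))
}

#' Fit the integrated model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs over the continuous
#' parameters (in small blocks on logit/log scales, with a proposal shape
#' taken from the curvature of the radio-tracking sub-model at its mode)
#' and integer random-walk proposals for the latent population states and
#' latent death counts.  Runs are reproducible given `seed`.
#'
#' The default run lengths are desk-scale; for production runs increase
#' `iter`/`burnin` towards the classical three-chain, million-iteration
#' settings via the arguments.
#'
#' @param bundle A [kite_bundle()].
#' @param variant `"IPM2"` (all four streams), `"IPM1"` (no dead
#'   recoveries) or `"MS"` (radio-tracking only).
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param iter Total iterations per chain.
#' @param burnin Burn-in iterations discarded (adaptation happens here).
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed.
#' @param priors From [default_priors()].
#' @param beta2 Breeding propensity of 2-year-olds.
#' @param recovery_popscale See [log_joint()].
#' @return An object of class `kite_fit`: list with `draws` (one matrix
#'   of retained draws per chain), `variant`, `years`, `acceptance`, and
#'   the run `config`.
#' @export
run_mcmc <- function(bundle, variant = c("IPM2", "IPM1", "MS"),
                     chains = 3, iter = 50000, burnin = 25000, thin = 5,
                     seed = 1, priors = default_priors(), beta2 = 0.1,
                     recovery_popscale = 1) {
  variant <- match.arg(toupper(variant[1]), c("IPM2", "IPM1", "MS"))
  stopifnot(inherits(bundle, "kite_bundle"), iter > burnin, thin >= 1)
  pre <- .prep_data(bundle, variant)
  pre$popscale <- recovery_popscale
  set.seed(seed)
  map <- .ms_map(pre)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)
  res <- lapply(seq_len(chains), function(ci) {
    set.seed(chain_seeds[ci])
    .mcmc_chain(pre, variant, priors, beta2, map, iter, burnin, thin,
                jitter = if (ci == 1) 0 else 0.15)
  })
  structure(list(draws = lapply(res, `[[`, "draws"),
                 acceptance = lapply(res, `[[`, "acceptance"),
                 variant = variant, years = pre$years,
                 config = list(chains = chains, iter = iter,
                               burnin = burnin, thin = thin, seed = seed,
                               beta2 = beta2,
                               recovery_popscale = recovery_popscale,
                               priors = priors)),
            class = "kite_fit")
}

#' Pool retained draws across chains
#' @param fit A `kite_fit`.
#' @return A single matrix of draws (iterations stacked over chains).
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "kite_fit"))
  do.call(rbind, fit$draws)
}

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter:
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of the means.
#'
#' @param fit A `kite_fit`, or a list of draw matrices (one per chain,
#'   identical columns).
#' @param threshold Parameters with `Rhat` above this value are flagged.
#' @return Named vector of `Rhat` values with attribute `"flagged"`.
#' @export
gelman_rubin <- function(fit, threshold = 1.1) {
  draws <- if (inherits(fit, "kite_fit")) fit$draws else fit
  if (length(draws) < 2) stop("at least 2 chains are required")
  n <- nrow(draws[[1]])
  k <- ncol(draws[[1]])
  means <- matrix(vapply(draws, colMeans, numeric(k)), k)
  vars <- matrix(vapply(draws, function(d) apply(d, 2, var), numeric(k)),
                 k)
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  rhat <- setNames(sqrt(((n - 1) / n * W + B_over_n) / W),
                   colnames(draws[[1]]))
  rhat[W == 0 & B_over_n == 0] <- 1
  structure(rhat, flagged = names(rhat)[is.finite(rhat) &
                                          rhat > threshold])
}

#' Posterior summaries and derived quantities
#'
#' Per draw: poison-free survivals `phi*_a = phi + (1 - phi) m_a`,
#' proportional reductions `Delta_a = 1 - phi / phi*_a`, year-specific
#' growth rates `lambda_t = Ntot[t+1] / Ntot[t]` and their study-period
#' geometric mean (population-based variants only; draws with a zero
#' population are recorded as `NA`).
#'
#' @param fit A `kite_fit`.
#' @param level Credible level (central interval; default 0.95).
#' @return List with `draws` (matrix of derived draws) and `summary`
#'   (data.frame `parameter`, `mean`, `sd`, `lower`, `upper`).
#' @export
derived_quantities <- function(fit, level = 0.95) {
  d <- pooled_draws(fit)
  phi <- d[, "phi"]
  out <- list()
  for (a in c("juv", "1y", "2my")) {
    ps <- phi + (1 - phi) * d[, paste0("m_", a)]
    out[[paste0("phi_star_", a)]] <- ps
    out[[paste0("delta_", a)]] <- 1 - phi / ps
  }
  if (fit$variant != "MS") {
    yrs <- fit$years
    Ntot <- d[, paste0("N1_", yrs)] + d[, paste0("N2_", yrs)] +
      d[, paste0("N3_", yrs)]
    lam <- Ntot[, -1, drop = FALSE] / Ntot[, -ncol(Ntot), drop = FALSE]
    lam[!is.finite(lam)] <- NA
    colnames(lam) <- paste0("lambda_", yrs[-length(yrs)])
    for (j in colnames(lam)) out[[j]] <- lam[, j]
    out$lambda_geo <- exp(rowMeans(log(lam)))
    out$f_mean <- exp(d[, "mu"])
  }
  dm <- do.call(cbind, out)
  alpha <- (1 - level) / 2
  summ <- data.frame(
    parameter = colnames(dm),
    mean = colMeans(dm, na.rm = TRUE),
    sd = apply(dm, 2, sd, na.rm = TRUE),
    lower = apply(dm, 2, quantile, alpha, na.rm = TRUE),
    upper = apply(dm, 2, quantile, 1 - alpha, na.rm = TRUE),
    row.names = NULL)
  list(draws = dm, summary = summ)
}

#' Forward population projection
#'
#' Simulates the stochastic population process forward from each retained
#' draw's final latent state, propagating full parameter uncertainty.
#' Future year-specific fecundities are drawn from the fitted log-normal
#' hierarchy.
#'
#' @param fit A population-based `kite_fit` (IPM1 or IPM2).
#' @param horizon Number of years to project (0 returns the filtered final
#'   state; negative is an error).
#' @param seed Integer seed for the projection randomness.
#' @param level Credible level for the reported intervals.
#' @return A data.frame `year`, `median`, `lower`, `upper` of total female
#'   population size, with the per-draw trajectories as attribute
#'   `"draws"`.
#' @export
project <- function(fit, horizon = 3, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "kite_fit"))
  if (fit$variant == "MS")
    stop("projection requires a population-based variant (IPM1/IPM2)")
  if (horizon < 0) stop("horizon must be >= 0")
  d <- pooled_draws(fit)
  yrs <- fit$years
  last <- yrs[length(yrs)]
  n <- nrow(d)
  N1 <- d[, paste0("N1_", last)]
  N2 <- d[, paste0("N2_", last)]
  N3 <- d[, paste0("N3_", last)]
  beta2 <- fit$config$beta2
  out <- matrix(NA_real_, n, horizon + 1)
  out[, 1] <- N1 + N2 + N3
  set.seed(seed)
  if (horizon > 0) {
    phi <- d[, "phi"]; gam <- d[, "gamma"]
    for (h in seq_len(horizon)) {
      f_new <- exp(rnorm(n, d[, "mu"], sqrt(d[, "sigma2"])))
      B <- beta2 * N2 + gam * N3
      N1n <- rpois(n, phi * (f_new / 2) * B)
      N2n <- rbinom(n, N1, phi)
      N3n <- rbinom(n, N2 + N3, phi)
      N1 <- N1n; N2 <- N2n; N3 <- N3n
      out[, h + 1] <- N1 + N2 + N3
    }
  }
  alpha <- (1 - level) / 2
  res <- data.frame(
    year = last + 0:horizon,
    median = apply(out, 2, median),
    lower = apply(out, 2, quantile, alpha),
    upper = apply(out, 2, quantile, 1 - alpha))
  attr(res, "draws") <- out
  res
}

#' @export
print.kite_fit <- function(x, ...) {
  nk <- nrow(x$draws[[1]])
  cat("<kite_fit> variant ", x$variant, ": ", length(x$draws),
      " chain(s) x ", nk, " retained draws\n", sep = "")
  cat("  iter ", x$config$iter, ", burn-in ", x$config$burnin,
      ", thin ", x$config$thin, ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.kite_fit <- function(object, level = 0.95, ...) {
  d <- pooled_draws(object)
  alpha <- (1 - level) / 2
  rhat <- if (length(object$draws) >= 2)
    gelman_rubin(object) else rep(NA_real_, ncol(d))
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    lower = apply(d, 2, quantile, alpha),
    upper = apply(d, 2, quantile, 1 - alpha),
    Rhat = as.numeric(rhat),
    row.names = NULL)
}
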