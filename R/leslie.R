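# Deterministic Leslie-matrix analysis of poison-induced mortality.
#
# The female population is projected with a pre-breeding, three-age-class
# matrix.  Survival in each class is the product of a poison-free survival
# phi*_a and a proportional reduction Delta_a due to illegal poisoning:
# phi_a = phi*_a * (1 - Delta_a).  The analysis asks how the asymptotic
# growth rate lambda responds to the Delta_a: sensitivities, elasticities,
# break-even reductions at which lambda = 1, and lambda surfaces over
# (Delta, fecundity) grids.

#' Vital rates of the deterministic model
#'
#' @param phi_star Length-3 vector of poison-free survivals for the
#'   juvenile, 1-year-old and 2+ classes (names `juv`, `1y`, `2my` are
#'   attached in that order).
#' @param delta Length-3 vector of proportional survival reductions due to
#'   poisoning, same order; realized survival is
#'   `phi_a = phi_star_a * (1 - delta_a)`.
#' @param f Fecundity per breeding pair (full brood; halved internally for
#'   the female-based matrix).
#' @param gamma Breeding proportion of females older than 2 years.
#' @param beta2 Breeding propensity of 2-year-olds (default 0.1).
#' @return An object of class `vital_rates`.
#' @seealso [vital_rates_from_estimates()] to build the rates from an
#'   age-independent survival and age-specific poison fractions.
#' @export
vital_rates <- function(phi_star, delta, f, gamma, beta2 = 0.1) {
  stopifnot(length(phi_star) == 3, length(delta) == 3,
            all(phi_star >= 0 & phi_star <= 1),
            all(delta >= 0 & delta <= 1),
            f >= 0, gamma >= 0, gamma <= 1, beta2 >= 0, beta2 <= 1)
  structure(list(phi_star = setNames(as.numeric(phi_star),
                                     c("juv", "1y", "2my")),
                 delta = setNames(as.numeric(delta), c("juv", "1y", "2my")),
                 f = f, gamma = gamma, beta2 = beta2),
            class = "vital_rates")
}

#' Poison-free survival under additive mortality
#'
#' If poison-caused deaths were removed and mortality is additive, survival
#' would rise to `phi* = phi + (1 - phi) * m`, where `m` is the proportion
#' of deaths caused by poison.
#'
#' @param phi Realized annual survival probability.
#' @param m Proportion of deaths due to poisoning.
#' @return Poison-free survival probability.
#' @export
poison_free_survival <- function(phi, m) {
  if (any(phi < 0 | phi > 1 | m < 0 | m > 1))
    stop("phi and m must be probabilities in [0, 1]")
  phi + (1 - phi) * m
}

#' Proportional survival reduction due to poisoning
#'
#' `Delta = 1 - phi / phi*`: the fraction by which poisoning lowers
#' survival relative to its poison-free value.
#'
#' @param phi Realized survival.
#' @param phi_star Poison-free survival (must be positive).
#' @return Proportional reduction in \[0, 1\].
#' @export
proportional_reduction <- function(phi, phi_star) {
  if (any(phi_star <= 0)) stop("phi_star must be positive")
  1 - phi / phi_star
}

#' Vital rates from integrated-model estimates
#'
#' Convenience constructor: derives the poison-free survivals and
#' proportional reductions from an age-independent survival `phi` and the
#' age-specific poison fractions `m`.
#'
#' @param phi Age-independent annual survival.
#' @param m Length-3 vector of poison fractions (juv, 1y, 2+).
#' @inheritParams vital_rates
#' @return A [vital_rates()] object whose realized survivals all equal
#'   `phi`.
#' @export
vital_rates_from_estimates <- function(phi, m, f, gamma, beta2 = 0.1) {
  ps <- poison_free_survival(phi, m)
  vital_rates(ps, proportional_reduction(phi, ps), f, gamma, beta2)
}

#' Pre-breeding Leslie projection matrix
#'
#' Builds the 3x3 female projection matrix
#' \deqn{A = \begin{pmatrix} 0 & \beta_2 (f/2) \phi_{juv} &
#'   \gamma (f/2) \phi_{juv} \\ \phi_{1y} & 0 & 0 \\
#'   0 & \phi_{2my} & \phi_{2my} \end{pmatrix}}
#' where `phi_a = phi_star_a * (1 - delta_a)`.  Fertility includes
#' first-year survival because the census is pre-breeding, and fecundity is
#' halved because only females are projected.
#'
#' @param v A [vital_rates()] object.
#' @return 3x3 numeric matrix with age-class dimnames.
#' @export
leslie_matrix <- function(v) {
  stopifnot(inherits(v, "vital_rates"))
  s <- v$phi_star * (1 - v$delta)
  A <- matrix(c(0, v$beta2 * (v$f / 2) * s[["juv"]],
                v$gamma * (v$f / 2) * s[["juv"]],
                s[["1y"]], 0, 0,
                0, s[["2my"]], s[["2my"]]),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("1y", "2y", "3py"), c("1y", "2y", "3py")))
  A
}

#' Asymptotic growth rate and eigenstructure
#'
#' Dominant eigenvalue `lambda` of the projection matrix together with the
#' stable age distribution `w` (right eigenvector, normalized to sum 1)
#' and the reproductive values `v` (left eigenvector, normalized so that
#' the inner product with `w` is 1).
#'
#' @param A A 3x3 projection matrix from [leslie_matrix()], or a
#'   [vital_rates()] object.
#' @return List with components `lambda`, `stable_age`, `reproductive_value`.
#' @export
growth_rate <- function(A) {
  if (inherits(A, "vital_rates")) A <- leslie_matrix(A)
  e <- eigen(A)
  i <- which.max(Re(e$values))
  if (abs(Im(e$values[i])) > 1e-9)
    stop("dominant eigenvalue is not real; matrix may be reducible")
  lambda <- Re(e$values[i])
  w <- Re(e$vectors[, i])
  w <- w / sum(w)
  el <- eigen(t(A))
  j <- which.max(Re(el$values))
  vv <- Re(el$vectors[, j])
  vv <- vv / sum(vv * w)
  list(lambda = lambda, stable_age = w, reproductive_value = vv)
}

#' Sensitivity of lambda to the matrix elements
#'
#' `s_ij = v_i w_j / <v, w>`: the derivative of the dominant eigenvalue
#' with respect to each matrix element, defined for every cell including
#' structural zeros (the standard convention).
#'
#' @inheritParams growth_rate
#' @return 3x3 matrix of sensitivities.
#' @export
matrix_sensitivity <- function(A) {
  if (inherits(A, "vital_rates")) A <- leslie_matrix(A)
  g <- growth_rate(A)
  S <- outer(g$reproductive_value, g$stable_age)
  dimnames(S) <- dimnames(A)
  S
}

#' Elasticity of lambda to the matrix elements
#'
#' `e_ij = (a_ij / lambda) * s_ij`.  Over the whole matrix the elasticities
#' sum to 1.
#'
#' @inheritParams growth_rate
#' @return 3x3 matrix of elasticities.
#' @export
matrix_elasticity <- function(A) {
  if (inherits(A, "vital_rates")) A <- leslie_matrix(A)
  matrix_sensitivity(A) * A / growth_rate(A)$lambda
}

# Exact derivatives of the matrix cells with respect to one vital rate.
.dA_dtheta <- function(v, parameter) {
  s <- v$phi_star * (1 - v$delta)
  dA <- matrix(0, 3, 3)
  half <- v$f / 2
  switch(parameter,
    phi_star_juv = { dA[1, 2] <- v$beta2 * half * (1 - v$delta[["juv"]])
                     dA[1, 3] <- v$gamma * half * (1 - v$delta[["juv"]]) },
    delta_juv    = { dA[1, 2] <- -v$beta2 * half * v$phi_star[["juv"]]
                     dA[1, 3] <- -v$gamma * half * v$phi_star[["juv"]] },
    phi_star_1y  = { dA[2, 1] <- 1 - v$delta[["1y"]] },
    delta_1y     = { dA[2, 1] <- -v$phi_star[["1y"]] },
    phi_star_2my = { dA[3, 2] <- dA[3, 3] <- 1 - v$delta[["2my"]] },
    delta_2my    = { dA[3, 2] <- dA[3, 3] <- -v$phi_star[["2my"]] },
    f            = { dA[1, 2] <- v$beta2 * s[["juv"]] / 2
                     dA[1, 3] <- v$gamma * s[["juv"]] / 2 },
    gamma        = { dA[1, 3] <- half * s[["juv"]] },
    stop("unknown vital rate: ", parameter)
  )
  dA
}

#' Names of the perturbable vital rates
#' @return Character vector of the eight vital-rate names.
#' @export
vital_rate_names <- function() {
  c("phi_star_juv", "phi_star_1y", "phi_star_2my",
    "delta_juv", "delta_1y", "delta_2my", "f", "gamma")
}

# Current value of one vital rate.
.vr_value <- function(v, parameter) {
  switch(parameter,
    phi_star_juv = v$phi_star[["juv"]], phi_star_1y = v$phi_star[["1y"]],
    phi_star_2my = v$phi_star[["2my"]],
    delta_juv = v$delta[["juv"]], delta_1y = v$delta[["1y"]],
    delta_2my = v$delta[["2my"]], f = v$f, gamma = v$gamma,
    stop("unknown vital rate: ", parameter))
}

#' Sensitivity and elasticity of lambda to a vital rate
#'
#' Lower-level perturbation: `dlambda/dtheta` is propagated through the
#' matrix cells by the exact chain rule,
#' `dlambda/dtheta = sum_ij s_ij * da_ij/dtheta`, and the elasticity is
#' `(theta / lambda) * dlambda/dtheta`.  Vital-rate derivatives can be
#' negative (reductions lower lambda); absolute values are reported, as is
#' conventional when only the magnitude of the response matters.
#'
#' @param v A [vital_rates()] object.
#' @param parameter One of [vital_rate_names()], or a vector of them.
#' @return A data.frame with columns `parameter`, `sensitivity`,
#'   `elasticity` (absolute values).
#' @export
vital_rate_perturbation <- function(v, parameter = vital_rate_names()) {
  stopifnot(inherits(v, "vital_rates"))
  S <- matrix_sensitivity(v)
  lambda <- growth_rate(v)$lambda
  out <- lapply(parameter, function(pn) {
    dldt <- sum(S * .dA_dtheta(v, pn))
    theta <- .vr_value(v, pn)
    data.frame(parameter = pn,
               sensitivity = abs(dldt),
               elasticity = abs(theta / lambda * dldt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Break-even poisoning level for one age class
#'
#' The proportional survival reduction `Delta_a` at which the growth rate
#' crosses 1, holding the other classes at their input reductions.  Solved
#' by bisection on \[0, 1\] to 1e-8.
#'
#' @param v A [vital_rates()] object giving the baseline.
#' @param age_class One of `"juv"`, `"1y"`, `"2my"`.
#' @return The break-even `Delta`, or `NA` (with a message) when lambda
#'   does not cross 1 on \[0, 1\].
#' @export
breakeven_reduction <- function(v, age_class = c("juv", "1y", "2my")) {
  age_class <- match.arg(age_class)
  lam_at <- function(d) {
    dd <- v$delta
    dd[[age_class]] <- d
    growth_rate(vital_rates(v$phi_star, dd, v$f, v$gamma, v$beta2))$lambda - 1
  }
  if (lam_at(0) * lam_at(1) > 0) {
    message("lambda does not cross 1 for any reduction of the ",
            age_class, " class")
    return(NA_real_)
  }
  uniroot(lam_at, c(0, 1), tol = 1e-8)$root
}

#' Growth-rate surfaces over poisoning and fecundity grids
#'
#' Tabulates lambda (i) along one-at-a-time curves in each class's
#' `Delta_a`, (ii) over a `(Delta_a, f)` grid per age class (from which the
#' lambda = 1 contour can be drawn), and (iii) over a grid where a common
#' `Delta` is applied to all classes against `f`.
#'
#' @param v Baseline [vital_rates()].
#' @param delta_grid Vector of proportional reductions (default 0 to 1 by
#'   0.01).
#' @param f_grid Vector of fecundities (default 0.5 to 2.5 by 0.05).
#' @return List of data.frames `curves` (`age`, `delta`, `lambda`),
#'   `per_class` (`age`, `delta`, `f`, `lambda`) and `common`
#'   (`delta`, `f`, `lambda`).
#' @export
lambda_surfaces <- function(v, delta_grid = seq(0, 1, by = 0.01),
                            f_grid = seq(0.5, 2.5, by = 0.05)) {
  if (!length(delta_grid) || !length(f_grid)) stop("empty grid")
  classes <- c("juv", "1y", "2my")
  lam <- function(dd, f) {
    growth_rate(vital_rates(v$phi_star, dd, f, v$gamma, v$beta2))$lambda
  }
  curves <- do.call(rbind, lapply(classes, function(a) {
    data.frame(age = a, delta = delta_grid,
               lambda = vapply(delta_grid, function(d) {
                 dd <- v$delta; dd[[a]] <- d; lam(dd, v$f)
               }, numeric(1)))
  }))
  per_class <- do.call(rbind, lapply(classes, function(a) {
    g <- expand.grid(delta = delta_grid, f = f_grid)
    g$lambda <- mapply(function(d, f) {
      dd <- v$delta; dd[[a]] <- d; lam(dd, f)
    }, g$delta, g$f)
    cbind(age = a, g)
  }))
  common <- expand.grid(delta = delta_grid, f = f_grid)
  common$lambda <- mapply(function(d, f) lam(rep(d, 3), f),
                          common$delta, common$f)
  list(curves = curves, per_class = per_class, common = common)
}
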