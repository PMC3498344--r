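# Multistate capture-recapture likelihood for radio-tagged birds.
#
# The chain is time-homogeneous because the state labels encode age: a single
# 16x16 transition matrix (whose alive rows use their own age-specific
# retention and cause-of-death classes) and a single 16x16 observation matrix
# describe every annual interval and occasion.  The likelihood of an
# encounter history is computed by the exact forward algorithm, conditioning
# on release in state alive-with-radio juvenile.

#' Multistate model parameters
#'
#' Bundles and validates the parameters of the multistate model:
#'
#' * `phi`: annual survival probability (age-independent, shared by sexes);
#' * `m_juv`, `m_1y`, `m_2my`: probability that a death was caused by poison,
#'   given death in the juvenile, one-year-old, or older age interval;
#' * `rho1`, `rho2`, `rho3`: annual radio-signal retention probability for
#'   the three retention classes (see [retention_class()]);
#' * `p`: encounter probability of a live bird with a functioning radio;
#' * `pA`: encounter probability of a live bird without a functioning radio;
#' * `rP`, `rO`: reporting probability of a bird found dead by poison /
#'   other causes without a functioning radio.
#'
#' Birds that die while carrying a functioning radio are recovered with
#' probability 1 (radios are tracked monthly, so carcasses are found soon
#' after death).
#'
#' @param phi,m_juv,m_1y,m_2my,rho1,rho2,rho3,p,pA,rP,rO Probabilities in
#'   \[0, 1\].
#' @return A named numeric vector of class `ms_params`.
#' @export
ms_params <- function(phi, m_juv, m_1y, m_2my, rho1, rho2, rho3,
                      p, pA, rP, rO) {
  x <- setNames(as.numeric(c(phi, m_juv, m_1y, m_2my, rho1, rho2, rho3,
                             p, pA, rP, rO)),
                c("phi", "m_juv", "m_1y", "m_2my", "rho1", "rho2",
                  "rho3", "p", "pA", "rP", "rO"))
  if (length(x) != 11 || anyNA(x) || any(x < 0) || any(x > 1))
    stop("all multistate parameters must be probabilities in [0, 1]")
  structure(x, class = "ms_params")
}

.as_ms_params <- function(params) {
  if (inherits(params, "ms_params")) return(params)
  nm <- c("phi", "m_juv", "m_1y", "m_2my", "rho1", "rho2", "rho3",
          "p", "pA", "rP", "rO")
  if (!all(nm %in% names(params)))
    stop("missing multistate parameters: ",
         paste(setdiff(nm, names(params)), collapse = ", "))
  do.call(ms_params, as.list(unlist(params)[nm]))
}

#' Annual transition matrix of the 16-state chain
#'
#' Rows are the state at occasion t, columns the state at occasion t + 1.
#' From alive-with-radio at age a (retention class k, cause-of-death class
#' c): survival phi splits between keeping (rho_k) and losing (1 - rho_k)
#' the radio signal while ageing one class; death (1 - phi) splits by cause
#' (m_c vs 1 - m_c) and, independently, by radio retention in the year of
#' death.  From alive-without-radio the bird stays radio-less.  Recently
#' dead states move to the absorbing unobserved-dead state.
#'
#' @param params An [ms_params()] vector (or coercible named vector/list).
#' @return A 16x16 row-stochastic matrix with state labels as dimnames.
#' @export
transition_matrix <- function(params) {
  params <- .as_ms_params(params)
  TT <- .tmat_fast(params[["phi"]],
                   c(params[["m_juv"]], params[["m_1y"]],
                     params[["m_2my"]]),
                   c(params[["rho1"]], params[["rho2"]],
                     params[["rho3"]]))
  dimnames(TT) <- list(latent_states()$label, latent_states()$label)
  TT
}

# dimnameless transition matrix on plain numeric inputs: the sampler's
# inner-loop path.  State indices: 1-6 alive with radio (by age), 7-11
# alive without radio (ages 1y-5my), 12 DP.t, 13 DO.t, 14 DP.nt,
# 15 DO.nt, 16 unobserved dead.
.tmat_fast <- function(phi, m, rho) {
  TT <- matrix(0, 16, 16)
  succ_t <- c(2L, 3L, 4L, 5L, 6L, 6L)
  succ_nt <- c(7L, 8L, 9L, 10L, 11L, 11L)
  rk <- rho[c(1, 1, 1, 2, 3, 3)]        # retention class by age
  ma <- m[c(1, 2, 3, 3, 3, 3)]          # cause-of-death class by age
  for (a in 1:6) {
    TT[a, succ_t[a]] <- TT[a, succ_t[a]] + phi * rk[a]
    TT[a, succ_nt[a]] <- TT[a, succ_nt[a]] + phi * (1 - rk[a])
    TT[a, 12] <- (1 - phi) * ma[a] * rk[a]
    TT[a, 14] <- (1 - phi) * ma[a] * (1 - rk[a])
    TT[a, 13] <- (1 - phi) * (1 - ma[a]) * rk[a]
    TT[a, 15] <- (1 - phi) * (1 - ma[a]) * (1 - rk[a])
  }
  for (a in 2:6) {                      # alive, no radio
    s <- 5L + a
    TT[s, succ_nt[a]] <- TT[s, succ_nt[a]] + phi
    TT[s, 14] <- (1 - phi) * ma[a]
    TT[s, 15] <- (1 - phi) * (1 - ma[a])
  }
  TT[cbind(12:15, 16L)] <- 1
  TT[16, 16] <- 1
  TT
}

#' Observation matrix of the 16-state chain
#'
#' Rows are latent states, columns the 16 observable event codes.  Live
#' birds with a functioning radio produce their age-specific alive event
#' with probability `p` (event 16 otherwise); live birds without a radio
#' their age-specific no-radio event with probability `pA`; birds recently
#' dead with a functioning radio are found with probability 1; birds
#' recently dead without a radio are reported with probability `rP`
#' (poison) or `rO` (other causes); the unobserved-dead state always emits
#' event 16.
#'
#' @inheritParams transition_matrix
#' @return A 16x16 row-stochastic matrix (states x events).
#' @export
observation_matrix <- function(params) {
  params <- .as_ms_params(params)
  OO <- .omat_fast(params[["p"]], params[["pA"]], params[["rP"]],
                   params[["rO"]])
  dimnames(OO) <- list(latent_states()$label, event_codes()$label)
  OO
}

.omat_fast <- function(p, pA, rP, rO) {
  OO <- matrix(0, 16, 16)
  for (s in 1:6) {                      # alive with radio -> events 1-6
    OO[s, s] <- p
    OO[s, 16] <- 1 - p
  }
  for (s in 7:11) {                     # alive without radio -> events 9-13
    OO[s, s + 2L] <- pA
    OO[s, 16] <- 1 - pA
  }
  OO[12, 7] <- 1                        # dead with radio: found for sure
  OO[13, 8] <- 1
  OO[14, 14] <- rP; OO[14, 16] <- 1 - rP
  OO[15, 15] <- rO; OO[15, 16] <- 1 - rO
  OO[16, 16] <- 1
  OO
}

# Convert a histories data.frame (id, sex, release_year, y<year>...) into an
# integer event matrix plus release indices.  Year columns may be named
# "y1999" or "1999".
.history_matrix <- function(histories, years = NULL) {
  if (is.null(years)) {
    yc <- grep("^y?[0-9]{4}$", names(histories), value = TRUE)
    years <- as.integer(sub("^y", "", yc))
  } else {
    yc <- intersect(c(paste0("y", years), as.character(years)),
                    names(histories))
    if (length(yc) != length(years)) stop("year columns not found")
  }
  o <- order(years)
  years <- years[o]; yc <- yc[o]
  ev <- as.matrix(histories[, yc, drop = FALSE])
  storage.mode(ev) <- "integer"
  rel <- match(histories$release_year, years)
  if (anyNA(rel)) stop("release_year outside the study years")
  list(events = ev, release = rel, years = years,
       id = as.character(histories$id))
}

# Group identical post-release event sequences.  The chain is
# time-homogeneous (the state alphabet encodes age), so the likelihood
# only depends on the sequence of events after release, not on the
# calendar year of release.  Two further reductions: sequences are
# truncated after a recovery event whenever the remaining events are all
# 16 (an observed death is followed by the absorbing unobserved-dead
# state, which emits event 16 with probability 1), and rows are sorted by
# decreasing length so the forward recursion works on a shrinking prefix.
.compress_histories <- function(hm) {
  n <- nrow(hm$events)
  TT <- ncol(hm$events)
  maxlen <- max(TT - min(hm$release), 1L)
  post <- matrix(NA_integer_, n, maxlen)
  len <- integer(n)
  dead_ev <- c(7L, 8L, 14L, 15L)
  for (i in seq_len(n)) {
    r <- hm$release[i]
    if (r < TT) {
      ev <- hm$events[i, (r + 1L):TT]
      d <- which(ev %in% dead_ev)
      if (length(d) && d[1] < length(ev) &&
          all(ev[(d[1] + 1L):length(ev)] == 16L))
        ev <- ev[seq_len(d[1])]
      len[i] <- length(ev)
      post[i, seq_along(ev)] <- ev
    }
  }
  key <- apply(post, 1L, paste, collapse = ",")
  grp <- match(key, unique(key))
  keep <- which(!duplicated(grp))
  keep <- keep[order(len[keep], decreasing = TRUE)]
  list(events = post[keep, , drop = FALSE],
       w = as.vector(tabulate(grp)[grp[keep]]),
       len = len[keep],
       nact = vapply(seq_len(maxlen), function(t) sum(len[keep] >= t),
                     integer(1)),
       rep_id = hm$id[keep],
       rep_release = hm$release[keep],
       years = hm$years)
}

# Forward-algorithm log-likelihood on a compressed history set.  Rows are
# sorted by decreasing sequence length, so the active set is always a
# prefix and finished rows are simply dropped from the working matrix.
.ch_loglik_compressed <- function(comp, TT, OO) {
  n <- nrow(comp$events)
  L <- ncol(comp$events)
  A <- matrix(0, n, 16)
  A[, 1] <- 1                           # released alive, radio on, juvenile
  ll <- 0
  OOt <- t(OO)
  nt_prev <- n
  for (t in seq_len(L)) {
    nt <- comp$nact[t]
    if (nt == 0L) break
    if (nt < nt_prev) A <- A[seq_len(nt), , drop = FALSE]
    A <- (A %*% TT) * OOt[comp$events[seq_len(nt), t], , drop = FALSE]
    s <- rowSums(A)
    if (any(s == 0)) {
      ib <- which(s == 0)
      warning("impossible event for individual ", comp$rep_id[ib[1]],
              " at occasion ",
              comp$years[comp$rep_release[ib[1]] + t],
              " (event ", comp$events[ib[1], t], ")")
      return(-Inf)
    }
    ll <- ll + sum(comp$w[seq_len(nt)] * log(s))
    A <- A / s
    nt_prev <- nt
  }
  ll
}

#' Log-likelihood of radio-tracking encounter histories
#'
#' Exact marginalization over the 16 latent states by the forward
#' algorithm, conditioning each bird on its release in state
#' alive-with-radio juvenile.  Male and female histories are pooled: all
#' parameters are shared between sexes.
#'
#' @param histories A data.frame with columns `id`, `sex`, `release_year`
#'   and one column per study year (named e.g. `y1999`) holding the event
#'   code 1-16 observed that year, with 0 before (and at most at) release.
#'   The release-year entry must be event 1 (the tagging itself) and does
#'   not contribute to the likelihood.
#' @param params An [ms_params()] vector.
#' @param years Optional integer vector of study years, if the columns
#'   cannot be inferred from names.
#' @return The summed log-likelihood (scalar).  `-Inf`, with a warning
#'   naming the individual and occasion, if some event has probability zero
#'   under `params`.
#' @export
ch_loglik <- function(histories, params, years = NULL) {
  params <- .as_ms_params(params)
  hm <- .history_matrix(histories, years)
  rel_ev <- hm$events[cbind(seq_len(nrow(hm$events)), hm$release)]
  if (any(rel_ev != 1L))
    stop("the release-year event must be 1 (seen alive, radio on, juvenile)")
  comp <- .compress_histories(hm)
  .ch_loglik_compressed(comp, transition_matrix(params),
                        observation_matrix(params))
}
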