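# State and event alphabets of the multistate capture-recapture model.
#
# A radio-tagged bird is followed through a 16-state hidden Markov chain:
# alive with a working radio in one of six age classes, alive without a
# working radio in one of five (non-juvenile) age classes, four "recently
# dead" states crossing cause of death (poison / other) with radio status,
# and one absorbing unobserved-dead state.  Age is deterministic given the
# release year (all birds are tagged as nestlings), so it lives in the state
# label rather than as a separate uncertainty.

#' Age classes of the multistate model
#'
#' Six annual age classes used for radio-tagged birds: juvenile (tagging to
#' end of first year), then one- to four-year-olds, and a terminal `5my`
#' class covering five or more years.
#'
#' @return Character vector of the six ordered age-class labels.
#' @export
age_classes <- function() c("juv", "1y", "2y", "3y", "4y", "5my")

#' Next age class
#'
#' @param age Age-class label (see [age_classes()]).
#' @return The following age class; `5my` is absorbing and maps to itself.
#' @examples
#' age_successor("juv")  # "1y"
#' age_successor("5my")  # "5my"
#' @export
age_successor <- function(age) {
  ages <- age_classes()
  i <- match(age, ages)
  if (anyNA(i)) stop("unknown age class: ", paste(age[is.na(i)], collapse = ", "))
  ages[pmin(i + 1L, length(ages))]
}

#' Radio-signal retention class of an age
#'
#' Tag batteries last about 3-4 years, so annual signal retention is modelled
#' with three age-dependent probabilities: class 1 applies to transitions
#' starting between tagging and the end of the third year of life
#' (`juv`, `1y`, `2y`), class 2 between 3 and 4 years old (`3y`), and class 3
#' to all following years (`4y`, `5my`).
#'
#' @inheritParams age_successor
#' @return Integer retention class in 1..3.
#' @export
retention_class <- function(age) {
  k <- c(juv = 1L, `1y` = 1L, `2y` = 1L, `3y` = 2L, `4y` = 3L, `5my` = 3L)[age]
  if (anyNA(k)) stop("unknown age class: ", paste(age[is.na(k)], collapse = ", "))
  unname(k)
}

#' Cause-of-death age class of an age
#'
#' The probability that a death was caused by poison is age-dependent with
#' three levels: juveniles, one-year-olds, and birds two years or older.
#'
#' @inheritParams age_successor
#' @return One of `"juv"`, `"1y"`, `"2my"`.
#' @export
mortality_class <- function(age) {
  a <- c(juv = "juv", `1y` = "1y", `2y` = "2my", `3y` = "2my",
         `4y` = "2my", `5my` = "2my")[age]
  if (anyNA(a)) stop("unknown age class: ", paste(age[is.na(a)], collapse = ", "))
  unname(a)
}

#' Latent states of the multistate model
#'
#' @return A data.frame with one row per latent state: `id` (1-16), `label`,
#'   `kind` (`alive_radio`, `alive_noradio`, `dead_obs`, `dead_unobs`), and
#'   `age` (the age-class label for alive states, `NA` for dead states --
#'   dead states carry radio status but no age).
#' @export
latent_states <- function() {
  ages <- age_classes()
  data.frame(
    id = 1:16,
    label = c(paste0(ages, ".t"), paste0(ages[-1], ".nt"),
              "DP.t", "DO.t", "DP.nt", "DO.nt", "UD"),
    kind = c(rep("alive_radio", 6), rep("alive_noradio", 5),
             rep("dead_obs", 4), "dead_unobs"),
    age = c(ages, ages[-1], rep(NA_character_, 5)),
    stringsAsFactors = FALSE
  )
}

#' Observable event codes
#'
#' Sixteen mutually exclusive annual events: 1-6 seen alive with a working
#' radio (by age class), 7/8 found dead by poison / other causes with a
#' working radio, 9-13 seen alive without a working radio (non-juvenile age
#' classes), 14/15 found dead by poison / other causes without a working
#' radio, and 16 neither seen nor heard.
#'
#' @return A data.frame with `id` (1-16), `label`, and `state`: the id of the
#'   unique latent state compatible with the event (`NA` for event 16, which
#'   is compatible with several states).
#' @export
event_codes <- function() {
  ages <- age_classes()
  data.frame(
    id = 1:16,
    label = c(paste0("seen.", ages, ".t"), "dead.poison.t", "dead.other.t",
              paste0("seen.", ages[-1], ".nt"), "dead.poison.nt",
              "dead.other.nt", "not.seen"),
    state = c(1:6, 12L, 13L, 7:11, 14L, 15L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

# Alphabet sanity checks, run when the package is loaded.
.check_alphabets <- function() {
  st <- latent_states()
  ev <- event_codes()
  stopifnot(
    nrow(st) == 16L, nrow(ev) == 16L,
    sum(st$kind == "alive_radio") == 6L,
    sum(st$kind == "alive_noradio") == 5L,
    sum(st$kind == "dead_obs") == 4L,
    sum(st$kind == "dead_unobs") == 1L,
    # events 1-15 each map to exactly one state, with no conflicts
    !anyNA(ev$state[1:15]),
    !anyDuplicated(ev$state[1:15]),
    is.na(ev$state[16])
  )
  invisible(TRUE)
}

.onLoad <- function(libname, pkgname) {
  .check_alphabets()
}
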