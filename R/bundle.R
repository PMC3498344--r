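# The dataset bundle: the four aligned data streams, with validation and
# plain-CSV readers/writers.

#' Assemble and validate a dataset bundle
#'
#' @param counts Data.frame `year`, `breeding_pairs`.
#' @param productivity Data.frame `year`, `n_broods`, `n_fledglings`.
#' @param recoveries Data.frame `year`, `n_dead_poison`, `n_dead_other`,
#'   or `NULL` when the stream is absent (allowed for variants that do not
#'   use it).
#' @param histories Data.frame `id`, `sex`, `release_year`, plus one
#'   integer column per study year (named `y<year>`) holding the event
#'   code 1-16 observed that year and 0 before release.
#' @return A list of class `kite_bundle` with a common `years` index.
#' @export
kite_bundle <- function(counts, productivity, recoveries = NULL,
                        histories) {
  .check_cols <- function(d, nm, what) {
    miss <- setdiff(nm, names(d))
    if (length(miss))
      stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  .check_counts <- function(x, what) {
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad))
      stop(what, ": non-negative integer required at row ", bad[1])
  }
  .check_cols(counts, c("year", "breeding_pairs"), "counts")
  .check_counts(counts$breeding_pairs, "counts$breeding_pairs")
  .check_cols(productivity, c("year", "n_broods", "n_fledglings"),
              "productivity")
  .check_counts(productivity$n_broods, "productivity$n_broods")
  .check_counts(productivity$n_fledglings, "productivity$n_fledglings")
  if (any(productivity$n_broods == 0 & productivity$n_fledglings > 0))
    stop("productivity: fledglings recorded in a year with zero broods")
  if (!is.null(recoveries)) {
    .check_cols(recoveries, c("year", "n_dead_poison", "n_dead_other"),
                "recoveries")
    .check_counts(recoveries$n_dead_poison, "recoveries$n_dead_poison")
    .check_counts(recoveries$n_dead_other, "recoveries$n_dead_other")
  }
  .check_cols(histories, c("id", "sex", "release_year"), "histories")
  hm <- .history_matrix(histories)
  for (i in seq_len(nrow(hm$events))) {
    ev <- hm$events[i, ]
    rel <- hm$release[i]
    if (any(ev < 0 | ev > 16))
      stop("histories: invalid event code for individual ", hm$id[i],
           " (row ", i, "): ", ev[which(ev < 0 | ev > 16)[1]])
    if (rel > 1 && any(ev[seq_len(rel - 1)] != 0))
      stop("histories: non-zero event before release for individual ",
           hm$id[i], " (row ", i, ")")
    if (ev[rel] != 1L)
      stop("histories: release-year event must be 1 for individual ",
           hm$id[i], " (row ", i, ")")
    if (rel < length(ev) && any(ev[(rel + 1):length(ev)] == 0))
      stop("histories: event 0 after release for individual ", hm$id[i],
           " (row ", i, ")")
  }
  years <- sort(unique(c(counts$year, productivity$year,
                         recoveries$year, hm$years)))
  if (!length(intersect(counts$year, hm$years)))
    stop("counts and histories share no study years")
  structure(list(counts = counts, productivity = productivity,
                 recoveries = recoveries, histories = histories,
                 years = years),
            class = "kite_bundle")
}

#' @export
print.kite_bundle <- function(x, ...) {
  cat("<kite_bundle> ", min(x$years), "-", max(x$years), "\n", sep = "")
  cat("  counts:      ", nrow(x$counts), " years, ",
      sum(x$counts$breeding_pairs), " breeding-pair records\n", sep = "")
  cat("  productivity:", sum(x$productivity$n_fledglings), "fledglings from",
      sum(x$productivity$n_broods), "broods\n")
  if (is.null(x$recoveries)) {
    cat("  recoveries:   (absent)\n")
  } else {
    cat("  recoveries:  ", sum(x$recoveries$n_dead_poison), "poisoned,",
        sum(x$recoveries$n_dead_other), "other causes\n")
  }
  cat("  histories:   ", nrow(x$histories), "tagged birds in",
      length(unique(x$histories$release_year)), "cohorts\n")
  invisible(x)
}

#' Read a dataset bundle from CSV files
#'
#' Expects `counts.csv`, `productivity.csv`, `recoveries.csv` and
#' `histories.csv` in `dir` (or explicit paths).  A missing recoveries
#' file is accepted: the resulting bundle can still be fitted under the
#' variants that do not use that stream.
#'
#' @param dir Directory containing the four CSV files.
#' @param counts,productivity,recoveries,histories Optional explicit paths
#'   overriding the defaults.
#' @return A validated [kite_bundle()].
#' @export
read_bundle <- function(dir = ".",
                        counts = file.path(dir, "counts.csv"),
                        productivity = file.path(dir, "productivity.csv"),
                        recoveries = file.path(dir, "recoveries.csv"),
                        histories = file.path(dir, "histories.csv")) {
  rd <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  rec <- if (file.exists(recoveries)) rd(recoveries) else NULL
  kite_bundle(rd(counts), rd(productivity), rec, rd(histories))
}

#' Write a dataset bundle to CSV files
#'
#' Inverse of [read_bundle()]: writes `counts.csv`, `productivity.csv`,
#' `recoveries.csv` (if present) and `histories.csv` into `dir`.
#'
#' @param bundle A [kite_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "kite_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(d, name) {
    utils::write.csv(d, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wr(bundle$counts, "counts.csv")
  wr(bundle$productivity, "productivity.csv")
  if (!is.null(bundle$recoveries)) wr(bundle$recoveries, "recoveries.csv")
  wr(bundle$histories, "histories.csv")
  invisible(dir)
}
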