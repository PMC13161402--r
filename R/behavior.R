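#' Percent correct performance
#'
#' Correct trials divided by the total of correct and incorrect trials;
#' aborted trials (fixation breaks, premature releases) are excluded from
#' both numerator and denominator.
#'
#' @param trials a trial table (or a [session_dataset()], from which the
#'   table is taken).
#' @param by character vector of grouping columns (default `"session_id"`).
#' @return data.frame with the grouping columns plus `n_correct`, `n_error`
#'   and `percent_correct`. Groups with no completed trials are absent;
#'   an error is raised if no completed trial exists at all.
#' @export
percent_correct <- function(trials, by = "session_id") {
  if (inherits(trials, "session_dataset")) trials <- trials$trials
  tr <- trials[trials$outcome != "aborted", , drop = FALSE]
  if (nrow(tr) == 0) stop("no completed (non-aborted) trials")
  miss <- setdiff(by, names(tr))
  if (length(miss)) stop("unknown grouping columns: ",
                         paste(miss, collapse = ", "))
  g <- tr[by]
  agg <- stats::aggregate(list(n_correct = tr$outcome == "correct",
                               n_error = tr$outcome == "error"),
                          by = g, FUN = sum)
  agg$percent_correct <- 100 * agg$n_correct / (agg$n_correct + agg$n_error)
  agg
}

#' Behavioral response functions
#'
#' Relative frequency of produced counts for each instructed numerosity and
#' format, computed per session and then averaged across sessions (the
#' session mean of per-session frequencies).  Rows are normalized
#' distributions over produced counts.
#'
#' @param trials trial table or [session_dataset()].
#' @param max_count largest produced count tracked explicitly (default: the
#'   maximum observed).
#' @return array `numerosity x format x produced count` of probabilities;
#'   each `(numerosity, format)` row sums to 1 (over sessions where that
#'   cell occurs).
#' @export
response_functions <- function(trials, max_count = NULL) {
  if (inherits(trials, "session_dataset")) trials <- trials$trials
  tr <- trials[trials$outcome != "aborted", , drop = FALSE]
  if (nrow(tr) == 0) stop("no completed trials")
  if (is.null(max_count)) max_count <- max(tr$produced_count)
  sessions <- unique(tr$session_id)
  formats <- sort(unique(tr$format))
  nums <- sort(unique(tr$numerosity))
  acc <- array(0, dim = c(length(nums), length(formats), max_count),
               dimnames = list(nums, formats, seq_len(max_count)))
  cnt <- array(0L, dim = dim(acc)[1:2], dimnames = dimnames(acc)[1:2])
  for (s in sessions) {
    trs <- tr[tr$session_id == s, , drop = FALSE]
    for (i in seq_along(nums)) for (j in seq_along(formats)) {
      sel <- trs$numerosity == nums[i] & trs$format == formats[j]
      if (!any(sel)) next
      p <- tabulate(pmin(trs$produced_count[sel], max_count),
                    nbins = max_count)
      acc[i, j, ] <- acc[i, j, ] + p / sum(p)
      cnt[i, j] <- cnt[i, j] + 1L
    }
  }
  if (any(cnt == 0)) warning("some (numerosity, format) cells unobserved")
  sweep(acc, 1:2, pmax(cnt, 1L), "/")
}

#' Behavioral chance level from unrestricted responses
#'
#' The task does not cap the number of releases, so the chance level is
#' estimated from the distribution of the maximum counts animals actually
#' choose when unconstrained: the reciprocal of the modal maximum count.
#' With the observed mode of 8 this yields 12.5%.  The construction is
#' heuristic but implemented exactly as used in practice.
#'
#' @param max_counts positive integer vector: observed maximum (unrestricted)
#'   response counts, e.g. one per session.
#' @return chance level in percent, `100 / mode(max_counts)` (ties broken
#'   toward the smaller count).
#' @export
chance_level <- function(max_counts) {
  if (length(max_counts) == 0) stop("empty response-count distribution")
  if (any(!is.finite(max_counts)) || any(max_counts <= 0) ||
      any(max_counts != round(max_counts)))
    stop("max_counts must be positive integers")
  tb <- table(max_counts)
  mode_count <- as.numeric(names(tb)[which.max(tb)])  # ties -> smaller
  100 / mode_count
}

#' Exclude poorly performing sessions
#'
#' Sessions with overall performance below the threshold (default 40%) are
#' excluded as reflecting insufficient task engagement.  "Below" is strict:
#' a session at exactly the threshold is included.
#'
#' @param summaries data.frame with columns `session_id` and
#'   `percent_correct` (e.g. from [percent_correct()]).
#' @param threshold exclusion threshold in percent.
#' @return the included subset, with an `included` logical column added.
#' @export
filter_sessions <- function(summaries, threshold = 40) {
  summaries$included <- summaries$percent_correct >= threshold
  summaries[summaries$included, , drop = FALSE]
}

#' One-sided t-tests of performance against chance
#'
#' For each stratum (by default numerosity x format x stimulus condition x
#' arrangement), computes per-session percent correct and tests the session
#' values against the chance level with a one-sided one-sample t-test
#' (alternative: performance above chance).
#'
#' @param trials trial table or [session_dataset()].
#' @param chance chance level in percent (scalar, or vector recycled over
#'   strata to allow per-stratum adjustment).
#' @param by stratification columns.
#' @return data.frame with stratum columns, `n_sessions`, `mean_pc`, `t`,
#'   `df`, `p`. Strata with fewer than 2 sessions get NA statistics and a
#'   warning.
#' @export
test_above_chance <- function(trials, chance = 12.5,
                              by = c("numerosity", "format",
                                     "stim_condition", "arrangement")) {
  if (inherits(trials, "session_dataset")) trials <- trials$trials
  pc <- percent_correct(trials, by = c("session_id", by))
  strata <- unique(pc[by])
  chance <- rep_len(chance, nrow(strata))
  res <- strata
  res$n_sessions <- NA_integer_
  res$mean_pc <- res$t <- res$df <- res$p <- NA_real_
  flagged <- FALSE
  for (i in seq_len(nrow(strata))) {
    sel <- rep(TRUE, nrow(pc))
    for (col in by) sel <- sel & pc[[col]] == strata[[col]][i]
    x <- pc$percent_correct[sel]
    res$n_sessions[i] <- length(x)
    res$mean_pc[i] <- mean(x)
    if (length(x) >= 2 && stats::sd(x) > 0) {
      tt <- stats::t.test(x, mu = chance[i], alternative = "greater")
      res$t[i] <- unname(tt$statistic)
      res$df[i] <- unname(tt$parameter)
      res$p[i] <- tt$p.value
    } else flagged <- TRUE
  }
  if (flagged)
    warning("strata with < 2 sessions (or zero variance) left undefined")
  res
}

#' Summarize behavioral performance of a dataset
#'
#' Convenience wrapper producing session-level percent correct (with the
#' exclusion flag), per-(numerosity, format) performance, response
#' functions, and above-chance tests in one object.
#'
#' @param ds a [session_dataset()].
#' @param chance chance level in percent.
#' @param exclude_threshold session exclusion threshold in percent.
#' @return list of class `behavior_summary`.
#' @export
behavior_summary <- function(ds, chance = 12.5, exclude_threshold = 40) {
  sess <- percent_correct(ds, by = "session_id")
  sess$included <- sess$percent_correct >= exclude_threshold
  keep <- ds$trials$session_id %in% sess$session_id[sess$included]
  tr <- ds$trials[keep, , drop = FALSE]
  by_nf <- percent_correct(tr, by = c("numerosity", "format"))
  rf <- response_functions(tr)
  above <- if (length(unique(tr$session_id)) >= 2)
    test_above_chance(tr, chance = chance) else NULL
  structure(list(sessions = sess, by_numerosity_format = by_nf,
                 response_functions = rf, chance = chance,
                 above_chance = above),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("behavior_summary:", nrow(x$sessions), "session(s),",
      sum(x$sessions$included), "included; overall",
      sprintf("%.1f%%", mean(x$sessions$percent_correct)),
      "correct; chance", sprintf("%.1f%%", x$chance), "\n")
  invisible(x)
}
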