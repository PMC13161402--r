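#' Construct and validate a session dataset
#'
#' The interchange container used by every analysis stage: a trial table, a
#' spike table, neuron metadata and a metadata list.  All times are in ms
#' relative to instruction onset.
#'
#' @param trials data.frame with columns `session_id`, `trial_id`,
#'   `numerosity`, `format`, `stim_condition`, `arrangement`,
#'   `produced_count` (NA for aborted trials), `outcome`
#'   (correct/error/aborted).
#' @param spikes data.frame with columns `neuron_id`, `trial_id`, `time_ms`.
#' @param neurons data.frame with columns `neuron_id`, `session_id`.
#' @param meta list with at least `phase` (fixation_ms, instruction_ms,
#'   planning_ms, execution_ms) and `provenance`.
#' @return an object of class `session_dataset`.
#' @export
session_dataset <- function(trials, spikes, neurons, meta) {
  ds <- structure(list(trials = trials, spikes = spikes, neurons = neurons,
                       meta = meta), class = "session_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a session dataset
#'
#' Checks schema and referential integrity; validation failures name the
#' offending rows.
#' @param ds a [session_dataset()].
#' @return `ds`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_dataset <- function(ds) {
  need_t <- c("session_id", "trial_id", "numerosity", "format",
              "stim_condition", "arrangement", "produced_count", "outcome")
  miss <- setdiff(need_t, names(ds$trials))
  if (length(miss)) stop("trials table missing columns: ",
                         paste(miss, collapse = ", "))
  need_s <- c("neuron_id", "trial_id", "time_ms")
  miss <- setdiff(need_s, names(ds$spikes))
  if (length(miss)) stop("spike table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(ds$trials$session_id, ds$trials$trial_id)
  dup <- duplicated(key)
  if (any(dup)) stop("duplicate trial ids within session at trial rows: ",
                     paste(utils::head(which(dup), 5), collapse = ", "))
  bad_out <- !(ds$trials$outcome %in% c("correct", "error", "aborted"))
  if (any(bad_out)) stop("invalid outcome at trial rows: ",
                         paste(utils::head(which(bad_out), 5), collapse = ", "))
  comp <- ds$trials$outcome != "aborted"
  mism <- comp & (is.na(ds$trials$produced_count) |
    ((ds$trials$produced_count == ds$trials$numerosity) !=
       (ds$trials$outcome == "correct")))
  if (any(mism)) stop("outcome inconsistent with produced_count at trial ",
                      "rows: ", paste(utils::head(which(mism), 5),
                                      collapse = ", "))
  if (nrow(ds$spikes)) {
    orphan_t <- !(ds$spikes$trial_id %in% ds$trials$trial_id)
    if (any(orphan_t))
      stop("spike rows reference unknown trials: rows ",
           paste(utils::head(which(orphan_t), 5), collapse = ", "))
    orphan_n <- !(ds$spikes$neuron_id %in% ds$neurons$neuron_id)
    if (any(orphan_n))
      stop("spike rows reference unknown neurons: rows ",
           paste(utils::head(which(orphan_n), 5), collapse = ", "))
  }
  invisible(ds)
}

#' @export
print.session_dataset <- function(x, ...) {
  n_sess <- length(unique(x$trials$session_id))
  cat("session_dataset:", n_sess, "session(s),", nrow(x$trials), "trials (",
      sum(x$trials$outcome == "correct"), "correct,",
      sum(x$trials$outcome == "error"), "error,",
      sum(x$trials$outcome == "aborted"), "aborted ),",
      nrow(x$neurons), "neurons,", nrow(x$spikes), "spikes\n")
  invisible(x)
}

#' Write a dataset to a directory of plain-text files
#'
#' Serializes to `trials.csv`, `spikes.csv`, `neurons.csv` and `meta.json`;
#' a diffable, language-neutral format that round-trips exactly
#' (spike times carry at most 3 decimals).
#'
#' @param ds a [session_dataset()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$spikes, file.path(path, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$neurons, file.path(path, "neurons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ds$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path directory containing `trials.csv`, `spikes.csv`,
#'   `neurons.csv`, `meta.json`.
#' @return a validated [session_dataset()]. An empty spike table is legal
#'   (all-zero-rate neurons).
#' @export
read_dataset <- function(path) {
  fs <- file.path(path, c("trials.csv", "spikes.csv", "neurons.csv",
                          "meta.json"))
  if (!all(file.exists(fs)))
    stop("dataset directory incomplete: missing ",
         paste(basename(fs[!file.exists(fs)]), collapse = ", "))
  trials <- utils::read.csv(fs[1], stringsAsFactors = FALSE)
  spikes <- utils::read.csv(fs[2], stringsAsFactors = FALSE,
                            colClasses = c(neuron_id = "character",
                                           trial_id = "integer",
                                           time_ms = "numeric"))
  neurons <- utils::read.csv(fs[3], stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(fs[4], simplifyVector = TRUE)
  session_dataset(trials, spikes, neurons, meta)
}

#' Sliding-bin scheme
#'
#' Left-aligned sliding windows: bin `b` (0-based) covers the half-open
#' interval `[start + b*step, start + b*step + width)`.  The number of bins
#' is `floor((end - start - width)/step) + 1`.
#'
#' @param start_ms,end_ms analysed interval in ms relative to instruction
#'   onset.
#' @param width_ms window width (default 200 ms).
#' @param step_ms step between window starts (default 20 ms).
#' @return object of class `bin_scheme` with elements `start_ms`, `end_ms`,
#'   `width_ms`, `step_ms`, `n_bins`, `starts` (window start times) and
#'   `centers`.
#' @export
bin_scheme <- function(start_ms, end_ms, width_ms = 200, step_ms = 20) {
  if (width_ms <= 0 || step_ms <= 0) stop("width and step must be positive")
  if (start_ms >= end_ms) stop("start_ms must be < end_ms")
  if (end_ms - start_ms < width_ms)
    stop("interval shorter than one window")
  n_bins <- floor((end_ms - start_ms - width_ms) / step_ms) + 1
  starts <- start_ms + (seq_len(n_bins) - 1) * step_ms
  structure(list(start_ms = start_ms, end_ms = end_ms, width_ms = width_ms,
                 step_ms = step_ms, n_bins = as.integer(n_bins),
                 starts = starts, centers = starts + width_ms / 2),
            class = "bin_scheme")
}

#' Number of spikes strictly before each of `x` among sorted times `t`
#' @keywords internal
#' @noRd
.count_before <- function(x, t) {
  if (length(t) == 0) return(rep(0L, length(x)))
  findInterval(x, t, left.open = TRUE)
}

#' Bin spike trains into a firing-rate tensor
#'
#' Counts spikes of every selected neuron and trial in each sliding window
#' of `scheme` (half-open bins: a spike exactly on the right edge is
#' excluded) and converts to rates in Hz.
#'
#' @param ds a [session_dataset()].
#' @param scheme a [bin_scheme()]; must lie within the recorded time range
#'   of every trial.
#' @param neurons character vector of neuron ids (default: all).
#' @param trials integer vector of trial ids (default: all non-aborted
#'   trials of the selected neurons' sessions).
#' @return object of class `binned_rates`: list with `rates` (array
#'   neurons x trials x bins, Hz), `scheme`, `neuron_ids`, `trial_ids`.
#' @export
bin_rates <- function(ds, scheme, neurons = NULL, trials = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"))
  ph <- ds$meta$phase
  t_min <- -ph$fixation_ms
  t_max <- ph$instruction_ms + ph$planning_ms + ph$execution_ms
  if (scheme$start_ms < t_min ||
      (scheme$starts[scheme$n_bins] + scheme$width_ms) > t_max)
    stop("bin scheme extends beyond recorded trial coverage [",
         t_min, ", ", t_max, "] ms")
  if (is.null(neurons)) neurons <- ds$neurons$neuron_id
  sess <- ds$neurons$session_id[match(neurons, ds$neurons$neuron_id)]
  if (is.null(trials)) {
    keep <- ds$trials$outcome != "aborted" & ds$trials$session_id %in% sess
    trials <- ds$trials$trial_id[keep]
  }
  lo <- scheme$starts
  hi <- scheme$starts + scheme$width_ms
  rates <- array(0, dim = c(length(neurons), length(trials), scheme$n_bins),
                 dimnames = list(neurons, NULL, NULL))
  spk <- ds$spikes[ds$spikes$neuron_id %in% neurons &
                     ds$spikes$trial_id %in% trials, , drop = FALSE]
  if (nrow(spk)) {
    grp <- split(spk$time_ms, list(factor(spk$neuron_id, levels = neurons),
                                   factor(spk$trial_id, levels = trials)),
                 drop = FALSE)
    for (j in seq_along(neurons)) {
      for (k in seq_along(trials)) {
        t <- grp[[paste(neurons[j], trials[k], sep = ".")]]
        if (is.null(t) || length(t) == 0) next
        t <- sort(t)
        rates[j, k, ] <- (.count_before(hi, t) - .count_before(lo, t)) /
          (scheme$width_ms / 1000)
      }
    }
  }
  structure(list(rates = rates, scheme = scheme, neuron_ids = neurons,
                 trial_ids = trials), class = "binned_rates")
}

#' Mean firing rate of a neuron in a time window
#'
#' Spike count in the half-open window `[window[1], window[2])` divided by
#' the window length, averaged over the given trials.
#'
#' @param ds a [session_dataset()].
#' @param neuron neuron id.
#' @param trials integer vector of trial ids; must be non-empty.
#' @param window numeric length-2, ms relative to instruction onset.
#' @param per_trial if `TRUE`, return the per-trial rates instead of their
#'   mean.
#' @return mean rate in Hz (or per-trial vector).
#' @export
mean_rate_in_window <- function(ds, neuron, trials, window,
                                per_trial = FALSE) {
  if (length(trials) == 0) stop("empty trial set")
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be (lo, hi) with hi > lo")
  spk <- ds$spikes[ds$spikes$neuron_id == neuron &
                     ds$spikes$trial_id %in% trials, , drop = FALSE]
  cnt <- rep(0, length(trials))
  if (nrow(spk)) {
    inw <- spk$time_ms >= window[1] & spk$time_ms < window[2]
    tb <- table(factor(spk$trial_id[inw], levels = trials))
    cnt <- as.numeric(tb)
  }
  rate <- cnt / ((window[2] - window[1]) / 1000)
  if (per_trial) rate else mean(rate)
}

#' Per-trial window rates for many neurons at once
#'
#' Internal workhorse behind the decoding feature builders: a neurons x
#' trials matrix of firing rates in one window.
#' @keywords internal
#' @noRd
.window_rates <- function(ds, neurons, trials, window) {
  out <- matrix(0, length(neurons), length(trials),
                dimnames = list(neurons, NULL))
  spk <- ds$spikes[ds$spikes$neuron_id %in% neurons &
                     ds$spikes$trial_id %in% trials &
                     ds$spikes$time_ms >= window[1] &
                     ds$spikes$time_ms < window[2], , drop = FALSE]
  if (nrow(spk)) {
    tb <- table(factor(spk$neuron_id, levels = neurons),
                factor(spk$trial_id, levels = trials))
    out <- out + as.matrix(tb)
  }
  out / ((window[2] - window[1]) / 1000)
}
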