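#' Sample a produced count from the behavioral model
#'
#' Approximate-number-system behavior: the internal estimate of the
#' instructed value `n` is log-normally distributed, `x ~ Normal(log n, w)`,
#' and the animal produces `round(exp(x))` handle releases (at least one).
#' This reproduces the two ANS signatures: errors cluster at numerically
#' adjacent values (distance effect) and the spread of produced counts grows
#' with `n` (size effect, Weber's law).
#'
#' @param numerosity instructed value, integer 1-5 (vectorized).
#' @param w Weber fraction, `w >= 0`. `w = 0` reproduces the instructed
#'   value deterministically.
#' @param n_draws draws per element of `numerosity` (default 1).
#' @return integer vector of produced counts (>= 1).
#' @export
sample_behavioral_response <- function(numerosity, w, n_draws = 1L) {
  if (any(!(numerosity %in% 1:5)))
    stop("numerosity must be in 1..5")
  if (w < 0) stop("weber fraction must be >= 0")
  n <- rep(as.numeric(numerosity), each = n_draws)
  x <- stats::rnorm(length(n), mean = log(n), sd = w)
  pmax(1L, as.integer(round(exp(x))))
}

#' Inter-response intervals of the enumeration period
#'
#' The timing of handle releases in the motor execution phase follows one of
#' three predefined temporal arrangements, designed so that neither rhythm
#' nor total duration predicts the numerical value: `standard` draws each
#' inter-response interval uniformly from 200, 500, 800 or 1100 ms;
#' `control1` fixes every interval at 200 ms; `control2` holds the overall
#' duration constant across numerosities (one interval of 2100 ms for value
#' 2, two of 800 ms for 3, three of 400 ms for 4, four of 200 ms for 5).
#'
#' @param scheme `"standard"`, `"control1"` or `"control2"`.
#' @param numerosity instructed value, 1-5.
#' @return numeric vector of `numerosity - 1` intervals in ms (empty for
#'   numerosity 1).
#' @export
temporal_arrangement <- function(scheme, numerosity) {
  if (!(numerosity %in% 1:5)) stop("numerosity must be in 1..5")
  k <- numerosity - 1L
  switch(scheme,
    standard = if (k == 0L) numeric(0) else
      sample(c(200, 500, 800, 1100), k, replace = TRUE),
    control1 = rep(200, k),
    control2 = switch(as.character(numerosity),
      "1" = numeric(0),
      "2" = 2100,
      "3" = c(800, 800),
      "4" = c(400, 400, 400),
      "5" = c(200, 200, 200, 200)),
    stop("unknown temporal arrangement scheme: ", scheme)
  )
}

#' Tuning factor on the (log) numerosity axis
#' @keywords internal
#' @noRd
.tuning_factor <- function(n_drive, pref, width, log_axis = TRUE) {
  if (is.na(pref)) return(0)
  if (log_axis) exp(-(log(n_drive) - log(pref))^2 / (2 * width^2))
  else exp(-(n_drive - pref)^2 / (2 * width^2))
}

#' Piecewise-constant firing rate profile of one neuron on one trial
#'
#' @return data.frame with columns `from`, `to`, `rate_hz` covering the
#'   trial from fixation onset to trial end.
#' @keywords internal
#' @noRd
.rate_profile <- function(neuron, n_drive, format, config) {
  pt <- phase_times(config)
  breaks <- c(pt[["fixation_on"]], 0, pt[["execution_on"]], pt[["trial_end"]])
  if (isTRUE(neuron$tuned)) {
    breaks <- c(breaks, neuron$window_onset_ms, neuron$window_offset_ms)
  }
  breaks <- sort(unique(breaks))
  from <- breaks[-length(breaks)]
  to <- breaks[-1]
  mid <- (from + to) / 2
  rate <- rep(neuron$baseline_hz, length(mid))
  if (isTRUE(neuron$tuned)) {
    inw <- mid >= neuron$window_onset_ms & mid < neuron$window_offset_ms
    tf <- .tuning_factor(n_drive, neuron$preferred_value,
                         neuron$tuning_width, config$log_axis)
    rate[inw] <- rate[inw] + neuron$gain_hz * tf
  }
  if (isTRUE(neuron$format_coupled) && identical(format, "sign")) {
    # format offset active from instruction onset to planning end
    inf_ <- mid >= 0 & mid < pt[["execution_on"]]
    rate[inf_] <- rate[inf_] + neuron$format_gain_hz
  }
  list(from = from, to = to, rate_hz = pmax(0, rate))
}

#' Sample an inhomogeneous Poisson spike train for one neuron and trial
#'
#' The firing rate is `lambda(t) = max(0, baseline + gain * f(n) * 1[t in
#' window] + format offset)`, with `f` a Gaussian tuning curve on the (log)
#' numerosity axis evaluated at the driving numerosity.  Execution-phase
#' activity is baseline only.  Spikes are drawn per piecewise-constant
#' segment (Poisson count, then uniform times), sorted, and rounded to 1 us
#' so that the on-disk text format round-trips exactly.
#'
#' @param neuron one row of a [make_population()] ground-truth table (as a
#'   list or one-row data.frame).
#' @param n_drive driving numerosity (1-5); under the default generator this
#'   is the produced (intended) count clipped to 1..5, so that error trials
#'   carry the signature of the erroneous plan.
#' @param format `"dot"` or `"sign"`.
#' @param config a [task_config()].
#' @return sorted numeric vector of spike times in ms relative to
#'   instruction onset.
#' @export
sample_spike_train <- function(neuron, n_drive, format, config) {
  neuron <- as.list(neuron)
  prof <- .rate_profile(neuron, n_drive, format, config)
  lam <- prof$rate_hz * (prof$to - prof$from) / 1000
  counts <- stats::rpois(length(lam), lam)
  times <- stats::runif(sum(counts), rep(prof$from, counts),
                        rep(prof$to, counts))
  unique(round(sort(times), 3))
}

#' Generate a complete synthetic experiment with known ground truth
#'
#' Builds one or more sessions of the number production task: a balanced
#' trial table over the 20 conditions (5 numerosities x 2 formats x 2
#' stimulus conditions), behavioral responses from the Weber-law model,
#' a small fraction of aborted trials, and Poisson spike trains for every
#' (neuron, trial) pair.  Each session combines the standard temporal
#' arrangement with one control arrangement, alternating between sessions.
#' Neurons are assigned to sessions round-robin (each neuron is recorded in
#' exactly one session, as in serial single-electrode recordings).
#'
#' Spike trains of tuned neurons are driven, during their response window,
#' by the numerosity the animal is planning to produce (`config$drive =
#' "produced"`, the default) or by the instructed value.  The produced-count
#' drive encodes the working hypothesis that planning activity predicts the
#' action count, so error trials carry reduced activity at the instructed
#' preferred value.
#'
#' Fully reproducible: all randomness derives from `config$seed`, with
#' per-(neuron, trial) substreams so the dataset is invariant to adding
#' neurons.
#'
#' @param config a [task_config()].
#' @param population a [make_population()] ground-truth table.
#' @return a list with elements `dataset` (a [session_dataset()]) and
#'   `truth` (the population table with session assignment added, plus the
#'   Weber fraction as attribute `"weber_fraction"`).
#' @export
generate_experiment <- function(config, population) {
  if (!inherits(config, "task_config")) stop("config must be a task_config")
  if (nrow(population) == 0) stop("neuron population must be non-empty")
  n_sess <- config$n_sessions
  pt <- phase_times(config)

  population$session_id <-
    sprintf("s%02d", rep_len(seq_len(n_sess), nrow(population)))

  trials_list <- vector("list", n_sess)
  trial_offset <- 0L
  for (s in seq_len(n_sess)) {
    sid <- sprintf("s%02d", s)
    control <- if (s %% 2 == 1) "control1" else "control2"
    grid <- expand.grid(numerosity = config$numerosities,
                        format = config$formats,
                        stim_condition = config$stim_conditions,
                        rep = seq_len(config$trials_per_condition),
                        stringsAsFactors = FALSE)
    # standard and the session's control arrangement, balanced per condition
    grid$arrangement <- ifelse(grid$rep %% 2 == 1, "standard", control)
    n_completed <- nrow(grid)
    n_abort <- round(config$abort_rate * n_completed)

    tr <- with_seed(mix_seed(config$seed, 7L, s), {
      ord <- sample.int(n_completed)
      g <- grid[ord, , drop = FALSE]
      produced <- sample_behavioral_response(g$numerosity,
                                             config$weber_fraction)
      outcome <- ifelse(produced == g$numerosity, "correct", "error")
      if (n_abort > 0) {
        ai <- sample.int(n_completed, n_abort, replace = TRUE)
        ab <- g[ai, , drop = FALSE]
        ab_df <- data.frame(numerosity = ab$numerosity, format = ab$format,
                            stim_condition = ab$stim_condition,
                            arrangement = ab$arrangement,
                            produced_count = NA_integer_,
                            outcome = "aborted", stringsAsFactors = FALSE)
      } else ab_df <- NULL
      out <- data.frame(numerosity = g$numerosity, format = g$format,
                        stim_condition = g$stim_condition,
                        arrangement = g$arrangement,
                        produced_count = as.integer(produced),
                        outcome = outcome, stringsAsFactors = FALSE)
      out <- rbind(out, ab_df)
      # interleave aborts at random positions
      out[sample.int(nrow(out)), , drop = FALSE]
    })
    tr <- data.frame(session_id = sid,
                     trial_id = trial_offset + seq_len(nrow(tr)),
                     tr, row.names = NULL, stringsAsFactors = FALSE)
    trial_offset <- trial_offset + nrow(tr)
    trials_list[[s]] <- tr
  }
  trials <- do.call(rbind, trials_list)

  # spike trains: one derived substream per (neuron, trial)
  spk_n <- vector("list", nrow(population))
  for (j in seq_len(nrow(population))) {
    neuron <- as.list(population[j, ])
    tr_s <- trials[trials$session_id == neuron$session_id &
                     trials$outcome != "aborted", , drop = FALSE]
    times_l <- vector("list", nrow(tr_s))
    for (k in seq_len(nrow(tr_s))) {
      n_drive <- if (config$drive == "produced")
        min(5L, max(1L, tr_s$produced_count[k])) else tr_s$numerosity[k]
      times_l[[k]] <- with_seed(
        mix_seed(config$seed, 11L, j, tr_s$trial_id[k]),
        sample_spike_train(neuron, n_drive, tr_s$format[k], config))
    }
    n_sp <- lengths(times_l)
    spk_n[[j]] <- data.frame(
      neuron_id = neuron$neuron_id,
      trial_id = rep(tr_s$trial_id, n_sp),
      time_ms = unlist(times_l, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, spk_n)
  if (is.null(spikes) || nrow(spikes) == 0)
    spikes <- data.frame(neuron_id = character(0), trial_id = integer(0),
                         time_ms = numeric(0))

  neurons <- data.frame(neuron_id = population$neuron_id,
                        session_id = population$session_id,
                        stringsAsFactors = FALSE)
  meta <- list(
    phase = list(fixation_ms = config$fixation_ms,
                 instruction_ms = config$instruction_ms,
                 planning_ms = config$planning_ms,
                 execution_ms = config$execution_ms),
    provenance = list(source = "synthetic", seed = config$seed,
                      trials_per_condition = config$trials_per_condition,
                      weber_fraction = config$weber_fraction,
                      drive = config$drive)
  )
  ds <- session_dataset(trials, spikes, neurons, meta)
  attr(population, "weber_fraction") <- config$weber_fraction
  list(dataset = ds, truth = population)
}
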