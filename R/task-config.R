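#' Task configuration for the number production experiment
#'
#' Describes the structure of a simulated number production session: a monkey
#' fixates, sees a numerical instruction cue (value 1-5, shown either as a
#' dot array or as a numeral sign, in a standard or a visually controlled
#' version), holds the value through a motor planning delay, and then
#' produces the matching count of handle releases.  The 5 numerosities x 2
#' formats x 2 stimulus conditions give 20 trial conditions.  Each session
#' combines the standard temporal arrangement of the response period with
#' one of two control arrangements, alternating between sessions.
#'
#' All times are in milliseconds relative to instruction onset; fixation
#' times are negative.
#'
#' @param n_sessions number of sessions to simulate.
#' @param trials_per_condition completed (non-aborted) trials per condition
#'   per session; must be at least 5 so that downstream per-condition
#'   inclusion rules are satisfiable.
#' @param fixation_ms,instruction_ms,planning_ms,execution_ms phase
#'   durations in ms. Defaults: 300 ms fixation baseline, 500 ms
#'   instruction, 1000 ms motor planning, 400 ms of simulated execution
#'   (execution activity is modelled as baseline only).
#' @param weber_fraction Weber fraction `w` of the behavioral model; the
#'   internal numerical estimate on a trial with instructed value `n` is
#'   `round(exp(x))`, `x ~ Normal(log n, w)`, clipped to be at least 1.
#' @param abort_rate fraction of additional aborted trials (fixation breaks
#'   or premature releases); aborted trials carry no produced count and no
#'   spikes, and are excluded from every analysis.
#' @param log_axis logical; if `TRUE` (default) neuronal tuning lives on a
#'   logarithmic numerosity axis, consistent with Weber-law behavior; if
#'   `FALSE`, a linear axis is used.
#' @param drive which numerosity drives planning-period activity:
#'   `"produced"` (default; activity reflects the animal's internal,
#'   possibly erroneous, intended count) or `"instructed"`.
#' @param seed root RNG seed; every stochastic draw in the generator is
#'   derived from it.
#'
#' @return an object of class `task_config` (a list).
#' @seealso [make_population()], [generate_experiment()]
#' @export
task_config <- function(n_sessions = 1L,
                        trials_per_condition = 10L,
                        fixation_ms = 300,
                        instruction_ms = 500,
                        planning_ms = 1000,
                        execution_ms = 400,
                        weber_fraction = 0.2,
                        abort_rate = 0.05,
                        log_axis = TRUE,
                        drive = c("produced", "instructed"),
                        seed = 1L) {
  drive <- match.arg(drive)
  if (trials_per_condition < 5)
    stop("trials_per_condition must be >= 5 (per-condition inclusion rule)")
  if (n_sessions < 1) stop("n_sessions must be >= 1")
  durs <- c(fixation_ms, instruction_ms, planning_ms, execution_ms)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("phase durations must be strictly positive")
  if (weber_fraction < 0) stop("weber_fraction must be >= 0")
  if (abort_rate < 0 || abort_rate >= 1) stop("abort_rate must be in [0, 1)")
  structure(list(
    n_sessions = as.integer(n_sessions),
    trials_per_condition = as.integer(trials_per_condition),
    numerosities = 1:5,
    formats = c("dot", "sign"),
    stim_conditions = c("standard", "control"),
    arrangements = c("standard", "control1", "control2"),
    fixation_ms = fixation_ms,
    instruction_ms = instruction_ms,
    planning_ms = planning_ms,
    execution_ms = execution_ms,
    weber_fraction = weber_fraction,
    abort_rate = abort_rate,
    log_axis = log_axis,
    drive = drive,
    seed = as.integer(seed)
  ), class = "task_config")
}

#' Phase boundary times of a configured trial
#'
#' @param config a [task_config()].
#' @return named vector with elements `fixation_on`, `instruction_on`,
#'   `planning_on`, `execution_on`, `trial_end` (ms relative to instruction
#'   onset).
#' @export
phase_times <- function(config) {
  c(fixation_on = -config$fixation_ms,
    instruction_on = 0,
    planning_on = config$instruction_ms,
    execution_on = config$instruction_ms + config$planning_ms,
    trial_end = config$instruction_ms + config$planning_ms +
      config$execution_ms)
}

#' Generate a ground-truth neuron population
#'
#' Draws per-neuron generative parameters for the Poisson spike simulator.
#' The population mixes the response classes observed in parietal
#' recordings: numerosity-tuned neurons (Gaussian tuning on a log or linear
#' numerosity axis) that are either excited or inhibited relative to
#' baseline, format-coupled nuisance neurons whose rate depends on the cue
#' format, and untuned neurons.  Tuned neurons carry either a static code
#' (one selective window spanning instruction and planning) or a dynamic
#' code (a short transient window of at most 400 ms).
#'
#' @param n_neurons population size.
#' @param p_tuned fraction of numerosity-tuned neurons (default 0.30, the
#'   order of magnitude seen in parietal cortex during motor planning).
#' @param p_format fraction of format-coupled (format-selective) neurons.
#' @param p_inhibited fraction of tuned neurons that are inhibited (rate
#'   dips below baseline at the preferred value); default 1/3, matching the
#'   roughly 2:1 excited:inhibited split reported for planning activity.
#' @param p_dynamic fraction of tuned neurons carrying a dynamic (transient)
#'   code rather than a static one.
#' @param gain_hz tuning gain in Hz at the preferred numerosity for excited
#'   neurons (inhibited neurons use a negative gain bounded by baseline).
#' @param tuning_width tuning-curve SD on the (log) numerosity axis.
#' @param baseline_range range of uniform baseline rates in Hz.
#' @param format_gain_hz additive rate offset for the sign format in
#'   format-coupled neurons, active from instruction onset to planning end.
#' @param code_type force all tuned neurons to one code type
#'   (`"static"`/`"dynamic"`), or `"mixed"` (default) to use `p_dynamic`.
#' @param seed RNG seed for the parameter draws.
#'
#' @return a `data.frame` of class `ground_truth` with one row per neuron:
#'   `neuron_id`, `tuned`, `preferred_value` (NA for untuned),
#'   `tuning_width`, `gain_hz`, `baseline_hz`, `window_onset_ms`,
#'   `window_offset_ms`, `code_type`, `format_coupled`, `format_gain_hz`,
#'   `sign` ("excited"/"inhibited"/NA).
#' @export
make_population <- function(n_neurons = 60L,
                            p_tuned = 0.30,
                            p_format = 0.05,
                            p_inhibited = 1 / 3,
                            p_dynamic = 0.5,
                            gain_hz = 20,
                            tuning_width = 0.3,
                            baseline_range = c(3, 12),
                            format_gain_hz = 8,
                            code_type = c("mixed", "static", "dynamic"),
                            seed = 1L) {
  code_type <- match.arg(code_type)
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  n <- as.integer(n_neurons)
  # one RNG substream per neuron: neuron i's parameters depend only on
  # (seed, i), so growing the population never perturbs existing neurons
  rows <- lapply(seq_len(n), function(i) {
    with_seed(mix_seed(seed, 101L, i), {
      u <- stats::runif(1)
      role <- if (u < p_tuned) "tuned"
        else if (u < p_tuned + p_format) "format" else "untuned"
      baseline <- stats::runif(1, baseline_range[1], baseline_range[2])
      pref <- NA_integer_; gain <- 0; onset <- offset <- NA_real_
      ct <- NA_character_; sign <- NA_character_
      if (role == "tuned") {
        pref <- sample(1:5, 1)
        inhib <- stats::runif(1) < p_inhibited
        # inhibited dip bounded so baseline + gain stays nonnegative
        gain <- if (inhib) -min(gain_hz, 0.9 * baseline) else gain_hz
        sign <- if (inhib) "inhibited" else "excited"
        is_dyn <- switch(code_type, mixed = stats::runif(1) < p_dynamic,
                         static = FALSE, dynamic = TRUE)
        ct <- if (is_dyn) "dynamic" else "static"
        if (ct == "static") {
          onset <- stats::runif(1, 100, 300)
          offset <- 1500
        } else {
          dur <- stats::runif(1, 250, 400)
          onset <- stats::runif(1, 100, 1500 - dur)
          offset <- onset + dur
        }
      }
      data.frame(
        neuron_id = sprintf("n%03d", i),
        tuned = role == "tuned",
        preferred_value = pref,
        tuning_width = tuning_width,
        gain_hz = gain,
        baseline_hz = baseline,
        window_onset_ms = onset,
        window_offset_ms = offset,
        code_type = ct,
        format_coupled = role == "format",
        format_gain_hz = if (role == "format") format_gain_hz else 0,
        sign = sign, stringsAsFactors = FALSE)
    })
  })
  gt <- do.call(rbind, rows)
  class(gt) <- c("ground_truth", "data.frame")
  gt
}
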