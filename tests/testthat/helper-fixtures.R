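# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Standard mixed population experiment: 1 session, 20 trials/condition,
# 30 neurons (~30% tuned, mixed static/dynamic, one format-coupled).
shared_experiment <- function() {
  if (is.null(.fixture_env$ex)) {
    cfg <- task_config(n_sessions = 1, trials_per_condition = 20, seed = 7)
    pop <- make_population(n_neurons = 30, seed = 13)
    .fixture_env$ex <- generate_experiment(cfg, pop)
    .fixture_env$cfg <- cfg
  }
  .fixture_env$ex
}

shared_config <- function() {
  shared_experiment()
  .fixture_env$cfg
}

# Selectivity analysis of the shared experiment, computed once.
shared_selectivity <- function() {
  if (is.null(.fixture_env$sel))
    .fixture_env$sel <- selectivity_analysis(shared_experiment()$dataset)
  .fixture_env$sel
}

# Tiny deterministic dataset built by hand: 1 session, explicit spike
# counts, no randomness.  `rate_per_num` gives, per numerosity, the number
# of spikes placed uniformly in [0, 1000) ms on every trial of that value.
hand_dataset <- function(rate_per_num = c(2, 4, 9, 4, 2),
                         trials_per_num = 4,
                         fixation_spikes = 0) {
  trials <- expand.grid(numerosity = 1:5, rep = seq_len(trials_per_num))
  trials <- data.frame(session_id = "s01",
                       trial_id = seq_len(nrow(trials)),
                       numerosity = trials$numerosity,
                       format = rep(c("dot", "sign"),
                                    length.out = nrow(trials)),
                       stim_condition = "standard",
                       arrangement = "standard",
                       produced_count = trials$numerosity,
                       outcome = "correct", stringsAsFactors = FALSE)
  spk <- list()
  for (i in seq_len(nrow(trials))) {
    k <- rate_per_num[trials$numerosity[i]]
    if (k > 0)
      spk[[length(spk) + 1]] <- data.frame(
        neuron_id = "n001", trial_id = trials$trial_id[i],
        time_ms = seq(0, 999, length.out = k + 1)[-1])
    if (fixation_spikes > 0)
      spk[[length(spk) + 1]] <- data.frame(
        neuron_id = "n001", trial_id = trials$trial_id[i],
        time_ms = seq(-299, -1, length.out = fixation_spikes))
  }
  spikes <- if (length(spk)) do.call(rbind, spk) else
    data.frame(neuron_id = character(0), trial_id = integer(0),
               time_ms = numeric(0))
  session_dataset(trials, spikes,
                  data.frame(neuron_id = "n001", session_id = "s01"),
                  meta = list(phase = list(fixation_ms = 300,
                                           instruction_ms = 500,
                                           planning_ms = 1000,
                                           execution_ms = 400),
                              provenance = list(source = "hand")))
}

# Brute-force window-count oracle used against bin_rates /
# mean_rate_in_window.
count_in_window_oracle <- function(times, lo, hi) {
  sum(times >= lo & times < hi)
}
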