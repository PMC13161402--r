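test_that("generation is deterministic and balanced over the condition grid", {
  cfg <- task_config(n_sessions = 1, trials_per_condition = 10,
                     abort_rate = 0.05, seed = 7)
  pop <- make_population(n_neurons = 6, seed = 2)
  ex1 <- generate_experiment(cfg, pop)
  ex2 <- generate_experiment(cfg, pop)
  expect_identical(ex1$dataset, ex2$dataset)

  tr <- ex1$dataset$trials
  completed <- tr[tr$outcome != "aborted", ]
  # 20 conditions x 10 trials
  expect_equal(nrow(completed), 200)
  tab <- table(completed$numerosity, completed$format,
               completed$stim_condition)
  expect_true(all(tab == 10))
  expect_gt(sum(tr$outcome == "aborted"), 0)
  # session 1 pairs standard with control1, balanced
  expect_setequal(unique(tr$arrangement), c("standard", "control1"))

  # adding neurons must not perturb existing trials or spike trains
  pop_big <- make_population(n_neurons = 8, seed = 2)
  ex3 <- generate_experiment(cfg, pop_big)
  expect_identical(ex1$dataset$trials, ex3$dataset$trials)
  old <- ex1$dataset$spikes
  new <- ex3$dataset$spikes
  new <- new[new$neuron_id %in% unique(old$neuron_id), ]
  rownames(new) <- NULL; rownames(old) <- NULL
  expect_identical(old, new)
})

test_that("generator rejects invalid configurations", {
  expect_error(task_config(trials_per_condition = 4), "at least 5|>= 5")
  expect_error(task_config(instruction_ms = 0), "positive")
  cfg <- task_config(seed = 1)
  expect_error(generate_experiment(cfg, make_population(1)[0, ]),
               "non-empty")
})

test_that("zero Weber fraction yields all-correct behavior", {
  cfg <- task_config(trials_per_condition = 5, weber_fraction = 0,
                     abort_rate = 0, seed = 3)
  ex <- generate_experiment(cfg, make_population(n_neurons = 2, seed = 1))
  expect_true(all(ex$dataset$trials$outcome == "correct"))
  expect_equal(sample_behavioral_response(rep(3, 50), w = 0), rep(3L, 50))
})

test_that("behavioral model shows distance and size effects", {
  set.seed(11)
  draws <- sample_behavioral_response(3, w = 0.2, n_draws = 1e5)
  tab <- tabulate(draws, nbins = 10)
  expect_equal(which.max(tab), 3)
  expect_gt(tab[2] + tab[4], tab[1] + tab[5])
  # distance effect: strictly decreasing response probability to distance 2
  p_d <- c(tab[3], tab[2] + tab[4], tab[1] + tab[5]) / length(draws)
  expect_true(all(diff(p_d) < 0))
  # size effect: SD grows with numerosity (scalar variability)
  sds <- vapply(1:5, function(n)
    stats::sd(sample_behavioral_response(n, w = 0.2, n_draws = 2e4)),
    numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_error(sample_behavioral_response(6, 0.2), "1..5")
})

test_that("temporal arrangements match the task's predefined timings", {
  expect_equal(temporal_arrangement("control2", 3), c(800, 800))
  expect_equal(temporal_arrangement("control2", 2), 2100)
  expect_equal(temporal_arrangement("control2", 4), rep(400, 3))
  expect_equal(temporal_arrangement("control1", 5), rep(200, 4))
  expect_length(temporal_arrangement("control1", 1), 0)
  expect_error(temporal_arrangement("bogus", 3), "unknown")
  expect_error(temporal_arrangement("standard", 7), "1..5")
  set.seed(5)
  draws <- replicate(1e4, temporal_arrangement("standard", 4)[1])
  freq <- table(factor(draws, levels = c(200, 500, 800, 1100))) / 1e4
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("spike trains are Poisson with the specified rate profile", {
  cfg <- task_config(seed = 1)  # trial spans [-300, 1900] = 2.2 s
  flat <- list(neuron_id = "n1", tuned = FALSE, preferred_value = NA,
               tuning_width = 0.3, gain_hz = 0, baseline_hz = 10,
               window_onset_ms = NA, window_offset_ms = NA,
               code_type = NA, format_coupled = FALSE, format_gain_hz = 0)
  set.seed(21)
  counts <- replicate(1e4,
    length(sample_spike_train(flat, 3, "dot", cfg)))
  expect_equal(mean(counts), 22, tolerance = 0.015)
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.9); expect_lt(fano, 1.1)

  # baseline 0 outside a driven window: no spikes outside the window
  gated <- flat
  gated$tuned <- TRUE; gated$preferred_value <- 3L
  gated$baseline_hz <- 0; gated$gain_hz <- 30
  gated$window_onset_ms <- 200; gated$window_offset_ms <- 700
  set.seed(22)
  for (i in 1:50) {
    st <- sample_spike_train(gated, 3, "dot", cfg)
    expect_true(all(st >= 200 & st < 700))
  }
})

test_that("tuned rates follow the Gaussian log-numerosity profile", {
  cfg <- task_config(seed = 1)
  neur <- list(neuron_id = "n1", tuned = TRUE, preferred_value = 3L,
               tuning_width = 0.3, gain_hz = 20, baseline_hz = 5,
               window_onset_ms = 500, window_offset_ms = 1500,
               code_type = "static", format_coupled = FALSE,
               format_gain_hz = 0)
  set.seed(31)
  mean_rate <- vapply(1:5, function(n) {
    cnt <- replicate(2000, {
      st <- sample_spike_train(neur, n, "dot", cfg)
      sum(st >= 500 & st < 1500)
    })
    mean(cnt)
  }, numeric(1))
  # closed form: expected window rate = baseline + gain * exp(-(log n -
  # log 3)^2 / (2 * 0.3^2)); expected total count over [-300,1900]
  lam <- function(n) 5 * 2.2 + 20 *
    exp(-(log(n) - log(3))^2 / (2 * 0.3^2)) * 1.0
  set.seed(32)
  for (n in c(1, 3, 5)) {
    cnt <- replicate(2000, length(sample_spike_train(neur, n, "dot", cfg)))
    expect_equal(mean(cnt), lam(n), tolerance = 0.03)
  }
  # ordering n=3 > n=2,4 > n=1,5
  expect_true(mean_rate[3] > mean_rate[2] && mean_rate[3] > mean_rate[4])
  expect_true(mean_rate[2] > mean_rate[1] && mean_rate[4] > mean_rate[5])

  # inhibited neurons dip below baseline inside the window
  inh <- neur; inh$gain_hz <- -4; inh$baseline_hz <- 5
  set.seed(33)
  cnt_in <- mean(replicate(2000, {
    st <- sample_spike_train(inh, 3, "dot", cfg)
    sum(st >= 500 & st < 1500)
  }))
  expect_lt(cnt_in, 5 * 1.0 * 0.7)  # well below the 5 Hz baseline count
})

test_that("ground-truth populations respect their structural invariants", {
  pop <- make_population(n_neurons = 200, seed = 9)
  tuned <- pop[pop$tuned, ]
  expect_true(all(tuned$window_offset_ms > tuned$window_onset_ms))
  dyn <- tuned[tuned$code_type == "dynamic", ]
  expect_true(all(dyn$window_offset_ms - dyn$window_onset_ms <= 400))
  stat <- tuned[tuned$code_type == "static", ]
  expect_true(all(stat$window_offset_ms == 1500))
  # rates stay nonnegative at every numerosity (clipping never active
  # at the preferred value of inhibited neurons)
  expect_true(all(tuned$baseline_hz + pmin(tuned$gain_hz, 0) >= 0))
  # role probabilities respected within binomial error (p = 0.30, 0.05)
  expect_gt(sum(pop$tuned), 200 * 0.30 - 3 * sqrt(200 * 0.3 * 0.7))
  expect_lt(sum(pop$tuned), 200 * 0.30 + 3 * sqrt(200 * 0.3 * 0.7))
  expect_lt(sum(pop$format_coupled), 25)
  # growing the population leaves existing neurons' parameters unchanged
  expect_identical(make_population(n_neurons = 50, seed = 9)[1:20, ],
                   make_population(n_neurons = 20, seed = 9))
})
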