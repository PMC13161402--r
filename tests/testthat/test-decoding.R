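# Gaussian toy features: K classes with means spaced by `sep` on the first
# coordinate plus isotropic noise.
toy_features <- function(K = 5, per_class = 20, sep = 5, sigma = 1,
                         p = 8, seed = 1) {
  set.seed(seed)
  y <- factor(rep(seq_len(K), each = per_class))
  mu <- matrix(0, K, p)
  mu[, 1] <- sep * seq_len(K)
  mu[, 2] <- sep * (seq_len(K) %% 2)
  x <- mu[as.integer(y), ] + matrix(rnorm(length(y) * p, sd = sigma),
                                    length(y), p)
  list(x = x, y = y)
}

test_that("well-separated classes decode perfectly; protocols validate", {
  toy <- toy_features(sigma = 1e-3, seed = 2)
  d <- decode(toy$x, toy$y, decoding_protocol(resamples = 3, seed = 1))
  expect_equal(d$accuracy, 100)
  expect_equal(unname(diag(d$confusion)), rep(1, 5))
  expect_error(decoding_protocol(trials_per_class = 15, folds = 10),
               "divisible")
  expect_error(decode(toy$x[-1, ], toy$y[-1],
                      decoding_protocol(resamples = 2)), "balanced")
})

test_that("confusion rows are normalized and chance matches 1/K", {
  toy <- toy_features(sigma = 3, seed = 3)
  d <- decode(toy$x, toy$y, decoding_protocol(resamples = 5, seed = 2))
  expect_true(all(abs(rowSums(d$confusion) - 1) < 1e-12))
  expect_equal(d$chance, 20)
  # shuffle nulls center on 1/K for K = 2, 3, 5
  for (K in c(2, 3, 5)) {
    toyK <- toy_features(K = K, per_class = 20, sigma = 2, seed = K)
    dn <- decode(toyK$x, toyK$y,
                 decoding_protocol(resamples = 100, seed = 4),
                 shuffle = TRUE)
    expect_equal(dn$accuracy, 100 / K, tolerance = 0.04)
  }
})

test_that("the linear SVM reproduces the analytic maximum-margin separator", {
  # 4 linearly separable points; the max-margin boundary is x1 = 1
  xtr <- rbind(c(0, 0), c(0, 1), c(2, 0), c(2, 1))
  ytr <- factor(c("a", "a", "b", "b"))
  m <- numopop:::.svm_fit(xtr, ytr, cost = 100)
  probes <- rbind(c(0.4, 0.5), c(0.99, 0), c(1.01, 1), c(1.9, 0.2))
  got <- as.character(predict(m, probes))
  want <- ifelse(probes[, 1] < 1, "a", "b")
  expect_equal(got, want)
})

test_that("accuracy degrades monotonically with feature noise", {
  sigmas <- c(0.5, 1.5, 3, 6, 12)
  accs <- vapply(seq_along(sigmas), function(i) {
    toy <- toy_features(sigma = sigmas[i], seed = 10)
    decode(toy$x, toy$y,
           decoding_protocol(resamples = 10, seed = 5))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 2))  # nonincreasing up to resampling noise
  expect_gt(accs[1] - accs[5], 20)
})

test_that("pseudopopulations sample without replacement, reproducibly", {
  ex <- shared_experiment(); ds <- ex$dataset
  neurons <- eligible_neurons(ds, 20)
  expect_gt(length(neurons), 10)
  pp <- build_pseudopopulation(ds, neurons, c(600, 1500), 20, seed = 9)
  expect_equal(dim(pp$x), c(100, length(neurons)))
  expect_equal(as.vector(table(pp$y)), rep(20, 5))
  # no duplicate trials per neuron within a class
  for (j in seq_along(neurons))
    expect_false(any(duplicated(pp$trial_ids[, j])))
  pp2 <- build_pseudopopulation(ds, neurons, c(600, 1500), 20, seed = 9)
  expect_identical(pp, pp2)
  pp3 <- build_pseudopopulation(ds, neurons, c(600, 1500), 20, seed = 10)
  expect_false(identical(pp$trial_ids, pp3$trial_ids))
})

test_that("planning activity decodes the planned number above chance", {
  ex <- shared_experiment(); ds <- ex$dataset
  d <- decode_numerosity(ds, protocol = decoding_protocol(resamples = 20,
                                                          seed = 11),
                         n_null = 20)
  expect_gt(d$accuracy, 45)
  expect_lt(d$null_mean, 25)
  expect_gt(d$accuracy, d$null_p95)
  # numerical distance effect in the confusion matrix
  dc <- distance_curves(d$confusion)
  expect_gt(dc[1, "1"], dc[1, "2"])
  expect_gt(dc[1, "2"], dc[1, "3"])
})

test_that("format-agnostic tuning yields cross ~ within format decoding", {
  ex <- shared_experiment(); ds <- ex$dataset
  xf <- decode_cross_format(ds,
    protocol = decoding_protocol(trials_per_class = 10, resamples = 20,
                                 seed = 12))
  within <- (xf$within_dot$accuracy + xf$within_sign$accuracy) / 2
  cross <- (xf$dot_to_sign$accuracy + xf$sign_to_dot$accuracy) / 2
  expect_gt(within, 40)
  expect_lt(within - cross, 5)
})

test_that("format-specific tuning collapses cross-format transfer", {
  # hand-built population whose preferred value differs between formats:
  # within-format structure is strong, across-format structure absent
  set.seed(77)
  n_neur <- 12; tpc <- 12
  trials <- expand.grid(numerosity = 1:5, format = c("dot", "sign"),
                        rep = seq_len(tpc), stringsAsFactors = FALSE)
  trials <- data.frame(session_id = "s01",
                       trial_id = seq_len(nrow(trials)),
                       numerosity = trials$numerosity,
                       format = trials$format,
                       stim_condition = "standard",
                       arrangement = "standard",
                       produced_count = trials$numerosity,
                       outcome = "correct", stringsAsFactors = FALSE)
  pref_dot <- sample(1:5, n_neur, replace = TRUE)
  pref_sign <- sample(1:5, n_neur, replace = TRUE)
  spk <- list()
  for (j in seq_len(n_neur)) {
    for (i in seq_len(nrow(trials))) {
      pref <- if (trials$format[i] == "dot") pref_dot[j] else pref_sign[j]
      rate <- 3 + 25 * exp(-(log(trials$numerosity[i]) - log(pref))^2 /
                             (2 * 0.09))
      k <- rpois(1, rate * 0.9)  # planning window 900 ms
      if (k > 0)
        spk[[length(spk) + 1]] <- data.frame(
          neuron_id = sprintf("n%03d", j), trial_id = trials$trial_id[i],
          time_ms = round(runif(k, 600, 1500), 3))
    }
  }
  ds <- session_dataset(trials, do.call(rbind, spk),
                        data.frame(neuron_id = sprintf("n%03d",
                                                       seq_len(n_neur)),
                                   session_id = "s01"),
                        meta = list(phase = list(fixation_ms = 300,
                                                 instruction_ms = 500,
                                                 planning_ms = 1000,
                                                 execution_ms = 400),
                                    provenance = list(source = "hand")))
  xf <- decode_cross_format(ds, window = c(600, 1500),
    protocol = decoding_protocol(trials_per_class = 10, resamples = 15,
                                 seed = 13))
  within <- (xf$within_dot$accuracy + xf$within_sign$accuracy) / 2
  cross <- (xf$dot_to_sign$accuracy + xf$sign_to_dot$accuracy) / 2
  expect_gt(within, 60)
  expect_lt(cross, 35)       # near the 20% chance level
  expect_gt(within - cross, 25)
})

test_that("static codes transfer across phases; windows must not overlap", {
  cfg <- task_config(trials_per_condition = 20, seed = 21)
  pop_s <- make_population(n_neurons = 20, p_tuned = 0.8, p_format = 0,
                           p_inhibited = 0, code_type = "static",
                           seed = 5)
  ex_s <- generate_experiment(cfg, pop_s)
  cp_s <- decode_cross_phase(ex_s$dataset,
    protocol = decoding_protocol(resamples = 15, seed = 14), n_null = 20)
  expect_gt(cp_s$accuracy["train_instruction_test_planning"],
            cp_s$null_p95["train_instruction_test_planning"])
  expect_gt(cp_s$accuracy["train_planning_test_instruction"],
            cp_s$null_p95["train_planning_test_instruction"])
  # purely dynamic population: across-phase transfer collapses
  pop_d <- make_population(n_neurons = 20, p_tuned = 0.8, p_format = 0,
                           p_inhibited = 0, code_type = "dynamic",
                           seed = 5)
  ex_d <- generate_experiment(cfg, pop_d)
  cp_d <- decode_cross_phase(ex_d$dataset,
    protocol = decoding_protocol(resamples = 15, seed = 14))
  across_s <- mean(cp_s$accuracy[c(2, 4)])
  across_d <- mean(cp_d$accuracy[c(2, 4)])
  expect_gt(across_s, across_d + 10)
  expect_error(decode_cross_phase(ex_s$dataset,
    windows = list(instruction = c(250, 800), planning = c(700, 1600))),
    "overlap")
})

test_that("produced-count errors degrade decoding of the instructed number", {
  ex <- shared_experiment(); ds <- ex$dataset
  ed <- decode_error_trials(ds,
    protocol = decoding_protocol(trials_per_class = 10, resamples = 25,
                                 seed = 15))
  expect_gt(ed$accuracy_correct, ed$accuracy_error + 10)
  expect_lt(ed$wilcoxon$p.value, 0.01)
})

test_that("errors sharing correct-trial statistics show no decoding gap", {
  cfg <- task_config(trials_per_condition = 20, weber_fraction = 0.25,
                     drive = "instructed", seed = 33)
  pop <- make_population(n_neurons = 20, p_tuned = 0.6, p_inhibited = 0,
                         seed = 6)
  ex <- generate_experiment(cfg, pop)
  ed <- decode_error_trials(ex$dataset,
    protocol = decoding_protocol(trials_per_class = 10, resamples = 25,
                                 seed = 16))
  expect_lt(abs(ed$accuracy_correct - ed$accuracy_error), 6)
})

test_that("outcome decoding separates correct, undershoot and overshoot", {
  cfg <- task_config(trials_per_condition = 40, weber_fraction = 0.25,
                     seed = 41)
  pop <- make_population(n_neurons = 20, p_tuned = 0.8, p_format = 0,
                         p_inhibited = 0, code_type = "static", seed = 8)
  ex <- generate_experiment(cfg, pop)
  do <- decode_outcome(ex$dataset,
    protocol = decoding_protocol(trials_per_class = 30, resamples = 15,
                                 seed = 17))
  expect_equal(dim(do$confusion), c(3, 3))
  expect_true(all(abs(rowSums(do$confusion) - 1) < 1e-12))
  expect_equal(do$chance, 100 / 3, tolerance = 1e-12)
  # outcome is driven by the produced count, so it is decodable
  expect_gt(do$accuracy, 45)
})
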