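# Brute-force oracle: enumerate all runs of >= min_run consecutive
# significant bins and pick the one with the largest numerosity rate range.
window_oracle <- function(p, alpha, min_run, num_means) {
  sig <- p < alpha
  best <- NULL; best_diff <- -Inf
  i <- 1
  while (i <= length(sig)) {
    if (sig[i]) {
      j <- i
      while (j < length(sig) && sig[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) {
        m <- rowMeans(num_means[, i:j, drop = FALSE])
        d <- max(m) - min(m)
        if (d > best_diff) { best <- c(i, j); best_diff <- d }
      }
      i <- j + 1
    } else i <- i + 1
  }
  best
}

test_that("inclusion filter applies the 0.5 Hz and 5-trial rules inclusively", {
  # 100 correct trials (20 conditions x 5); inclusion interval spans
  # [-300, 1500] = 1.8 s, so 0.5 Hz needs exactly 90 spikes
  mk <- function(n_spikes) {
    trials <- expand.grid(numerosity = 1:5, format = c("dot", "sign"),
                          stim_condition = c("standard", "control"),
                          rep = 1:5, stringsAsFactors = FALSE)
    trials <- data.frame(session_id = "s01",
                         trial_id = seq_len(nrow(trials)), trials,
                         arrangement = "standard",
                         produced_count = trials$numerosity,
                         outcome = "correct", stringsAsFactors = FALSE)
    trials$rep <- NULL
    per <- rep(floor(n_spikes / nrow(trials)), nrow(trials))
    per[seq_len(n_spikes - sum(per))] <- per[seq_len(n_spikes - sum(per))] + 1
    spk <- do.call(rbind, lapply(which(per > 0), function(i)
      data.frame(neuron_id = "n001", trial_id = trials$trial_id[i],
                 time_ms = seq(0, 1400, length.out = per[i]))))
    session_dataset(trials, spk,
                    data.frame(neuron_id = "n001", session_id = "s01"),
                    meta = list(phase = list(fixation_ms = 300,
                                             instruction_ms = 500,
                                             planning_ms = 1000,
                                             execution_ms = 400),
                                provenance = list(source = "hand")))
  }
  expect_true(include_neuron(mk(90), "n001"))    # exactly 0.5 Hz
  expect_false(include_neuron(mk(85), "n001"))   # 0.47 Hz
  # missing trials in one condition
  ds <- mk(120)
  drop <- ds$trials$numerosity == 5 & ds$trials$format == "sign" &
    ds$trials$stim_condition == "control"
  ds$trials$outcome[which(drop)[1]] <- "error"
  ds$trials$produced_count[which(drop)[1]] <- 6L
  expect_false(include_neuron(ds, "n001"))
})

test_that("inclusion verdicts match a brute-force recount on random data", {
  ex <- shared_experiment(); ds <- ex$dataset
  for (nid in ds$neurons$neuron_id[1:8]) {
    tr <- ds$trials[ds$trials$outcome != "aborted", ]
    rate <- mean(vapply(tr$trial_id, function(t)
      sum(ds$spikes$time_ms[ds$spikes$neuron_id == nid &
                              ds$spikes$trial_id == t] >= -300 &
            ds$spikes$time_ms[ds$spikes$neuron_id == nid &
                                ds$spikes$trial_id == t] < 1500),
      numeric(1))) / 1.8
    cor <- tr[tr$outcome == "correct", ]
    cells <- table(cor$numerosity, cor$format, cor$stim_condition)
    verdict <- rate >= 0.5 && all(cells >= 5) && length(cells) == 20
    expect_equal(include_neuron(ds, nid), verdict)
  }
})

test_that("selective-window detection enforces the 11-bin run criterion", {
  sch <- bin_scheme(100, 1600, 200, 20)
  nm <- matrix(rep(c(1, 2, 5, 2, 1), sch$n_bins), 5)
  p <- rep(0.5, sch$n_bins)
  p[10 + (1:10)] <- 0.001    # 10 consecutive: below criterion
  expect_null(detect_selective_window(p, sch, nm))
  p[10 + (1:11)] <- 0.001    # exactly 11: qualifies
  w <- detect_selective_window(p, sch, nm)
  expect_equal(w$onset_ms, sch$starts[11])
  expect_equal(w$offset_ms, sch$starts[21] + 200)
  expect_length(w$bins, 11)
})

test_that("among multiple runs the largest rate difference wins (vs oracle)", {
  sch <- bin_scheme(100, 1600, 200, 20)
  nb <- sch$n_bins
  set.seed(123)
  for (i in 1:50) {
    p <- runif(nb)
    # plant two candidate runs of random lengths
    s1 <- sample(1:20, 1); l1 <- sample(11:15, 1)
    s2 <- sample(36:50, 1); l2 <- sample(11:15, 1)
    p[s1:(s1 + l1 - 1)] <- 0.001
    p[s2:(s2 + l2 - 1)] <- 0.001
    nm <- matrix(runif(5 * nb, 0, 10), 5)
    got <- detect_selective_window(p, sch, nm, alpha = 0.01, min_run = 11)
    want <- window_oracle(p, 0.01, 11, nm)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$bins, want[1]:want[2])
    }
  }
})

test_that("sliding ANOVA finds tuned windows and is quiet on null neurons", {
  ex <- shared_experiment(); ds <- ex$dataset; truth <- ex$truth
  sel <- shared_selectivity()
  sn <- sel$neurons
  tuned_ids <- truth$neuron_id[truth$tuned]
  # a strong majority of tuned neurons detected, untuned essentially never
  expect_gte(sum(sn$selective[sn$neuron_id %in% tuned_ids]),
             0.7 * length(tuned_ids))
  fp <- sum(sn$selective[!sn$neuron_id %in% tuned_ids])
  expect_lte(fp, 1)
  # p_number significant inside the ground-truth window of a strong neuron
  strong <- truth[truth$tuned & truth$sign == "excited" &
                    truth$code_type == "static", ][1, ]
  j <- match(strong$neuron_id, sel$scan$neuron_ids)
  sch <- sel$scheme
  inside <- sch$starts >= strong$window_onset_ms + 50 &
    (sch$starts + sch$width_ms) <= strong$window_offset_ms
  expect_gt(mean(sel$scan$p_number[j, inside] < 0.01), 0.9)
})

test_that("format-coupled neurons are not classed as exclusively number", {
  ex <- shared_experiment(); truth <- ex$truth
  sel <- shared_selectivity()
  fmt_ids <- truth$neuron_id[truth$format_coupled]
  cls <- sel$classes
  for (nid in fmt_ids) {
    got <- cls$class[cls$neuron_id == nid & cls$phase == "planning"]
    if (length(got)) expect_false(got == "exclusively_number")
  }
})

test_that("preferred value and sign follow argmax and baseline comparison", {
  ds <- hand_dataset(rate_per_num = c(2, 4, 9, 4, 2))
  ps <- preferred_and_sign(ds, "n001", c(0, 1000))
  expect_equal(ps$preferred_value, 3)
  expect_equal(unname(ps$rates), c(2, 4, 9, 4, 2))
  expect_equal(ps$sign, "excited")  # baseline is 0 Hz here
  # tie broken toward the smaller numerosity
  ds2 <- hand_dataset(rate_per_num = c(2, 9, 9, 4, 2))
  expect_equal(preferred_and_sign(ds2, "n001", c(0, 1000))$preferred_value,
               2)
  # window mean 3 Hz vs 10 Hz baseline: inhibited
  ds3 <- hand_dataset(rate_per_num = c(3, 3, 3, 3, 3),
                      fixation_spikes = 3)  # 3 per 300 ms = 10 Hz
  ps3 <- preferred_and_sign(ds3, "n001", c(0, 1000))
  expect_equal(ps3$baseline_rate, 10)
  expect_equal(ps3$sign, "inhibited")
})

test_that("preferred-numerosity recovery improves monotonically with gain", {
  # noise-free behavior: exactly 20 correct trials per numerosity x format
  cfg <- task_config(trials_per_condition = 10, weber_fraction = 0,
                     seed = 5)
  rec <- vapply(c(2, 8, 20), function(g) {
    pop <- make_population(n_neurons = 15, p_tuned = 1, p_format = 0,
                           p_inhibited = 0, gain_hz = g,
                           code_type = "static", seed = 17)
    ex <- generate_experiment(cfg, pop)
    sel <- selectivity_analysis(ex$dataset)
    m <- merge(sel$neurons[sel$neurons$selective, ],
               ex$truth[c("neuron_id", "preferred_value")],
               by = "neuron_id")
    if (nrow(m) == 0) 0 else
      sum(m$preferred_value.x == m$preferred_value.y) / 15
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_gt(rec[3], 0.8)
  expect_lt(rec[1], rec[3])
})

test_that("split-half reliability separates tuned from untuned neurons", {
  ex <- shared_experiment(); ds <- ex$dataset; truth <- ex$truth
  strong <- truth[truth$tuned & truth$sign == "excited" &
                    truth$code_type == "static", ][1, ]
  r <- split_half_reliability(ds, strong$neuron_id,
                              c(strong$window_onset_ms,
                                strong$window_offset_ms),
                              n_perm = 300, seed = 2)
  expect_gt(r$r, 0.8)
  expect_gt(r$percentile, 95)
  # identical halves give r = 1 exactly
  dsd <- hand_dataset(rate_per_num = c(2, 4, 9, 4, 2), trials_per_num = 4)
  rd <- split_half_reliability(dsd, "n001", c(0, 1000), n_perm = 50,
                               seed = 1)
  expect_equal(rd$r, 1)
  # flat neuron: flagged undefined
  dsf <- hand_dataset(rate_per_num = c(3, 3, 3, 3, 3))
  rf <- split_half_reliability(dsf, "n001", c(0, 1000), n_perm = 50,
                               seed = 1)
  expect_true(is.na(rf$r))
})

test_that("untuned neurons produce uniform reliability percentiles", {
  cfg <- task_config(trials_per_condition = 5, seed = 23)
  pop <- make_population(n_neurons = 40, p_tuned = 0, p_format = 0,
                         seed = 11)
  ex <- generate_experiment(cfg, pop)
  pct <- vapply(seq_len(40), function(j)
    split_half_reliability(ex$dataset, pop$neuron_id[j], c(500, 1500),
                           n_perm = 100, seed = j)$percentile,
    numeric(1))
  expect_gt(mean(pct, na.rm = TRUE), 30)
  expect_lt(mean(pct, na.rm = TRUE), 70)
})

test_that("normalization is idempotent and guards flat curves", {
  x <- c(2, 4, 9, 4, 2)
  nx <- normalize_curve(x)
  expect_equal(max(nx), 1); expect_equal(min(nx), 0)
  expect_equal(normalize_curve(nx), nx)
  expect_equal(normalize_curve(rep(3, 5)), rep(0.5, 5))
})

test_that("population tuning peaks at distance zero and decays", {
  ex <- shared_experiment(); ds <- ex$dataset
  sel <- shared_selectivity()
  sn <- sel$neurons[sel$neurons$selective &
                      sel$neurons$sign == "excited", ]
  expect_gte(nrow(sn), 3)
  pt <- population_tuning(ds, sn)
  d <- pt$distance
  expect_equal(unname(which.max(d)), which(names(d) == "0"))
  # monotone decay to |distance| 2 on both sides
  expect_gt(d["0"], d["1"]); expect_gt(d["1"], d["2"])
  expect_gt(d["0"], d["-1"]); expect_gt(d["-1"], d["-2"])
  # single neuron: the population curve is its own normalized curve
  one <- population_tuning(ds, sn[1, ])
  expect_equal(unname(one$by_preferred[sn$preferred_value[1], ]),
               unname(one$curves[1, ]))
})

test_that("error-trial Wilcoxon matches a brute-force signed-rank oracle", {
  x <- c(14.2, 9.8, 11.5, 16.0, 8.1)
  y <- c(12.0, 9.9, 10.1, 13.8, 8.4)
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
  d <- x - y
  r <- rank(abs(d))
  v_oracle <- sum(r[d > 0])
  expect_equal(unname(wt$statistic), v_oracle)
})

test_that("errors driven by the produced count depress preferred-value rates", {
  ex <- shared_experiment(); ds <- ex$dataset
  sel <- shared_selectivity()
  sn <- sel$neurons[sel$neurons$selective &
                      sel$neurons$sign == "excited", ]
  et <- error_trial_tuning(ds, sn, min_error_trials = 3)
  expect_gte(nrow(et$per_neuron), 4)
  expect_gt(mean(et$per_neuron$rate_correct - et$per_neuron$rate_error), 0)
  expect_lt(et$wilcoxon$p.value, 0.05)
  # erroneous production of the preferred count elevates activity relative
  # to correct production of the instructed adjacent value
  if (!is.null(et$adjacent)) {
    adj <- et$adjacent$per_neuron
    expect_gt(mean(adj$incorrect_n - adj$correct_minus1, na.rm = TRUE), 0)
  }
})
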