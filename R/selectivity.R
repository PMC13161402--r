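#' Neuron inclusion filter
#'
#' A neuron enters the tuning analyses if (a) its mean firing rate over the
#' interval from baseline onset to the end of motor planning is at least
#' `min_rate_hz` and (b) at least `min_trials` correct trials are available
#' for each of the 20 conditions (numerosity x format x stimulus
#' condition).  Both boundaries are inclusive.
#'
#' @param ds a [session_dataset()].
#' @param neuron neuron id.
#' @param min_rate_hz minimum mean rate (default 0.5 Hz).
#' @param min_trials minimum correct trials per condition (default 5).
#' @return logical.
#' @export
include_neuron <- function(ds, neuron, min_rate_hz = 0.5, min_trials = 5) {
  ph <- ds$meta$phase
  sess <- ds$neurons$session_id[match(neuron, ds$neurons$neuron_id)]
  tr <- ds$trials[ds$trials$session_id == sess &
                    ds$trials$outcome != "aborted", , drop = FALSE]
  if (nrow(tr) == 0) return(FALSE)
  win <- c(-ph$fixation_ms, ph$instruction_ms + ph$planning_ms)
  rate <- mean_rate_in_window(ds, neuron, tr$trial_id, win)
  if (rate < min_rate_hz) return(FALSE)
  cor <- tr[tr$outcome == "correct", , drop = FALSE]
  cells <- table(cor$numerosity, cor$format, cor$stim_condition)
  n_cond <- length(unique(tr$numerosity)) * length(unique(tr$format)) *
    length(unique(tr$stim_condition))
  length(cells) == n_cond && all(cells >= min_trials)
}

#' Sliding-window two-factor ANOVA selectivity scan
#'
#' For every neuron and sliding time bin, a two-factor fixed-effects ANOVA
#' of firing rate with factors numerosity (1-5) and format (dot vs sign)
#' yields p-values for the two main effects and their interaction.  The
#' canonical parameters are 200 ms windows stepped by 20 ms at significance
#' threshold 0.01; an alternative 500 ms window for coarse sample-period
#' classification is obtained by passing a different `scheme`.  Stimulus
#' condition is not a factor (its visual meaning differs across formats).
#'
#' @param binned a [bin_rates()] tensor of correct trials.
#' @param labels data.frame with columns `numerosity` and `format`, one row
#'   per trial of `binned` (same order).
#' @param alpha significance threshold stored with the result.
#' @param type sums-of-squares type for unbalanced cells (2, the default,
#'   or 1).
#' @return object of class `selectivity_scan`: `p_number`, `p_format`,
#'   `p_interaction` (neurons x bins matrices), `num_means` (list per
#'   neuron: 5 x bins matrix of per-numerosity mean rates), `scheme`,
#'   `alpha`, `neuron_ids`.
#' @export
sliding_anova <- function(binned, labels, alpha = 0.01, type = 2) {
  stopifnot(inherits(binned, "binned_rates"))
  nb <- binned$scheme$n_bins
  nn <- length(binned$neuron_ids)
  if (nrow(labels) != length(binned$trial_ids))
    stop("labels must have one row per trial of the binned tensor")
  pN <- pF <- pI <- matrix(NA_real_, nn, nb,
                           dimnames = list(binned$neuron_ids, NULL))
  num_means <- vector("list", nn)
  names(num_means) <- binned$neuron_ids
  nums <- sort(unique(labels$numerosity))
  for (j in seq_len(nn)) {
    Y <- matrix(binned$rates[j, , ], nrow = length(binned$trial_ids))
    dec <- anova2_decomposition(Y, labels$numerosity, labels$format,
                                type = type)
    pN[j, ] <- dec$p["number", ]
    pF[j, ] <- dec$p["format", ]
    pI[j, ] <- dec$p["interaction", ]
    nm <- matrix(NA_real_, length(nums), nb,
                 dimnames = list(nums, NULL))
    for (i in seq_along(nums))
      nm[i, ] <- colMeans(Y[labels$numerosity == nums[i], , drop = FALSE])
    num_means[[j]] <- nm
  }
  structure(list(p_number = pN, p_format = pF, p_interaction = pI,
                 num_means = num_means, scheme = binned$scheme,
                 alpha = alpha, neuron_ids = binned$neuron_ids),
            class = "selectivity_scan")
}

#' Maximal runs of consecutive below-threshold bins
#' @return data.frame with `from`, `to`, `length` (bin indices), possibly
#'   empty.
#' @keywords internal
#' @noRd
.sig_runs <- function(p, alpha) {
  sig <- !is.na(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(from = starts[keep], to = ends[keep], length = r$lengths[keep])
}

#' Detect a neuron's selective window
#'
#' A selective window is a run of at least `min_run` consecutive
#' significant bins (`p < alpha`).  With the default 20 ms step and 11-bin
#' minimum this enforces the canonical >= 300 ms of sustained selectivity.
#' If several runs qualify, the one with the largest firing-rate difference
#' between numerical values (max minus min of the per-numerosity mean rates
#' averaged over the run) is chosen.  The window is reported as
#' `[first bin start, last bin end]`.
#'
#' @param p_series p-value series over bins (one neuron, one factor).
#' @param scheme the [bin_scheme()] the series was computed on.
#' @param num_means optional 5 x bins matrix of per-numerosity mean rates
#'   used for the tie-break; required only when several runs qualify.
#' @param alpha significance threshold (default 0.01).
#' @param min_run minimum run length in bins (default 11).
#' @return list with `onset_ms`, `offset_ms`, `bins` (indices), `rate_diff`,
#'   or `NULL` when no window qualifies.
#' @export
detect_selective_window <- function(p_series, scheme, num_means = NULL,
                                    alpha = 0.01, min_run = 11) {
  runs <- .sig_runs(p_series, alpha)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)
  if (nrow(runs) > 1) {
    if (is.null(num_means))
      stop("num_means required to choose among multiple qualifying runs")
    diffs <- vapply(seq_len(nrow(runs)), function(i) {
      m <- rowMeans(num_means[, runs$from[i]:runs$to[i], drop = FALSE])
      max(m) - min(m)
    }, numeric(1))
    runs <- runs[which.max(diffs), , drop = FALSE]
    rd <- max(diffs)
  } else {
    rd <- if (is.null(num_means)) NA_real_ else {
      m <- rowMeans(num_means[, runs$from:runs$to, drop = FALSE])
      max(m) - min(m)
    }
  }
  bins <- runs$from:runs$to
  list(onset_ms = scheme$starts[runs$from],
       offset_ms = scheme$starts[runs$to] + scheme$width_ms,
       bins = bins, rate_diff = rd)
}

#' Classify neurons by ANOVA selectivity per trial phase
#'
#' Within each phase's analysis interval (by default instruction:
#' 100-600 ms, planning: 600-1600 ms, i.e. 100 ms response-latency offsets
#' after each phase onset), a factor counts as significant if it sustains a
#' run of at least `min_run` significant bins whose windows lie inside the
#' interval.  A neuron is exclusively number selective if numerosity is
#' significant while neither format nor the interaction is.
#'
#' @param scan a [sliding_anova()] result.
#' @param phases named list of `(lo, hi)` ms intervals.
#' @param min_run minimum run length in bins.
#' @return data.frame: `neuron_id`, `phase`, `number`, `format`,
#'   `interaction` (logicals), `class` in
#'   `{"exclusively_number", "format", "interaction", "mixed", "none"}`.
#' @export
classify_selectivity <- function(scan,
                                 phases = list(instruction = c(100, 600),
                                               planning = c(600, 1600)),
                                 min_run = 11) {
  stopifnot(inherits(scan, "selectivity_scan"))
  sch <- scan$scheme
  out <- list()
  for (ph in names(phases)) {
    iv <- phases[[ph]]
    inph <- which(sch$starts >= iv[1] &
                    (sch$starts + sch$width_ms) <= iv[2])
    if (length(inph) < min_run)
      stop("phase interval '", ph, "' holds fewer than min_run bins")
    has_run <- function(p) {
      runs <- .sig_runs(p[inph], scan$alpha)
      any(runs$length >= min_run)
    }
    for (j in seq_along(scan$neuron_ids)) {
      sN <- has_run(scan$p_number[j, ])
      sF <- has_run(scan$p_format[j, ])
      sI <- has_run(scan$p_interaction[j, ])
      cls <- if (sN && !sF && !sI) "exclusively_number"
        else if (sN) "mixed"
        else if (sF && !sI) "format"
        else if (sI) "interaction"
        else "none"
      out[[length(out) + 1]] <- data.frame(
        neuron_id = scan$neuron_ids[j], phase = ph, number = sN,
        format = sF, interaction = sI, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Preferred numerosity and response sign of a selective neuron
#'
#' The preferred numerosity is the value eliciting the highest mean firing
#' rate within the neuron's selective window (ties broken toward the
#' smaller value).  The neuron is excited if its window rate, collapsed
#' over numerosities, exceeds the fixation-period baseline, inhibited
#' otherwise.
#'
#' @param ds a [session_dataset()].
#' @param neuron neuron id.
#' @param window selective window `(onset_ms, offset_ms)`.
#' @param baseline_window fixation window; default `(-fixation_ms, 0)`.
#' @return list with `preferred_value`, `sign`, `rates` (mean rate per
#'   numerosity), `window_rate`, `baseline_rate`.
#' @export
preferred_and_sign <- function(ds, neuron, window, baseline_window = NULL) {
  if (is.null(baseline_window))
    baseline_window <- c(-ds$meta$phase$fixation_ms, 0)
  sess <- ds$neurons$session_id[match(neuron, ds$neurons$neuron_id)]
  tr <- ds$trials[ds$trials$session_id == sess &
                    ds$trials$outcome == "correct", , drop = FALSE]
  nums <- sort(unique(tr$numerosity))
  rates <- vapply(nums, function(n)
    mean_rate_in_window(ds, neuron, tr$trial_id[tr$numerosity == n],
                        window), numeric(1))
  names(rates) <- nums
  pref <- nums[which.max(rates)]  # which.max returns first max: smaller n
  wrate <- mean_rate_in_window(ds, neuron, tr$trial_id, window)
  brate <- mean_rate_in_window(ds, neuron, tr$trial_id, baseline_window)
  list(preferred_value = pref,
       sign = if (wrate >= brate) "excited" else "inhibited",
       rates = rates, window_rate = wrate, baseline_rate = brate)
}

#' Min-max normalize a tuning curve
#'
#' Maps a curve to `[0, 1]` by its minimum and maximum.  Flat curves (range
#' below `eps`) are mapped to a constant 0.5 rather than dividing by zero.
#' Normalization is idempotent.
#'
#' @param x numeric vector.
#' @param eps flatness guard.
#' @return normalized vector.
#' @export
normalize_curve <- function(x, eps = 1e-12) {
  r <- max(x) - min(x)
  if (!is.finite(r) || r < eps) return(rep(0.5, length(x)))
  (x - min(x)) / r
}

#' Split-half cross-validation of a tuning curve
#'
#' Correct trials are split into two balanced halves (stratified by
#' numerosity x format); a tuning curve is computed from each half and
#' their similarity quantified by the Pearson correlation of the two
#' five-point curves.  Significance comes from a label-permutation null:
#' numerosity labels are shuffled, pseudo-tuning curves recomputed, and the
#' percentile of the observed correlation within `n_perm` permuted
#' correlations is reported as the reliability.
#'
#' @param ds a [session_dataset()].
#' @param neuron neuron id.
#' @param window selective window `(onset_ms, offset_ms)`.
#' @param n_perm number of label permutations (canonically 10000).
#' @param seed RNG seed.
#' @return list with `r`, `percentile` (0-100), `curve_a`, `curve_b`
#'   (normalized), `n_perm`. `r` is NA (flagged) if either half-curve has
#'   zero variance.
#' @export
split_half_reliability <- function(ds, neuron, window, n_perm = 1000,
                                   seed = 1L) {
  sess <- ds$neurons$session_id[match(neuron, ds$neurons$neuron_id)]
  tr <- ds$trials[ds$trials$session_id == sess &
                    ds$trials$outcome == "correct", , drop = FALSE]
  nums <- sort(unique(tr$numerosity))
  rate <- mean_rate_in_window(ds, neuron, tr$trial_id, window,
                              per_trial = TRUE)
  stratum <- paste(tr$numerosity, tr$format)
  with_seed(mix_seed(seed, 31L), {
    half <- rep(NA, nrow(tr))
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      if (length(idx) < 2) stop("need >= 2 trials per stratum to split")
      pick <- sample(idx, floor(length(idx) / 2))
      half[pick] <- 1L
      half[setdiff(idx, pick)] <- 2L
    }
    curve <- function(r, labels, h) {
      vapply(nums, function(n) mean(r[labels == n & half == h]), numeric(1))
    }
    ca <- curve(rate, tr$numerosity, 1L)
    cb <- curve(rate, tr$numerosity, 2L)
    if (stats::sd(ca) == 0 || stats::sd(cb) == 0)
      return(list(r = NA_real_, percentile = NA_real_,
                  curve_a = normalize_curve(ca),
                  curve_b = normalize_curve(cb), n_perm = n_perm))
    r_obs <- stats::cor(ca, cb)
    null <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      perm <- sample(tr$numerosity)
      pa <- curve(rate, perm, 1L)
      pb <- curve(rate, perm, 2L)
        # a permutation can leave a (label, half) cell empty; score it 0
      null[i] <- if (anyNA(pa) || anyNA(pb) ||
                       stats::sd(pa) == 0 || stats::sd(pb) == 0) 0
                 else stats::cor(pa, pb)
    }
    list(r = r_obs, percentile = 100 * mean(null < r_obs),
         curve_a = normalize_curve(ca), curve_b = normalize_curve(cb),
         n_perm = n_perm)
  })
}

#' Full selectivity analysis of a dataset
#'
#' Applies the inclusion filter, runs the sliding ANOVA on correct trials,
#' detects selective windows, and determines preferred numerosity and
#' response sign for every exclusively number-selective neuron.
#'
#' @param ds a [session_dataset()].
#' @param scheme analysis [bin_scheme()]; default 200/20 ms bins from 100 ms
#'   after instruction onset to 100 ms into execution.
#' @param alpha,min_run run criterion.
#' @return list of class `selectivity_result`: `scan`, `classes` (from
#'   [classify_selectivity()]), `neurons` data.frame (neuron_id, included,
#'   selective, onset/offset, preferred_value, sign).
#' @export
selectivity_analysis <- function(ds, scheme = NULL, alpha = 0.01,
                                 min_run = 11) {
  ph <- ds$meta$phase
  if (is.null(scheme))
    scheme <- bin_scheme(100, ph$instruction_ms + ph$planning_ms + 100,
                         width_ms = 200, step_ms = 20)
  ids <- ds$neurons$neuron_id
  included <- vapply(ids, function(nid) include_neuron(ds, nid), logical(1))
  res <- data.frame(neuron_id = ids, included = included,
                    selective = FALSE, onset_ms = NA_real_,
                    offset_ms = NA_real_, preferred_value = NA_integer_,
                    sign = NA_character_, stringsAsFactors = FALSE)
  inc_ids <- ids[included]
  scan <- NULL
  classes <- NULL
  if (length(inc_ids)) {
    sessions <- unique(ds$neurons$session_id[match(inc_ids,
                                                   ds$neurons$neuron_id)])
    scans <- list()
    for (s in sessions) {
      nid_s <- inc_ids[ds$neurons$session_id[match(inc_ids,
                                             ds$neurons$neuron_id)] == s]
      tr <- ds$trials[ds$trials$session_id == s &
                        ds$trials$outcome == "correct", , drop = FALSE]
      binned <- bin_rates(ds, scheme, neurons = nid_s,
                          trials = tr$trial_id)
      scans[[s]] <- sliding_anova(binned,
                                  tr[c("numerosity", "format")],
                                  alpha = alpha)
    }
    scan <- .merge_scans(scans)
    classes <- classify_selectivity(scan, min_run = min_run)
    for (j in seq_along(scan$neuron_ids)) {
      nid <- scan$neuron_ids[j]
      win <- detect_selective_window(scan$p_number[j, ], scheme,
                                     num_means = scan$num_means[[j]],
                                     alpha = alpha, min_run = min_run)
      # exclusively number selective: a qualifying numerosity run anywhere
      # in the analysis interval, with no format or interaction run
      has_run <- function(p) any(.sig_runs(p, alpha)$length >= min_run)
      excl <- !has_run(scan$p_format[j, ]) &&
        !has_run(scan$p_interaction[j, ])
      if (!is.null(win) && excl) {
        k <- match(nid, res$neuron_id)
        ps <- preferred_and_sign(ds, nid, c(win$onset_ms, win$offset_ms))
        res$selective[k] <- TRUE
        res$onset_ms[k] <- win$onset_ms
        res$offset_ms[k] <- win$offset_ms
        res$preferred_value[k] <- ps$preferred_value
        res$sign[k] <- ps$sign
      }
    }
  }
  structure(list(scan = scan, classes = classes, neurons = res,
                 scheme = scheme, alpha = alpha, min_run = min_run),
            class = "selectivity_result")
}

.merge_scans <- function(scans) {
  if (length(scans) == 1) return(scans[[1]])
  s1 <- scans[[1]]
  s1$p_number <- do.call(rbind, lapply(scans, `[[`, "p_number"))
  s1$p_format <- do.call(rbind, lapply(scans, `[[`, "p_format"))
  s1$p_interaction <- do.call(rbind, lapply(scans, `[[`, "p_interaction"))
  s1$num_means <- do.call(c, lapply(scans, `[[`, "num_means"))
  s1$neuron_ids <- unlist(lapply(scans, `[[`, "neuron_ids"),
                          use.names = FALSE)
  s1
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("selectivity_result:", nrow(x$neurons), "neurons,",
      sum(x$neurons$included), "included,",
      sum(x$neurons$selective), "exclusively number-selective\n")
  invisible(x)
}

#' Population tuning curves of selective neurons
#'
#' Each neuron's tuning curve (mean rate per numerosity in its selective
#' window) is min-max normalized and averaged across neurons grouped by
#' preferred numerosity; a distance-aligned average (preferred value at
#' distance 0) pools all selective neurons.
#'
#' @param ds a [session_dataset()].
#' @param neurons data.frame with `neuron_id`, `onset_ms`, `offset_ms`,
#'   `preferred_value` for the selective neurons (e.g. the selective subset
#'   of [selectivity_analysis()]`$neurons`).
#' @return list: `by_preferred` (5 x 5 matrix, rows = preferred value,
#'   normalized mean curve; NA rows when no neuron prefers that value),
#'   `n_by_preferred`, `distance` (named vector over distances -4..4),
#'   `curves` (neurons x 5 matrix of normalized curves).
#' @export
population_tuning <- function(ds, neurons) {
  nums <- 1:5
  curves <- matrix(NA_real_, nrow(neurons), 5,
                   dimnames = list(neurons$neuron_id, nums))
  for (i in seq_len(nrow(neurons))) {
    ps <- preferred_and_sign(ds, neurons$neuron_id[i],
                             c(neurons$onset_ms[i], neurons$offset_ms[i]))
    curves[i, ] <- normalize_curve(ps$rates[as.character(nums)])
  }
  by_pref <- matrix(NA_real_, 5, 5, dimnames = list(nums, nums))
  n_by <- integer(5)
  for (p in nums) {
    sel <- which(neurons$preferred_value == p)
    n_by[p] <- length(sel)
    if (length(sel))
      by_pref[p, ] <- colMeans(curves[sel, , drop = FALSE])
  }
  dist_vals <- -4:4
  dsum <- dcnt <- stats::setNames(numeric(9), dist_vals)
  for (i in seq_len(nrow(neurons))) {
    p <- neurons$preferred_value[i]
    for (n in nums) {
      d <- as.character(n - p)
      dsum[d] <- dsum[d] + curves[i, n]
      dcnt[d] <- dcnt[d] + 1
    }
  }
  distance <- ifelse(dcnt > 0, dsum / dcnt, NA_real_)
  list(by_preferred = by_pref, n_by_preferred = n_by,
       distance = distance, curves = curves)
}

#' Correct-versus-error tuning analysis
#'
#' Tests whether planning activity predicts the produced rather than the
#' instructed count.  For every selective neuron with at least
#' `min_error_trials` error trials, the firing rate at the preferred
#' numerosity is compared between correct and error trials (paired Wilcoxon
#' signed-rank across neurons).  A second contrast uses neurons preferring
#' 2-4: trials where the preferred value `n` was erroneously produced when
#' `n - 1` or `n + 1` was instructed are compared against correct trials of
#' the instructed value.
#'
#' @param ds a [session_dataset()].
#' @param neurons selective-neuron table (`neuron_id`, `onset_ms`,
#'   `offset_ms`, `preferred_value`).
#' @param min_error_trials minimum error trials at the preferred value
#'   (default 3).
#' @return list of class `error_tuning`: `per_neuron` (rates correct/error
#'   at preferred value), `wilcoxon` (htest or NULL), `n_excluded`,
#'   `adjacent` (the n-vs-n+/-1 contrast: per-neuron normalized activities
#'   and Wilcoxon tests for the n-1 and n+1 directions).
#' @export
error_trial_tuning <- function(ds, neurons, min_error_trials = 3) {
  rows <- list(); excl <- 0L
  for (i in seq_len(nrow(neurons))) {
    nid <- neurons$neuron_id[i]
    p <- neurons$preferred_value[i]
    win <- c(neurons$onset_ms[i], neurons$offset_ms[i])
    sess <- ds$neurons$session_id[match(nid, ds$neurons$neuron_id)]
    tr <- ds$trials[ds$trials$session_id == sess, , drop = FALSE]
    cor_t <- tr$trial_id[tr$outcome == "correct" & tr$numerosity == p]
    err_t <- tr$trial_id[tr$outcome == "error" & tr$numerosity == p]
    if (length(err_t) < min_error_trials) { excl <- excl + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      neuron_id = nid, preferred_value = p,
      rate_correct = mean_rate_in_window(ds, nid, cor_t, win),
      rate_error = mean_rate_in_window(ds, nid, err_t, win),
      n_error = length(err_t), stringsAsFactors = FALSE)
  }
  per_neuron <- if (length(rows)) do.call(rbind, rows) else NULL
  wt <- NULL
  if (!is.null(per_neuron) && nrow(per_neuron) >= 2) {
    d <- per_neuron$rate_correct - per_neuron$rate_error
    wt <- if (all(d == 0)) NULL else
      stats::wilcox.test(per_neuron$rate_correct, per_neuron$rate_error,
                         paired = TRUE, exact = FALSE)
  }

  # n vs n+/-1: preferred value produced erroneously
  adj_rows <- list()
  for (i in seq_len(nrow(neurons))) {
    p <- neurons$preferred_value[i]
    if (!(p %in% 2:4)) next
    nid <- neurons$neuron_id[i]
    win <- c(neurons$onset_ms[i], neurons$offset_ms[i])
    sess <- ds$neurons$session_id[match(nid, ds$neurons$neuron_id)]
    tr <- ds$trials[ds$trials$session_id == sess, , drop = FALSE]
    err_n <- tr$trial_id[tr$outcome == "error" &
                           !is.na(tr$produced_count) &
                           tr$produced_count == p &
                           tr$numerosity %in% c(p - 1, p + 1)]
    if (length(err_n) < min_error_trials) next
    cor_all <- tr$trial_id[tr$outcome == "correct"]
    ref <- mean_rate_in_window(ds, nid, cor_all, win)
    if (ref <= 0) next
    grab <- function(ids) if (length(ids))
      100 * mean_rate_in_window(ds, nid, ids, win) / ref else NA_real_
    adj_rows[[length(adj_rows) + 1]] <- data.frame(
      neuron_id = nid, preferred_value = p,
      incorrect_n = grab(err_n),
      correct_minus1 = grab(tr$trial_id[tr$outcome == "correct" &
                                          tr$numerosity == p - 1]),
      correct_plus1 = grab(tr$trial_id[tr$outcome == "correct" &
                                         tr$numerosity == p + 1]),
      stringsAsFactors = FALSE)
  }
  adjacent <- NULL
  if (length(adj_rows)) {
    adj <- do.call(rbind, adj_rows)
    test_pair <- function(a, b) {
      ok <- stats::complete.cases(a, b)
      if (sum(ok) >= 2 && any(a[ok] != b[ok]))
        stats::wilcox.test(a[ok], b[ok], paired = TRUE, exact = FALSE)
      else NULL
    }
    adjacent <- list(per_neuron = adj,
                     minus1 = test_pair(adj$incorrect_n, adj$correct_minus1),
                     plus1 = test_pair(adj$incorrect_n, adj$correct_plus1))
  }
  structure(list(per_neuron = per_neuron, wilcoxon = wt, n_excluded = excl,
                 adjacent = adjacent), class = "error_tuning")
}
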