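# Resampled linear SVM population decoding.
#
# The classifier itself is libsvm's linear one-vs-one multiclass machine
# (via e1071); everything around it -- pseudopopulation construction,
# stratified folding, leak-free z-scoring, confusion aggregation and
# shuffle nulls -- is implemented here.

#' Decoding protocol parameters
#'
#' @param trials_per_class pseudotrials sampled per class per neuron
#'   (canonically 20; must be divisible by `folds`).
#' @param folds cross-validation folds (canonically 10).
#' @param resamples number of random resamples (canonically 1000).
#' @param z_score `"fold"` (default): z-scoring uses training-fold mean/SD
#'   applied to test trials (leak-free). `"pooled"`: the sampled feature
#'   matrix is z-scored once before cross-validation, the literal order of
#'   the classical recipe, kept for comparison.
#' @param cost regularization strength of the linear SVM (default 1).
#' @param seed RNG seed for all sampling in the protocol.
#' @return object of class `decoding_protocol`.
#' @export
decoding_protocol <- function(trials_per_class = 20L, folds = 10L,
                              resamples = 1000L,
                              z_score = c("fold", "pooled"),
                              cost = 1, seed = 1L) {
  z_score <- match.arg(z_score)
  if (trials_per_class %% folds != 0)
    stop("trials_per_class must be divisible by folds")
  if (resamples < 1) stop("resamples must be >= 1")
  structure(list(trials_per_class = as.integer(trials_per_class),
                 folds = as.integer(folds),
                 resamples = as.integer(resamples),
                 z_score = z_score, cost = cost, seed = as.integer(seed)),
            class = "decoding_protocol")
}

#' z-score columns by training statistics; drop zero-variance features
#' @return list(train, tests = list of transformed test matrices, dropped)
#' @keywords internal
#' @noRd
.zscore_by_train <- function(train, tests) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  keep <- sd > 0
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sd[keep], "/")
  te <- lapply(tests, function(x)
    sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/"))
  list(train = tr, tests = te, dropped = sum(!keep))
}

#' @keywords internal
#' @noRd
.svm_fit <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
}

#' Stratified fold assignment: one fold id per row of y
#' @keywords internal
#' @noRd
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Decode class labels from a feature matrix
#'
#' Runs `resamples` repetitions of stratified k-fold cross-validation of a
#' linear one-vs-one multiclass SVM and aggregates a row-normalized
#' confusion matrix (rows = true label, columns = predicted; entries are
#' empirical classification frequencies).  Overall accuracy is the mean of
#' the diagonal.  With `shuffle = TRUE` the class labels are permuted
#' independently in every resample, which yields the chance-level null
#' distribution under the identical protocol.
#'
#' @param features numeric matrix, pseudotrials x neurons.
#' @param labels class labels (coerced to factor); classes must be
#'   balanced and class size divisible by `protocol$folds`.
#' @param protocol a [decoding_protocol()].
#' @param shuffle permute labels per resample (shuffle null).
#' @param seed_tag integer folded into the seed so observed and null runs
#'   use distinct substreams.
#' @return object of class `decoding_result`: `confusion`, `accuracy`,
#'   `sem`, `per_class`, `acc_resamples`, `n_resamples`, `chance`.
#' @export
decode <- function(features, labels, protocol = decoding_protocol(),
                   shuffle = FALSE, seed_tag = 0L) {
  y <- factor(labels)
  K <- nlevels(y)
  sizes <- table(y)
  if (length(unique(sizes)) != 1)
    stop("decode() requires balanced classes")
  if (sizes[1] %% protocol$folds != 0)
    stop("class size must be divisible by the number of folds")
  x <- as.matrix(features)
  conf <- matrix(0, K, K, dimnames = list(levels(y), levels(y)))
  accs <- numeric(protocol$resamples)
  with_seed(mix_seed(protocol$seed, 41L, seed_tag, shuffle), {
    for (r in seq_len(protocol$resamples)) {
      yr <- if (shuffle) sample(y) else y
      xr <- x
      if (protocol$z_score == "pooled") {
        sdv <- apply(xr, 2, stats::sd)
        keep <- sdv > 0
        xr <- scale(xr[, keep, drop = FALSE])
      }
      fold <- .stratified_folds(yr, protocol$folds)
      ok <- 0L; tot <- 0L
      for (f in seq_len(protocol$folds)) {
        tr <- fold != f
        xtr <- xr[tr, , drop = FALSE]; ytr <- droplevels(yr[tr])
        xte <- xr[!tr, , drop = FALSE]
        if (protocol$z_score == "fold") {
          z <- .zscore_by_train(xtr, list(xte))
          xtr <- z$train; xte <- z$tests[[1]]
        }
        pred <- predict(.svm_fit(xtr, ytr, protocol$cost), xte)
        truth <- yr[!tr]
        for (i in seq_along(pred))
          conf[as.integer(truth[i]), as.integer(factor(pred[i],
            levels = levels(y)))] <-
            conf[as.integer(truth[i]), as.integer(factor(pred[i],
              levels = levels(y)))] + 1
        ok <- ok + sum(pred == truth); tot <- tot + length(pred)
      }
      accs[r] <- 100 * ok / tot
    }
  })
  conf <- conf / rowSums(conf)
  structure(list(confusion = conf, accuracy = mean(accs),
                 sem = stats::sd(accs) / sqrt(length(accs)),
                 per_class = 100 * diag(conf), acc_resamples = accs,
                 n_resamples = protocol$resamples, chance = 100 / K),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result: accuracy %.1f +/- %.1f%% (chance %.1f%%, %d resamples)\n",
              x$accuracy, x$sem, x$chance, x$n_resamples))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, main = "confusion matrix", ...) {
  K <- nrow(x$confusion)
  graphics::image(1:K, 1:K, t(x$confusion[K:1, , drop = FALSE]),
                  xlab = "predicted", ylab = "instructed", axes = FALSE,
                  main = main, col = grDevices::hcl.colors(64, "YlOrRd",
                                                           rev = TRUE), ...)
  graphics::axis(1, 1:K, colnames(x$confusion))
  graphics::axis(2, 1:K, rev(rownames(x$confusion)))
  invisible(x)
}

#' Neurons eligible for a decoding analysis
#'
#' @param ds a [session_dataset()].
#' @param min_per_class minimum correct trials per numerosity.
#' @param by_format additionally require the minimum per format.
#' @param outcome trial outcomes counted (default `"correct"`).
#' @return character vector of neuron ids.
#' @export
eligible_neurons <- function(ds, min_per_class = 20, by_format = FALSE,
                             outcome = "correct") {
  tr <- ds$trials[ds$trials$outcome %in% outcome, , drop = FALSE]
  ok <- vapply(seq_len(nrow(ds$neurons)), function(i) {
    trs <- tr[tr$session_id == ds$neurons$session_id[i], , drop = FALSE]
    if (by_format) {
      tab <- table(trs$numerosity, trs$format)
      nrow(tab) == 5 && ncol(tab) == 2 && all(tab >= min_per_class)
    } else {
      tab <- table(trs$numerosity)
      length(tab) == 5 && all(tab >= min_per_class)
    }
  }, logical(1))
  ds$neurons$neuron_id[ok]
}

#' Per-neuron trial indices by class
#' @keywords internal
#' @noRd
.class_trial_index <- function(ds, neurons, trial_pool, class_of) {
  # trial_pool: data.frame of trials (rows define candidate pseudotrials)
  # class_of: factor over trial_pool rows
  lapply(neurons, function(nid) {
    sess <- ds$neurons$session_id[match(nid, ds$neurons$neuron_id)]
    lapply(split(seq_len(nrow(trial_pool)),
                 class_of), function(ix)
      ix[trial_pool$session_id[ix] == sess])
  })
}

#' Build a pseudopopulation feature matrix
#'
#' Samples `trials_per_class` trials per class without replacement for
#' every neuron and conjoins them across neurons by (class, draw index):
#' the i-th pseudotrial of class c concatenates each neuron's i-th sampled
#' trial of class c.  Neurons recorded in different sessions are thereby
#' combined into label-aligned pseudotrials.  Features are mean firing
#' rates in `window`.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids; each must have at least `trials_per_class`
#'   correct trials per class (others are dropped with a message).
#' @param window feature window `(lo, hi)` ms.
#' @param trials_per_class pseudotrials per class.
#' @param label_col class label column of the trial table (default
#'   `"numerosity"`).
#' @param seed RNG seed.
#' @return list with `x` (matrix `K*trials_per_class` x neurons), `y`
#'   (factor), `trial_ids` (array class-draw x neuron of sampled trial
#'   ids), `neurons`.
#' @export
build_pseudopopulation <- function(ds, neurons, window,
                                   trials_per_class = 20,
                                   label_col = "numerosity", seed = 1L) {
  tr <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  cls <- factor(tr[[label_col]])
  R <- .window_rates(ds, neurons, tr$trial_id, window)
  idx <- .class_trial_index(ds, neurons, tr, cls)
  enough <- vapply(idx, function(l)
    all(vapply(l, length, integer(1)) >= trials_per_class), logical(1))
  if (!all(enough)) {
    message(sum(!enough), " neuron(s) dropped: fewer than ",
            trials_per_class, " correct trials in some class")
    neurons <- neurons[enough]; idx <- idx[enough]
    R <- R[enough, , drop = FALSE]
  }
  if (length(neurons) == 0) stop("no eligible neurons")
  K <- nlevels(cls)
  with_seed(mix_seed(seed, 43L), {
    picks <- array(NA_integer_, c(K * trials_per_class, length(neurons)))
    for (j in seq_along(neurons))
      for (k in seq_len(K))
        picks[(k - 1) * trials_per_class + seq_len(trials_per_class), j] <-
          sample(idx[[j]][[k]], trials_per_class)
    x <- matrix(0, K * trials_per_class, length(neurons),
                dimnames = list(NULL, neurons))
    for (j in seq_along(neurons)) x[, j] <- R[j, picks[, j]]
    y <- factor(rep(levels(cls), each = trials_per_class),
                levels = levels(cls))
    trial_ids <- picks
    trial_ids[] <- tr$trial_id[picks]
    list(x = x, y = y, trial_ids = trial_ids, neurons = neurons)
  })
}

#' Decode the planned numerosity from population activity
#'
#' The standard within-condition protocol: in every resample a fresh
#' pseudopopulation (`trials_per_class` trials per numerosity per neuron)
#' is drawn, z-scored, and classified by stratified k-fold cross-validation
#' with a linear one-vs-one SVM; the shuffle null repeats the identical
#' procedure on permuted labels.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids (default: all with enough trials).
#' @param window feature window; default the motor planning period.
#' @param protocol a [decoding_protocol()].
#' @param n_null number of shuffle-null resamples (0 to skip).
#' @return a `decoding_result` with additional elements `null_acc`
#'   (per-null-resample accuracies), `null_mean`, `null_p95`.
#' @export
decode_numerosity <- function(ds, neurons = NULL, window = NULL,
                              protocol = decoding_protocol(),
                              n_null = 0L) {
  ph <- ds$meta$phase
  if (is.null(window))
    window <- c(ph$instruction_ms + 100,
                ph$instruction_ms + ph$planning_ms)
  if (is.null(neurons))
    neurons <- eligible_neurons(ds, protocol$trials_per_class)
  if (length(neurons) == 0) stop("no eligible neurons")
  run <- function(shuffle, n_rep, tag) {
    conf <- NULL; accs <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      pp <- build_pseudopopulation(ds, neurons, window,
                                   protocol$trials_per_class,
                                   seed = mix_seed(protocol$seed, tag, r))
      p1 <- protocol; p1$resamples <- 1L
      p1$seed <- mix_seed(protocol$seed, tag + 1L, r)
      d <- decode(pp$x, pp$y, p1, shuffle = shuffle)
      accs[r] <- d$accuracy
      conf <- if (is.null(conf)) d$confusion else conf + d$confusion
    }
    list(conf = conf / n_rep, accs = accs)
  }
  obs <- run(FALSE, protocol$resamples, 50L)
  res <- structure(list(confusion = obs$conf, accuracy = mean(obs$accs),
                        sem = stats::sd(obs$accs) / sqrt(length(obs$accs)),
                        per_class = 100 * diag(obs$conf),
                        acc_resamples = obs$accs,
                        n_resamples = protocol$resamples,
                        chance = 100 / nlevels(factor(ds$trials$numerosity)),
                        neurons = neurons, window = window),
                   class = "decoding_result")
  if (n_null > 0) {
    nul <- run(TRUE, n_null, 60L)
    res$null_acc <- nul$accs
    res$null_mean <- mean(nul$accs)
    res$null_p95 <- unname(stats::quantile(nul$accs, 0.95))
  }
  res
}

#' Within- and across-format decoding
#'
#' Tests whether the numerosity code generalizes across the two instruction
#' formats: classifiers are trained on pseudotrials of one format and
#' tested on held-out pseudotrials of the same format (within) or of the
#' other format (across).  All four combinations share one neuron set
#' (at least `trials_per_class` correct trials per numerosity per format).
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids (default: eligible set).
#' @param window feature window; default the motor planning period.
#' @param protocol a [decoding_protocol()]; canonical `trials_per_class`
#'   here is 10 with 10 folds (train on 9, test on 1 per class).
#' @param n_null shuffle-null resamples per combination (0 to skip).
#' @return list of class `cross_format_result` with elements
#'   `within_dot`, `within_sign`, `dot_to_sign`, `sign_to_dot`, each a list
#'   with `accuracy`, `sem`, `acc_resamples` (+ `null_mean`, `null_p95`
#'   when requested), plus `neurons`.
#' @export
decode_cross_format <- function(ds, neurons = NULL, window = NULL,
                                protocol = decoding_protocol(
                                  trials_per_class = 10L),
                                n_null = 0L) {
  ph <- ds$meta$phase
  if (is.null(window))
    window <- c(ph$instruction_ms + 100,
                ph$instruction_ms + ph$planning_ms)
  if (is.null(neurons))
    neurons <- eligible_neurons(ds, protocol$trials_per_class,
                                by_format = TRUE)
  if (length(neurons) == 0) stop("no eligible neurons")
  tr <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  cls <- factor(paste(tr$format, tr$numerosity))
  R <- .window_rates(ds, neurons, tr$trial_id, window)
  idx <- .class_trial_index(ds, neurons, tr, cls)
  tpc <- protocol$trials_per_class
  combos <- c("within_dot", "within_sign", "dot_to_sign", "sign_to_dot")

  run <- function(shuffle, n_rep, tag) {
    acc <- matrix(0, n_rep, 4, dimnames = list(NULL, combos))
    with_seed(mix_seed(protocol$seed, tag), {
      for (r in seq_len(n_rep)) {
        # sample tpc trials per (format, numerosity) per neuron
        feats <- list()
        for (fmt in c("dot", "sign")) {
          x <- matrix(0, 5 * tpc, length(neurons))
          for (j in seq_along(neurons)) {
            for (k in 1:5) {
              ix <- idx[[j]][[paste(fmt, k)]]
              rows <- (k - 1) * tpc + seq_len(tpc)
              x[rows, j] <- R[j, sample(ix, tpc)]
            }
          }
          feats[[fmt]] <- x
        }
        y <- factor(rep(1:5, each = tpc))
        if (shuffle) y <- sample(y)
        draw <- rep(seq_len(tpc), times = 5)
        fold_of_draw <- sample(rep_len(seq_len(protocol$folds), tpc))
        hits <- matrix(0, protocol$folds, 4); ntest <- 0
        for (f in seq_len(protocol$folds)) {
          te <- fold_of_draw[draw] == f
          for (tf in c("dot", "sign")) {
            xtr <- feats[[tf]][!te, , drop = FALSE]
            z <- .zscore_by_train(xtr, list(feats[[tf]][te, , drop = FALSE],
              feats[[setdiff(c("dot", "sign"), tf)]][te, , drop = FALSE]))
            m <- .svm_fit(z$train, y[!te], protocol$cost)
            pw <- predict(m, z$tests[[1]])
            px <- predict(m, z$tests[[2]])
            wi <- if (tf == "dot") "within_dot" else "within_sign"
            xi <- if (tf == "dot") "dot_to_sign" else "sign_to_dot"
            hits[f, match(wi, combos)] <- mean(pw == y[te])
            hits[f, match(xi, combos)] <- mean(px == y[te])
          }
        }
        acc[r, ] <- 100 * colMeans(hits)
      }
    })
    acc
  }
  obs <- run(FALSE, protocol$resamples, 70L)
  out <- lapply(combos, function(cb) {
    list(accuracy = mean(obs[, cb]),
         sem = stats::sd(obs[, cb]) / sqrt(nrow(obs)),
         acc_resamples = obs[, cb])
  })
  names(out) <- combos
  if (n_null > 0) {
    nul <- run(TRUE, n_null, 80L)
    for (cb in combos) {
      out[[cb]]$null_mean <- mean(nul[, cb])
      out[[cb]]$null_p95 <- unname(stats::quantile(nul[, cb], 0.95))
    }
  }
  out$neurons <- neurons
  class(out) <- "cross_format_result"
  out
}

#' Within- and across-phase decoding
#'
#' Probes whether the numerosity code carries over from the sensory
#' instruction phase to motor planning: classifiers are trained on one
#' phase's window and tested on held-out trials of the same or the other
#' phase.  The two analysis windows are non-overlapping by construction
#' (instruction: 300 ms starting 250 ms after instruction onset; planning:
#' 900 ms starting 700 ms after instruction onset).
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids; canonically the neurons selective to
#'   numerosity in either phase with at least 20 trials per class.
#' @param protocol a [decoding_protocol()] (canonically 20 trials per
#'   class, 10 folds: 18 train / 2 test).
#' @param windows named list with `instruction` and `planning` windows.
#' @param n_null shuffle-null resamples for the 95% confidence thresholds.
#' @return list of class `cross_phase_result`: `accuracy` (named vector:
#'   train_instruction_test_instruction, train_instruction_test_planning,
#'   train_planning_test_planning, train_planning_test_instruction), `sem`,
#'   `null_p95` (same names, when requested), `acc_resamples`, `neurons`,
#'   `windows`.
#' @export
decode_cross_phase <- function(ds, neurons = NULL,
                               protocol = decoding_protocol(),
                               windows = list(instruction = c(250, 550),
                                              planning = c(700, 1600)),
                               n_null = 0L) {
  if (is.null(neurons))
    neurons <- eligible_neurons(ds, protocol$trials_per_class)
  if (length(neurons) == 0) stop("no eligible neurons")
  if (!(windows$instruction[2] <= windows$planning[1] ||
          windows$planning[2] <= windows$instruction[1]))
    stop("the instruction and planning analysis windows must not overlap")
  tr <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  cls <- factor(tr$numerosity)
  RA <- .window_rates(ds, neurons, tr$trial_id, windows$instruction)
  RB <- .window_rates(ds, neurons, tr$trial_id, windows$planning)
  idx <- .class_trial_index(ds, neurons, tr, cls)
  tpc <- protocol$trials_per_class
  keys <- c("train_instruction_test_instruction",
            "train_instruction_test_planning",
            "train_planning_test_planning",
            "train_planning_test_instruction")

  run <- function(shuffle, n_rep, tag) {
    acc <- matrix(0, n_rep, 4, dimnames = list(NULL, keys))
    with_seed(mix_seed(protocol$seed, tag), {
      for (r in seq_len(n_rep)) {
        picks <- matrix(0L, 5 * tpc, length(neurons))
        for (j in seq_along(neurons))
          for (k in 1:5)
            picks[(k - 1) * tpc + seq_len(tpc), j] <-
              sample(idx[[j]][[k]], tpc)
        xA <- xB <- matrix(0, 5 * tpc, length(neurons))
        for (j in seq_along(neurons)) {
          xA[, j] <- RA[j, picks[, j]]
          xB[, j] <- RB[j, picks[, j]]
        }
        y <- factor(rep(1:5, each = tpc))
        if (shuffle) y <- sample(y)
        draw <- rep(seq_len(tpc), times = 5)
        fold_of_draw <- sample(rep_len(seq_len(protocol$folds), tpc))
        hits <- matrix(0, protocol$folds, 4)
        for (f in seq_len(protocol$folds)) {
          te <- fold_of_draw[draw] == f
          zA <- .zscore_by_train(xA[!te, , drop = FALSE],
                                 list(xA[te, , drop = FALSE]))
          zB <- .zscore_by_train(xB[!te, , drop = FALSE],
                                 list(xB[te, , drop = FALSE]))
          mA <- .svm_fit(zA$train, y[!te], protocol$cost)
          mB <- .svm_fit(zB$train, y[!te], protocol$cost)
          hits[f, 1] <- mean(predict(mA, zA$tests[[1]]) == y[te])
          hits[f, 2] <- mean(predict(mA, zB$tests[[1]]) == y[te])
          hits[f, 3] <- mean(predict(mB, zB$tests[[1]]) == y[te])
          hits[f, 4] <- mean(predict(mB, zA$tests[[1]]) == y[te])
        }
        acc[r, ] <- 100 * colMeans(hits)
      }
    })
    acc
  }
  obs <- run(FALSE, protocol$resamples, 90L)
  res <- list(accuracy = colMeans(obs),
              sem = apply(obs, 2, stats::sd) / sqrt(nrow(obs)),
              acc_resamples = obs, neurons = neurons, windows = windows,
              chance = 20)
  if (n_null > 0) {
    nul <- run(TRUE, n_null, 95L)
    res$null_p95 <- apply(nul, 2, stats::quantile, 0.95)
    res$null_mean <- colMeans(nul)
  }
  class(res) <- "cross_phase_result"
  res
}

#' Decoding accuracy on correct versus error test trials
#'
#' Classifiers are trained exclusively on correct trials (9 per class per
#' fold with the canonical 10-trials-per-class protocol) and tested, in
#' every fold, on one held-out correct trial per class plus one randomly
#' drawn error trial per class (error trials labelled by their instructed
#' numerosity).  The two test subsets are scored separately and compared by
#' a paired Wilcoxon signed-rank test across resamples.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids (default: neurons with
#'   `protocol$trials_per_class` correct trials and at least one error
#'   trial per class).
#' @param window feature window; default the motor planning period.
#' @param protocol a [decoding_protocol()] (canonical `trials_per_class`
#'   10).
#' @return list of class `error_decoding_result`: `accuracy_correct`,
#'   `accuracy_error` (+ sems), `acc_resamples` (matrix), `wilcoxon`,
#'   `neurons`.
#' @export
decode_error_trials <- function(ds, neurons = NULL, window = NULL,
                                protocol = decoding_protocol(
                                  trials_per_class = 10L)) {
  ph <- ds$meta$phase
  if (is.null(window))
    window <- c(ph$instruction_ms + 100,
                ph$instruction_ms + ph$planning_ms)
  if (is.null(neurons)) {
    cor_ok <- eligible_neurons(ds, protocol$trials_per_class)
    err_ok <- eligible_neurons(ds, 1, outcome = "error")
    neurons <- intersect(cor_ok, err_ok)
  }
  if (length(neurons) == 0) stop("no eligible neurons")
  trC <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  trE <- ds$trials[ds$trials$outcome == "error", , drop = FALSE]
  R_C <- .window_rates(ds, neurons, trC$trial_id, window)
  R_E <- .window_rates(ds, neurons, trE$trial_id, window)
  idxC <- .class_trial_index(ds, neurons, trC, factor(trC$numerosity))
  idxE <- .class_trial_index(ds, neurons, trE, factor(trE$numerosity))
  tpc <- protocol$trials_per_class
  acc <- matrix(0, protocol$resamples, 2,
                dimnames = list(NULL, c("correct", "error")))
  with_seed(mix_seed(protocol$seed, 110L), {
    for (r in seq_len(protocol$resamples)) {
      picks <- matrix(0L, 5 * tpc, length(neurons))
      for (j in seq_along(neurons))
        for (k in 1:5)
          picks[(k - 1) * tpc + seq_len(tpc), j] <-
            sample(idxC[[j]][[k]], tpc)
      x <- matrix(0, 5 * tpc, length(neurons))
      for (j in seq_along(neurons)) x[, j] <- R_C[j, picks[, j]]
      y <- factor(rep(1:5, each = tpc))
      draw <- rep(seq_len(tpc), times = 5)
      fold_of_draw <- sample(rep_len(seq_len(protocol$folds), tpc))
      hc <- he <- numeric(protocol$folds)
      for (f in seq_len(protocol$folds)) {
        te <- fold_of_draw[draw] == f
        # error test pseudotrials: one random error trial per class/neuron
        xe <- matrix(0, 5, length(neurons))
        for (j in seq_along(neurons))
          for (k in 1:5) {
            pool <- idxE[[j]][[k]]
            xe[k, j] <- R_E[j, if (length(pool) == 1) pool
                            else sample(pool, 1)]
          }
        z <- .zscore_by_train(x[!te, , drop = FALSE],
                              list(x[te, , drop = FALSE], xe))
        m <- .svm_fit(z$train, y[!te], protocol$cost)
        hc[f] <- mean(predict(m, z$tests[[1]]) == y[te])
        he[f] <- mean(predict(m, z$tests[[2]]) == factor(1:5))
      }
      acc[r, ] <- 100 * c(mean(hc), mean(he))
    }
  })
  wt <- stats::wilcox.test(acc[, "correct"], acc[, "error"], paired = TRUE,
                           exact = FALSE)
  structure(list(accuracy_correct = mean(acc[, "correct"]),
                 accuracy_error = mean(acc[, "error"]),
                 sem_correct = stats::sd(acc[, "correct"]) / sqrt(nrow(acc)),
                 sem_error = stats::sd(acc[, "error"]) / sqrt(nrow(acc)),
                 acc_resamples = acc, wilcoxon = wt, neurons = neurons),
            class = "error_decoding_result")
}

#' Decode trial outcome (correct, -1 error, +1 error)
#'
#' Three-class decoding of the production outcome from planning activity:
#' correct responses, undershoots (one action too few) and overshoots (one
#' action too many).  Chance is 33.3%.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids (default: neurons with
#'   `protocol$trials_per_class` trials of each outcome class).
#' @param window feature window; default the motor planning period.
#' @param protocol a [decoding_protocol()] (canonically 30 trials per
#'   class, 10 folds: 27 train / 3 test).
#' @param n_null shuffle-null resamples.
#' @return a `decoding_result` (3x3 confusion, chance 33.3%).
#' @export
decode_outcome <- function(ds, neurons = NULL, window = NULL,
                           protocol = decoding_protocol(
                             trials_per_class = 30L),
                           n_null = 0L) {
  ph <- ds$meta$phase
  if (is.null(window))
    window <- c(ph$instruction_ms + 100,
                ph$instruction_ms + ph$planning_ms)
  tr <- ds$trials[ds$trials$outcome != "aborted", , drop = FALSE]
  oc <- rep(NA_character_, nrow(tr))
  oc[tr$outcome == "correct"] <- "correct"
  oc[tr$outcome == "error" &
       tr$produced_count == tr$numerosity - 1] <- "minus1"
  oc[tr$outcome == "error" &
       tr$produced_count == tr$numerosity + 1] <- "plus1"
  keep <- !is.na(oc)
  tr <- tr[keep, , drop = FALSE]
  oc <- factor(oc[keep], levels = c("correct", "minus1", "plus1"))
  if (is.null(neurons)) {
    neurons <- ds$neurons$neuron_id[vapply(seq_len(nrow(ds$neurons)),
      function(i) {
        tab <- table(oc[tr$session_id == ds$neurons$session_id[i]])
        all(tab >= protocol$trials_per_class)
      }, logical(1))]
  }
  if (length(neurons) == 0) stop("no eligible neurons")
  R <- .window_rates(ds, neurons, tr$trial_id, window)
  idx <- .class_trial_index(ds, neurons, tr, oc)
  tpc <- protocol$trials_per_class
  run_one <- function(r, shuffle, tag) {
    picks <- matrix(0L, 3 * tpc, length(neurons))
    for (j in seq_along(neurons))
      for (k in 1:3)
        picks[(k - 1) * tpc + seq_len(tpc), j] <-
          sample(idx[[j]][[k]], tpc)
    x <- matrix(0, 3 * tpc, length(neurons))
    for (j in seq_along(neurons)) x[, j] <- R[j, picks[, j]]
    y <- factor(rep(levels(oc), each = tpc), levels = levels(oc))
    p1 <- protocol; p1$resamples <- 1L
    p1$seed <- mix_seed(protocol$seed, tag, r)
    decode(x, y, p1, shuffle = shuffle)
  }
  conf <- NULL; accs <- numeric(protocol$resamples)
  with_seed(mix_seed(protocol$seed, 120L), {
    for (r in seq_len(protocol$resamples)) {
      d <- run_one(r, FALSE, 121L)
      accs[r] <- d$accuracy
      conf <- if (is.null(conf)) d$confusion else conf + d$confusion
    }
  })
  res <- structure(list(confusion = conf / protocol$resamples,
                        accuracy = mean(accs),
                        sem = stats::sd(accs) / sqrt(length(accs)),
                        per_class = 100 * diag(conf / protocol$resamples),
                        acc_resamples = accs,
                        n_resamples = protocol$resamples,
                        chance = 100 / 3, neurons = neurons),
                   class = "decoding_result")
  if (n_null > 0) {
    nacc <- numeric(n_null)
    with_seed(mix_seed(protocol$seed, 130L), {
      for (r in seq_len(n_null)) nacc[r] <- run_one(r, TRUE, 131L)$accuracy
    })
    res$null_acc <- nacc
    res$null_mean <- mean(nacc)
    res$null_p95 <- unname(stats::quantile(nacc, 0.95))
  }
  res
}
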