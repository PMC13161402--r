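# Time-resolved population statistics: omega-squared explained-variance
# traces, cross-temporal decoding matrices, cluster-based permutation
# significance, and confusion-diagonal distance curves.

#' Omega-squared percent-explained-variance time course
#'
#' For every sliding bin, a two-factor ANOVA (numerosity x format) of each
#' neuron's firing rate yields the omega-squared percentage of variance
#' explained by each factor; the population trace is the mean over neurons.
#' The analysis is repeated over `n_resamples` random balanced trial
#' subsets (mean and SEM across repetitions), and a chance baseline is
#' built by shuffling trial labels `n_shuffles` times within every
#' repetition, pooling `n_resamples * n_shuffles` null values per time
#' step; the 95th percentile of that pool is the baseline threshold.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids; neurons with fewer than `min_per_level`
#'   correct trials per factor level are dropped (with a message).
#' @param scheme a [bin_scheme()]; canonical span is 300 ms before
#'   instruction onset to 100 ms after planning ends, 200/20 ms bins.
#' @param n_resamples trial-subset repetitions (canonically 50).
#' @param n_shuffles label shuffles per repetition (canonically 20).
#' @param trials_per_cell trials drawn per numerosity x format cell in each
#'   repetition (default: the largest balanced count available).
#' @param min_per_level inclusion minimum per factor level (default 10).
#' @param seed RNG seed.
#' @return object of class `pev_trace`: `pev` (3 x bins matrix of mean
#'   omega-squared %, rows number/format/interaction), `sem`, `null_p95`
#'   (3 x bins), `time_ms` (bin centers), `n_neurons`, `scheme`.
#' @export
pev_timecourse <- function(ds, neurons = NULL, scheme = NULL,
                           n_resamples = 50L, n_shuffles = 20L,
                           trials_per_cell = NULL, min_per_level = 10L,
                           seed = 1L) {
  ph <- ds$meta$phase
  if (is.null(scheme))
    scheme <- bin_scheme(-300, ph$instruction_ms + ph$planning_ms + 100,
                         width_ms = 200, step_ms = 20)
  if (is.null(neurons)) neurons <- ds$neurons$neuron_id
  tr <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  # inclusion: >= min_per_level correct trials per numerosity and format
  keep <- vapply(neurons, function(nid) {
    s <- ds$neurons$session_id[match(nid, ds$neurons$neuron_id)]
    trs <- tr[tr$session_id == s, , drop = FALSE]
    all(table(trs$numerosity) >= min_per_level) &&
      all(table(trs$format) >= min_per_level) &&
      length(unique(trs$numerosity)) == 5
  }, logical(1))
  if (any(!keep))
    message(sum(!keep), " neuron(s) dropped by the PEV inclusion filter")
  neurons <- neurons[keep]
  if (length(neurons) == 0) stop("no eligible neurons")

  sessions <- unique(ds$neurons$session_id[match(neurons,
                                                 ds$neurons$neuron_id)])
  nb <- scheme$n_bins
  facs <- c("number", "format", "interaction")
  obs <- array(NA_real_, c(3, nb, n_resamples),
               dimnames = list(facs, NULL, NULL))
  null_pool <- array(NA_real_, c(3, nb, n_resamples * n_shuffles),
                     dimnames = list(facs, NULL, NULL))
  binned_by_sess <- list()
  labels_by_sess <- list()
  for (s in sessions) {
    trs <- tr[tr$session_id == s, , drop = FALSE]
    nid_s <- neurons[ds$neurons$session_id[match(neurons,
                                          ds$neurons$neuron_id)] == s]
    binned_by_sess[[s]] <- bin_rates(ds, scheme, neurons = nid_s,
                                     trials = trs$trial_id)
    labels_by_sess[[s]] <- trs
  }
  with_seed(mix_seed(seed, 140L), {
    for (r in seq_len(n_resamples)) {
      per_neuron <- list()   # omega2 3 x nb per neuron, this subset
      null_r <- array(0, c(3, nb, n_shuffles))
      n_tot <- 0
      for (s in sessions) {
        b <- binned_by_sess[[s]]
        trs <- labels_by_sess[[s]]
        cellkey <- paste(trs$numerosity, trs$format)
        tab <- table(cellkey)
        ncell <- if (is.null(trials_per_cell)) min(tab) else trials_per_cell
        sub <- unlist(lapply(split(seq_len(nrow(trs)), cellkey),
                             function(ix) sample(ix, ncell)),
                      use.names = FALSE)
        num <- trs$numerosity[sub]
        fmt <- trs$format[sub]
        shuffles <- replicate(n_shuffles, sample(seq_along(sub)),
                              simplify = FALSE)
        for (j in seq_along(b$neuron_ids)) {
          Y <- matrix(b$rates[j, sub, ], nrow = length(sub))
          dec <- anova2_decomposition(Y, num, fmt)
          w <- rbind(omega_squared(dec, "number"),
                     omega_squared(dec, "format"),
                     omega_squared(dec, "interaction"))
          per_neuron[[length(per_neuron) + 1]] <- w
          for (k in seq_len(n_shuffles)) {
            dn <- anova2_decomposition(Y, num[shuffles[[k]]],
                                       fmt[shuffles[[k]]])
            null_r[, , k] <- null_r[, , k] +
              rbind(omega_squared(dn, "number"),
                    omega_squared(dn, "format"),
                    omega_squared(dn, "interaction"))
          }
          n_tot <- n_tot + 1
        }
      }
      obs[, , r] <- Reduce(`+`, per_neuron) / n_tot
      null_pool[, , (r - 1) * n_shuffles + seq_len(n_shuffles)] <-
        null_r / n_tot
    }
  })
  pev <- apply(obs, 1:2, mean)
  sem <- apply(obs, 1:2, stats::sd) / sqrt(n_resamples)
  null_p95 <- apply(null_pool, 1:2, stats::quantile, 0.95)
  structure(list(pev = pev, sem = sem, null_p95 = null_p95,
                 null_pool = null_pool, time_ms = scheme$centers,
                 n_neurons = length(neurons), scheme = scheme,
                 n_resamples = n_resamples, n_shuffles = n_shuffles),
            class = "pev_trace")
}

#' @export
print.pev_trace <- function(x, ...) {
  cat("pev_trace:", x$n_neurons, "neurons,", length(x$time_ms), "bins;",
      sprintf("peak number-PEV %.2f%%", max(x$pev["number", ])), "\n")
  invisible(x)
}

#' @export
plot.pev_trace <- function(x, ...) {
  cols <- c(number = "firebrick", format = "steelblue",
            interaction = "grey40")
  graphics::matplot(x$time_ms, t(x$pev), type = "l", lty = 1, col = cols,
                    xlab = "time from instruction onset (ms)",
                    ylab = expression(omega^2 ~ "PEV (%)"), ...)
  graphics::matlines(x$time_ms, t(x$null_p95), lty = 3, col = cols)
  graphics::legend("topleft", legend = rownames(x$pev), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Cross-temporal decoding matrix
#'
#' Trains a linear one-vs-one SVM on population firing rates of every time
#' bin and tests it on held-out trials of every time bin, yielding a
#' train-time x test-time accuracy matrix.  Train and test trials are
#' disjoint also off the diagonal: the test trials at every test bin come
#' from the held-out fold of the trial split.  Sustained ("static") codes
#' generalize off-diagonal, producing a square pattern; transient
#' ("dynamic") codes confine accuracy to the diagonal.  Shuffle-null
#' matrices from label permutations under the identical protocol feed the
#' cluster-based permutation test.
#'
#' @param ds a [session_dataset()].
#' @param neurons neuron ids with at least `protocol$trials_per_class`
#'   correct trials per numerosity (default: the eligible set).
#' @param scheme a [bin_scheme()].
#' @param protocol a [decoding_protocol()] (canonically 20 trials per
#'   class, 10 folds: 18 train / 2 test; `resamples` is ignored here in
#'   favour of `n_redraws`).
#' @param n_redraws random trial redraws (canonically 50).
#' @param n_shuffles label shuffles per redraw for the null (canonically
#'   20; 0 to skip).
#' @return object of class `cross_temporal_matrix`: `accuracy` (bins x
#'   bins, train x test, %), `null` (array shuffles x bins x bins or NULL),
#'   `scheme`, `chance`, `n_redraws`.
#' @export
cross_temporal_matrix <- function(ds, neurons = NULL, scheme,
                                  protocol = decoding_protocol(),
                                  n_redraws = 50L, n_shuffles = 20L) {
  if (is.null(neurons))
    neurons <- eligible_neurons(ds, protocol$trials_per_class)
  if (length(neurons) == 0) stop("no eligible neurons")
  tr <- ds$trials[ds$trials$outcome == "correct", , drop = FALSE]
  cls <- factor(tr$numerosity)
  K <- nlevels(cls)
  binned <- bin_rates(ds, scheme, neurons = neurons, trials = tr$trial_id)
  idx <- .class_trial_index(ds, neurons, tr, cls)
  tpc <- protocol$trials_per_class
  nb <- scheme$n_bins
  acc <- matrix(0, nb, nb)
  nul <- if (n_shuffles > 0)
    array(0, c(n_redraws * n_shuffles, nb, nb)) else NULL

  trial_pos <- match(tr$trial_id, binned$trial_ids)
  run_cv <- function(X, y, fold_of_draw, draw) {
    # X: rows pseudotrials x neurons x bins (3d); returns nb x nb hits
    hits <- matrix(0, nb, nb)
    for (f in seq_len(protocol$folds)) {
      te <- fold_of_draw[draw] == f
      ztr <- list(); zte <- list()
      for (b in seq_len(nb)) {
        z <- .zscore_by_train(matrix(X[!te, , b], ncol = dim(X)[2]),
                              list(matrix(X[te, , b], ncol = dim(X)[2])))
        ztr[[b]] <- z$train; zte[[b]] <- z$tests[[1]]
      }
      for (bi in seq_len(nb)) {
        m <- .svm_fit(ztr[[bi]], y[!te], protocol$cost)
        for (bj in seq_len(nb))
          hits[bi, bj] <- hits[bi, bj] + mean(predict(m, zte[[bj]]) == y[te])
      }
    }
    hits / protocol$folds
  }
  with_seed(mix_seed(protocol$seed, 150L), {
    for (r in seq_len(n_redraws)) {
      picks <- matrix(0L, K * tpc, length(neurons))
      for (j in seq_along(neurons))
        for (k in seq_len(K))
          picks[(k - 1) * tpc + seq_len(tpc), j] <-
            sample(idx[[j]][[k]], tpc)
      X <- array(0, c(K * tpc, length(neurons), nb))
      for (j in seq_along(neurons))
        X[, j, ] <- binned$rates[j, trial_pos[picks[, j]], ]
      y <- factor(rep(levels(cls), each = tpc), levels = levels(cls))
      draw <- rep(seq_len(tpc), times = K)
      fold_of_draw <- sample(rep_len(seq_len(protocol$folds), tpc))
      acc <- acc + run_cv(X, y, fold_of_draw, draw)
      if (n_shuffles > 0) {
        for (s in seq_len(n_shuffles)) {
          ys <- sample(y)
          nul[(r - 1) * n_shuffles + s, , ] <-
            100 * run_cv(X, ys, fold_of_draw, draw)
        }
      }
    }
  })
  structure(list(accuracy = 100 * acc / n_redraws, null = nul,
                 scheme = scheme, chance = 100 / K, n_redraws = n_redraws,
                 n_shuffles = n_shuffles, neurons = neurons),
            class = "cross_temporal_matrix")
}

#' @export
print.cross_temporal_matrix <- function(x, ...) {
  cat("cross_temporal_matrix:", nrow(x$accuracy), "x", ncol(x$accuracy),
      sprintf("bins; diagonal mean %.1f%%, off-diagonal mean %.1f%% (chance %.1f%%)\n",
              mean(diag(x$accuracy)),
              mean(x$accuracy[row(x$accuracy) != col(x$accuracy)]),
              x$chance))
  invisible(x)
}

#' @export
plot.cross_temporal_matrix <- function(x, ...) {
  t_ <- x$scheme$centers
  graphics::image(t_, t_, x$accuracy, xlab = "training time (ms)",
                  ylab = "testing time (ms)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Generalization index of a cross-temporal matrix
#'
#' Mean off-diagonal minus mean diagonal accuracy.  Near zero for a static
#' code (training time hardly matters), strongly negative for a dynamic
#' code (accuracy confined to the diagonal).
#'
#' @param x a [cross_temporal_matrix()] result or a plain accuracy matrix.
#' @param exclude_band half-width (in bins) of the near-diagonal band
#'   counted as "diagonal-like" and excluded from the off-diagonal mean;
#'   default 0 (strict off-diagonal).
#' @return scalar index in percentage points.
#' @export
generalization_index <- function(x, exclude_band = 0) {
  m <- if (inherits(x, "cross_temporal_matrix")) x$accuracy else x
  d <- abs(row(m) - col(m))
  mean(m[d > exclude_band]) - mean(diag(m))
}

#' Connected components of a logical matrix
#' @keywords internal
#' @noRd
.label_components <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        ii <- p[1] + nb[q, 1]; jj <- p[2] + nb[q, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Cluster-based permutation test on a decoding matrix
#'
#' Cells are called significant when the observed accuracy exceeds the
#' per-cell 95th percentile (at `alpha_cluster`) of the shuffle-null
#' values; contiguous significant cells (4-connectivity by default) form
#' clusters whose statistic is the cell count.  The null cluster-size
#' distribution is the maximum cluster size obtained by applying the same
#' thresholding to each permuted matrix; observed clusters whose size
#' exceeds its `1 - alpha_rank` quantile are deemed significant.
#'
#' @param observed accuracy matrix (or a [cross_temporal_matrix()], whose
#'   stored null is used by default).
#' @param null array of permuted accuracy matrices
#'   (`n_perm x nrow x ncol`); at least 20 permutations required.
#' @param alpha_cluster cell-wise threshold quantile (default 0.05).
#' @param alpha_rank cluster-size rank threshold (default 0.05).
#' @param connectivity 4 (default) or 8.
#' @return object of class `cluster_test`: `clusters` (data.frame id,
#'   size, p_rank, significant), `labels` (cluster-id matrix),
#'   `cell_threshold`, `null_max_sizes`, `size_threshold`.
#' @export
cluster_permutation_test <- function(observed, null = NULL,
                                     alpha_cluster = 0.05,
                                     alpha_rank = 0.05,
                                     connectivity = 4) {
  if (inherits(observed, "cross_temporal_matrix")) {
    if (is.null(null)) null <- observed$null
    observed <- observed$accuracy
  }
  if (is.null(null) || dim(null)[1] < 20)
    stop("at least 20 permutation matrices are required")
  n_perm <- dim(null)[1]
  # the observed matrix joins the permutation pool for thresholding, so
  # observed and permuted matrices are exchangeable under the null (the
  # rank test is otherwise anti-conservative at small permutation counts)
  pool <- array(NA_real_, dim(null) + c(1, 0, 0))
  pool[seq_len(n_perm), , ] <- null
  pool[n_perm + 1, , ] <- observed
  thr <- apply(pool, c(2, 3), stats::quantile, 1 - alpha_cluster)
  mask <- observed > thr
  lab <- .label_components(mask, connectivity)
  null_max <- vapply(seq_len(n_perm), function(i) {
    m <- null[i, , ] > thr
    l <- .label_components(m, connectivity)
    if (max(l) == 0) 0L else max(tabulate(l[l > 0]))
  }, integer(1))
  size_thr <- stats::quantile(null_max, 1 - alpha_rank)
  n_cl <- max(lab)
  clusters <- if (n_cl > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n_cl)
    data.frame(id = seq_len(n_cl), size = sizes,
               p_rank = vapply(sizes, function(sz)
                 (1 + sum(null_max >= sz)) / (1 + n_perm), numeric(1)),
               significant = sizes > size_thr)
  } else {
    data.frame(id = integer(0), size = integer(0), p_rank = numeric(0),
               significant = logical(0))
  }
  structure(list(clusters = clusters, labels = lab, cell_threshold = thr,
                 null_max_sizes = null_max,
                 size_threshold = unname(size_thr),
                 alpha_cluster = alpha_cluster, alpha_rank = alpha_rank,
                 connectivity = connectivity),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("cluster_test:", nrow(x$clusters), "cluster(s),",
      sum(x$clusters$significant), "significant (size threshold",
      x$size_threshold, ")\n")
  invisible(x)
}

#' Classification probability as a function of numerical distance
#'
#' Averages the entries of row-normalized confusion matrices along
#' diagonals parallel to the main diagonal: distance 0 is the mean of the
#' main diagonal (accuracy), distance d pools the +d and -d diagonals.
#'
#' @param confusions a single row-normalized confusion matrix or a list of
#'   them (e.g. one per time bin).
#' @return matrix with one row per input matrix and one column per
#'   distance `0 .. K-1`.
#' @export
distance_curves <- function(confusions) {
  if (is.matrix(confusions)) confusions <- list(confusions)
  K <- nrow(confusions[[1]])
  out <- matrix(NA_real_, length(confusions), K,
                dimnames = list(names(confusions), 0:(K - 1)))
  for (i in seq_along(confusions)) {
    cm <- confusions[[i]]
    if (any(abs(rowSums(cm) - 1) > 1e-6))
      stop("confusion matrix rows must sum to 1 (row-normalized input)")
    d <- abs(row(cm) - col(cm))
    out[i, ] <- vapply(0:(K - 1), function(k) mean(cm[d == k]), numeric(1))
  }
  out
}
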