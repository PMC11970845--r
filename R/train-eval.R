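# Training loop (Adam + binary cross entropy) and the evaluation harness:
# rank-based AUROC / AUPR, recall and accuracy, percentile-bootstrap
# confidence intervals over sets, paired significance tests, and the two
# robustness sweeps (number of updating steps, evaluation set size).

#' Training configuration
#'
#' Defaults follow the study design for both tasks: binary cross entropy with
#' Adam, learning rate 1e-4, 20 epochs, minibatches of 32 sets.
#'
#' @param lr Learning rate.
#' @param epochs Number of passes over the training sets.
#' @param batch_size Sets per optimiser step.
#' @param seed Seed controlling set shuffling (parameter initialisation is
#'   seeded in [set_model()]).
#' @param verbose Print the per-epoch loss.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-4, epochs = 20L, batch_size = 32L, seed = 1L,
                         verbose = FALSE) {
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

#' Train a set model
#'
#' Minibatch Adam on binary cross entropy. For the instance task each set
#' contributes the mean BCE over its instances against the one-hot target;
#' for the set task, the BCE of the single set probability. Gradients are
#' averaged over the sets of a batch. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param model A [set_model()].
#' @param sets List of training sets, each a list with `x` (images list or
#'   embedding matrix) and `y` (one-hot vector or scalar 0/1 label).
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history` (data frame of epoch and
#'   mean training loss).
#' @export
train <- function(model, sets, config = train_config()) {
  if (length(sets) == 0) stop("no training sets supplied")
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(sets))
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        gacc <- NULL
        bl <- 0
        model$params <- params
        for (i in idx) {
          f <- model_forward(model, sets[[i]]$x)
          l <- bce_loss(f$logits, sets[[i]]$y)
          bl <- bl + l$loss
          g <- model_backward(model, f, l$dlogits)
          gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
        }
        bl <- bl / length(idx)
        if (!is.finite(bl)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               " (try a smaller learning rate)")
        }
        gacc <- tree_scale(gacc, 1 / length(idx))
        st <- adam_step(params, gacc, state, lr = config$lr)
        params <- st$params
        state <- st$state
        losses <- c(losses, bl)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = mean(losses)))
      if (config$verbose) {
        message(sprintf("epoch %d  loss %.5f", ep, mean(losses)))
      }
    }
  })
  model$params <- params
  list(model = model, history = history)
}

# ---------------------------------------------------------------------------
# Rank-based metrics
# ---------------------------------------------------------------------------

#' Area under the ROC curve (rank-based, midrank ties)
#' @param scores Numeric predictions.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined for single-class labels")
  r <- rank(scores) # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision, tie-grouped)
#'
#' Scores are processed in decreasing order; tied scores form one block and
#' contribute their recall increment at the block's precision.
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) {
    stop("AUPR undefined for single-class labels")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  n_seen <- grp_end
  prec <- tp / n_seen
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / n1
}

# ---------------------------------------------------------------------------
# Evaluation
# ---------------------------------------------------------------------------

# collect per-set predictions once; everything else (point metrics and
# bootstrap resamples) is recomputed from this cache
collect_predictions <- function(model, sets) {
  lapply(seq_along(sets), function(i) {
    f <- model_forward(model, sets[[i]]$x)
    list(scores = as.numeric(f$probs), y = sets[[i]]$y)
  })
}

metrics_from_cache <- function(cache, task) {
  if (task == "instance") {
    sc <- unlist(lapply(cache, `[[`, "scores"))
    y <- unlist(lapply(cache, `[[`, "y"))
    hit <- vapply(cache, function(e) {
      which.max(e$scores) == which.max(e$y)
    }, logical(1))
    pred <- as.integer(sc >= 0.5)
    c(auroc = auroc(sc, y), aupr = aupr(sc, y),
      recall = mean(hit), # argmax convention: top-scored instance is the lesion
      recall_threshold = sum(pred == 1 & y == 1) / sum(y == 1),
      accuracy = mean(pred == y))
  } else {
    sc <- vapply(cache, function(e) e$scores[1], numeric(1))
    y <- vapply(cache, function(e) e$y[1], numeric(1))
    pred <- as.integer(sc >= 0.5)
    c(auroc = auroc(sc, y), aupr = aupr(sc, y),
      recall = sum(pred == 1 & y == 1) / sum(y == 1),
      accuracy = mean(pred == y))
  }
}

#' Evaluate a model on held-out sets
#'
#' Computes AUROC and AUPR from pooled instance scores (instance task) or the
#' per-set probabilities (set task), recall and accuracy at the documented
#' operating points, and percentile-bootstrap confidence intervals obtained
#' by resampling whole sets. For the instance task `recall` is the fraction
#' of sets whose truly positive instance receives the highest score (argmax
#' convention); `recall_threshold` is instance-level recall at threshold 0.5.
#'
#' @param model A trained [set_model()].
#' @param sets Held-out sets (same format as [train()]).
#' @param task `"instance"` or `"set"`; defaults to the model's head.
#' @param n_bootstrap Bootstrap resamples for the confidence intervals
#'   (0 disables them).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return A `metric_report`: list with `metrics` (named vector), `ci`
#'   (data frame with `metric`, `low`, `high`), `n_sets`, `n_bootstrap`, and
#'   the per-set prediction cache used for paired comparisons.
#' @export
evaluate <- function(model, sets, task = NULL, n_bootstrap = 1000L,
                     conf = 0.95, seed = 1L) {
  if (is.null(task)) task <- model$head
  task <- match.arg(task, c("instance", "set"))
  cache <- collect_predictions(model, sets)
  report_from_cache(cache, task, n_bootstrap, conf, seed)
}

report_from_cache <- function(cache, task, n_bootstrap = 1000L, conf = 0.95,
                              seed = 1L) {
  pt <- metrics_from_cache(cache, task)
  ci <- NULL
  if (n_bootstrap > 0) {
    n <- length(cache)
    boot <- with_seed(seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(metrics_from_cache(cache[idx], task),
                 error = function(e) rep(NA_real_, length(pt)))
      }, numeric(length(pt)))
    })
    a <- (1 - conf) / 2
    ci <- data.frame(
      metric = names(pt),
      low = apply(boot, 1, stats::quantile, probs = a, na.rm = TRUE),
      high = apply(boot, 1, stats::quantile, probs = 1 - a, na.rm = TRUE),
      row.names = NULL)
  }
  structure(list(metrics = pt, ci = ci, n_sets = length(cache),
                 n_bootstrap = n_bootstrap, task = task, cache = cache),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", x$task, "task,", x$n_sets, "sets\n")
  for (m in names(x$metrics)) {
    line <- sprintf("  %-17s %.4f", m, x$metrics[[m]])
    if (!is.null(x$ci)) {
      r <- x$ci[x$ci$metric == m, ]
      line <- paste0(line, sprintf("  (95%% CI %.4f-%.4f)", r$low, r$high))
    }
    cat(line, "\n")
  }
  invisible(x)
}

#' Pairwise significance of metric differences between operators
#'
#' Paired bootstrap over the shared evaluation sets: both models' cached
#' per-set predictions are resampled with the same indices, the metric
#' difference is recomputed per resample, and a two-sided P value is derived
#' from the fraction of resamples on either side of zero (with a +1
#' continuity correction, so P is in (0, 1]). A model compared with itself
#' yields P = 1.
#'
#' @param reports List of `metric_report`s evaluated on identical sets (same
#'   order, same labels).
#' @param metric Which metric to compare.
#' @param n_bootstrap Number of paired resamples.
#' @param seed Bootstrap seed.
#' @return Symmetric matrix of two-sided P values.
#' @export
compare_operators <- function(reports, metric = "auroc",
                              n_bootstrap = 10000L, seed = 1L) {
  stopifnot(length(reports) >= 2)
  n <- unique(vapply(reports, function(r) length(r$cache), integer(1)))
  if (length(n) != 1) stop("reports are not paired: different numbers of sets")
  y0 <- lapply(reports[[1]]$cache, `[[`, "y")
  for (r in reports[-1]) {
    if (!identical(lapply(r$cache, `[[`, "y"), y0)) {
      stop("reports are not paired: labels differ across reports")
    }
  }
  task <- reports[[1]]$task
  k <- length(reports)
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("model", seq_len(k))
  P <- matrix(1, k, k, dimnames = list(nm, nm))
  idx_mat <- with_seed(seed, {
    matrix(sample.int(n, n * n_bootstrap, replace = TRUE), n, n_bootstrap)
  })
  one_metric <- function(cache, idx) {
    tryCatch(metrics_from_cache(cache[idx], task)[[metric]],
             error = function(e) NA_real_)
  }
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      diffs <- vapply(seq_len(n_bootstrap), function(j) {
        one_metric(reports[[a]]$cache, idx_mat[, j]) -
          one_metric(reports[[b]]$cache, idx_mat[, j])
      }, numeric(1))
      diffs <- diffs[is.finite(diffs)]
      B <- length(diffs)
      p <- 2 * min((sum(diffs <= 0) + 1) / (B + 1),
                   (sum(diffs >= 0) + 1) / (B + 1))
      P[a, b] <- P[b, a] <- min(p, 1)
    }
  }
  P
}

# ---------------------------------------------------------------------------
# Sweeps
# ---------------------------------------------------------------------------

#' Sweep the number of PICASO updating steps J
#'
#' Trains one model per (J, seed) combination and evaluates it, emitting a
#' tidy table of metrics against the cascade depth. Performance need not be
#' monotone in J.
#'
#' @param train_sets,val_sets Training and held-out sets.
#' @param J_values Cascade depths to try (1 is the natural baseline).
#' @param seeds One model is trained per seed per J.
#' @param encoder,aggregator,head,head_mode Passed to [set_model()]; the
#'   aggregator's `n_steps` is overridden by each J.
#' @param config A [train_config()].
#' @param n_bootstrap Bootstrap resamples in each evaluation (0 disables).
#' @return Data frame with one row per (J, seed) and one column per metric.
#' @export
sweep_steps <- function(train_sets, val_sets, J_values = 1:4, seeds = 1L,
                        encoder, aggregator, head = "instance",
                        head_mode = "vector", config = train_config(),
                        n_bootstrap = 0L) {
  rows <- list()
  for (J in J_values) {
    for (s in seeds) {
      agg <- aggregator
      agg$n_steps <- as.integer(J)
      m <- set_model(encoder, agg, head = head, head_mode = head_mode,
                     seed = s)
      cfg <- config
      cfg$seed <- s
      tr <- train(m, train_sets, cfg)
      rep <- evaluate(tr$model, val_sets, n_bootstrap = n_bootstrap)
      rows[[length(rows) + 1]] <-
        data.frame(J = J, seed = s, t(rep$metrics))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a trained model across evaluation set sizes
#'
#' Rebuilds the evaluation sets at each requested size M (no retraining) and
#' evaluates the same model on each, mirroring the robustness analysis of a
#' model trained on sets of at most eight images and deployed on smaller or
#' larger cases.
#'
#' @param model A trained [set_model()].
#' @param M_values Evaluation set sizes.
#' @param build_fn Function `build_fn(M)` returning evaluation sets of size M
#'   (same format as [train()]).
#' @param n_bootstrap Bootstrap resamples per evaluation (0 disables).
#' @return Data frame with one row per M and one column per metric.
#' @export
sweep_set_size <- function(model, M_values, build_fn, n_bootstrap = 0L) {
  rows <- lapply(M_values, function(M) {
    sets <- build_fn(M)
    rep <- evaluate(model, sets, n_bootstrap = n_bootstrap)
    data.frame(M = M, t(rep$metrics))
  })
  do.call(rbind, rows)
}

#' Write a metric report to CSV and JSON
#'
#' @param report A `metric_report`.
#' @param path_csv,path_json Output files (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  df <- data.frame(metric = names(report$metrics),
                   value = as.numeric(report$metrics))
  if (!is.null(report$ci)) df <- merge(df, report$ci, sort = FALSE)
  if (!is.null(path_csv)) utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(task = report$task, n_sets = report$n_sets,
                              metrics = as.list(report$metrics),
                              ci = df),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
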