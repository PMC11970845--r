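# Independent oracles and small utilities shared across tests. These are
# deliberately naive implementations (explicit loops, brute force) so they
# stay independent of the package's vectorised code paths.

# quadratic-time pairwise AUROC: fraction of (positive, negative) pairs won,
# ties counted half
auroc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

# threshold-walking average precision with tied scores handled as blocks
aupr_threshold <- function(scores, labels) {
  n1 <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    recall <- tp / n1
    area <- area + (recall - prev_recall) * prec
    prev_recall <- recall
  }
  area
}

# one Lloyd step: hard nearest-centroid assignment, then cluster means;
# empty clusters keep their centroid
lloyd_step <- function(mu, X) {
  K <- nrow(mu)
  out <- mu
  assign <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- colSums((t(mu) - X[i, ])^2)
    assign[i] <- which.min(d2)
  }
  for (k in seq_len(K)) {
    if (any(assign == k)) {
      out[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    }
  }
  out
}

# flatten a parameter tree / write a flat vector back into it
flatten_tree <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_tree), use.names = FALSE)
  else as.numeric(x)
}

unflatten_tree <- function(x, v, pos = 1) {
  if (is.list(x)) {
    for (i in seq_along(x)) {
      r <- unflatten_tree(x[[i]], v, pos)
      x[[i]] <- r$x
      pos <- r$pos
    }
    list(x = x, pos = pos)
  } else {
    n <- length(x)
    x[] <- v[pos:(pos + n - 1)]
    list(x = x, pos = pos + n)
  }
}

# central finite-difference check of the analytic gradient of the BCE loss
# with respect to every (sampled) parameter
max_grad_rel_err <- function(model, x, y, n_check = 60, eps = 1e-6,
                             seed = 7) {
  f <- picaso:::model_forward(model, x)
  l <- picaso:::bce_loss(f$logits, y)
  g <- picaso:::model_backward(model, f, l$dlogits)
  gf <- flatten_tree(g)
  pf <- flatten_tree(model$params)
  set.seed(seed)
  idx <- sample(length(pf), min(n_check, length(pf)))
  num <- vapply(idx, function(i) {
    pp <- pf
    pp[i] <- pf[i] + eps
    m2 <- model
    m2$params <- unflatten_tree(model$params, pp)$x
    lp <- picaso:::bce_loss(picaso:::model_forward(m2, x)$logits, y)$loss
    pp[i] <- pf[i] - eps
    m2$params <- unflatten_tree(model$params, pp)$x
    lm <- picaso:::bce_loss(picaso:::model_forward(m2, x)$logits, y)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  max(abs(num - gf[idx]) / pmax(1e-6, abs(num) + abs(gf[idx])))
}

rand_embeddings <- function(M, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(M * d), M, d)
}

# a tiny manifest: n_groups groups, each with n_pos positives and n_neg
# negatives
toy_pool <- function(n_groups = 4, n_pos = 1, n_neg = 7) {
  n <- n_pos + n_neg
  data.frame(
    instance_id = sprintf("g%02d_i%02d", rep(seq_len(n_groups), each = n),
                          rep(seq_len(n), n_groups)),
    group_id = sprintf("g%02d", rep(seq_len(n_groups), each = n)),
    cohort = "a",
    label = rep(c(rep(1L, n_pos), rep(0L, n_neg)), n_groups))
}
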