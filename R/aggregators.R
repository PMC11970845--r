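# Permutation-invariant set aggregators. All of them map a variable-size set
# of d-dimensional instance embeddings (rows of E) to a fixed-shape aggregate;
# every instance enters only through symmetric reductions (softmax-weighted
# sums, max/mean/sum pooling), which is what makes the operators valid set
# functions.

#' Aggregator configuration
#'
#' Describes one set operator: the PICASO cascade, a DeepSet variant or a
#' Set Transformer. `dim` is the model width d of the aggregator; instance
#' embeddings are projected to this width before aggregation.
#'
#' @param operator One of `"picaso"`, `"deepset"`, `"deepset++"`,
#'   `"set_transformer"`, `"set_transformer++"`.
#' @param dim Model width d; must be divisible by `n_heads` for the
#'   attention-based operators.
#' @param n_hive Number of histopathologic vectors N_HV (PICASO only).
#' @param n_heads Attention heads N_h.
#' @param n_steps Number of cascaded Transformer blocks J (PICASO only).
#' @param share_weights If `TRUE` (default) the same Transformer block
#'   parameters are reused at every step, so the parameter count does not grow
#'   with J.
#' @param ffn_mult Feed-forward hidden width as a multiple of `dim`.
#' @param pool DeepSet pooling: `"max"`, `"mean"` or `"sum"`.
#' @param weighted DeepSet only: learn per-instance scalar gates,
#'   softmax-normalised over the set and applied before pooling.
#' @param n_seeds Set Transformer: number of learnable seed vectors for
#'   pooling by multihead attention.
#' @param n_sab Set Transformer: number of self-attention blocks over the
#'   instances before pooling (the "++" variant adds one more).
#' @param plain_pma Set Transformer: if `TRUE` the pooling step is raw
#'   multihead cross-attention of the seeds over the instances, with no
#'   residual/feed-forward wrapper (used for structural checks).
#' @return An object of class `aggregator_config`.
#' @export
aggregator_config <- function(operator = c("picaso", "deepset", "deepset++",
                                           "set_transformer", "set_transformer++"),
                              dim = 64L, n_hive = 1L, n_heads = 8L,
                              n_steps = 3L, share_weights = TRUE,
                              ffn_mult = 2L, pool = c("max", "mean", "sum"),
                              weighted = FALSE, n_seeds = 1L, n_sab = 1L,
                              plain_pma = FALSE) {
  operator <- match.arg(operator)
  pool <- match.arg(pool)
  if (dim < 1 || n_hive < 1) stop("dim and n_hive must be positive")
  if (operator %in% c("picaso", "set_transformer", "set_transformer++") &&
      dim %% n_heads != 0) {
    stop("dim = ", dim, " must be divisible by n_heads = ", n_heads)
  }
  if (operator == "picaso" && n_steps < 1) stop("n_steps (J) must be >= 1")
  if (operator == "set_transformer++") n_sab <- n_sab + 1L
  structure(list(operator = operator, dim = as.integer(dim),
                 n_hive = as.integer(n_hive), n_heads = as.integer(n_heads),
                 n_steps = as.integer(n_steps), share_weights = share_weights,
                 ffn_mult = as.integer(ffn_mult), pool = pool,
                 weighted = weighted, n_seeds = as.integer(n_seeds),
                 n_sab = as.integer(n_sab), plain_pma = plain_pma),
            class = "aggregator_config")
}

#' Initialise the learnable HiVe
#'
#' Draws the initial histopathologic-vector matrix mu0 (N_HV x d) from the
#' Kaiming scheme (zero mean, variance 2/d). mu0 is the only HiVe that is a
#' trainable parameter; the per-input updates mu_1..mu_J are activations.
#'
#' @param n_hive Number of rows N_HV (>= 1).
#' @param dim Width d (>= 1); also the fan-in of the initialisation.
#' @param seed Integer seed; the same (n_hive, dim, seed) always yields the
#'   identical matrix.
#' @return An object of class `hive_state` with fields `mu`, `step_index = 0`
#'   and `learnable = TRUE`.
#' @export
init_hive <- function(n_hive, dim, seed = 0L) {
  if (n_hive < 1 || dim < 1) stop("n_hive and dim must be >= 1")
  mu <- with_seed(seed, kaiming_matrix(n_hive, dim, fan_in = dim))
  structure(list(mu = mu, step_index = 0L, learnable = TRUE),
            class = "hive_state")
}

# pre-norm Transformer block: cross-attention + feed-forward, residual around
# both sublayers; query-side and key/value-side layer norms are separate.
transformer_block_init <- function(d, n_heads, ffn_mult = 2L) {
  list(ln_q = layernorm_init(d), ln_kv = layernorm_init(d),
       mha = mha_init(d, n_heads), ln2 = layernorm_init(d),
       f1 = linear_init(d, ffn_mult * d), f2 = linear_init(ffn_mult * d, d))
}

transformer_block_fwd <- function(mu, E, p, n_heads) {
  qn <- layernorm_fwd(mu, p$ln_q)
  kvn <- layernorm_fwd(E, p$ln_kv)
  at <- mha_fwd(qn$out, kvn$out, p$mha, n_heads)
  h <- mu + at$out
  hn <- layernorm_fwd(h, p$ln2)
  z <- linear_fwd(hn$out, p$f1)
  a <- gelu(z)
  out <- h + linear_fwd(a, p$f2)
  list(out = out, attn = at$attn,
       cache = list(qn = qn, kvn = kvn, at = at, hn = hn, z = z, a = a, p = p))
}

transformer_block_backward <- function(cache, dout) {
  p <- cache$p
  l2 <- linear_bwd(cache$a, p$f2, dout)
  dz <- l2$dx * gelu_grad(cache$z)
  l1 <- linear_bwd(cache$hn$out, p$f1, dz)
  ln2b <- layernorm_bwd(cache$hn$cache, l1$dx)
  dh <- dout + ln2b$dx
  mb <- mha_bwd(cache$at$cache, dh)
  lnqb <- layernorm_bwd(cache$qn$cache, mb$d_query)
  lnkvb <- layernorm_bwd(cache$kvn$cache, mb$d_kv)
  dmu <- dh + lnqb$dx
  dE <- lnkvb$dx
  list(grads = list(ln_q = lnqb$grads, ln_kv = lnkvb$grads, mha = mb$grads,
                    ln2 = ln2b$grads, f1 = l1$grads, f2 = l2$grads),
       dmu = dmu, dE = dE)
}

#' One PICASO update step
#'
#' Applies one Transformer block to the HiVe: the current mu_j is the query,
#' the instance embeddings are key and value, and the block's
#' residual/normalisation/feed-forward composition produces mu_{j+1}.
#'
#' @param hive A `hive_state` (see [init_hive()]).
#' @param E Instance-embedding matrix, M x d.
#' @param params Block parameters from `transformer_block_init()`; if `NULL`,
#'   fresh parameters are drawn under `seed`.
#' @param n_heads Attention heads.
#' @param seed Seed used only when `params` is `NULL`.
#' @return A `hive_state` with updated `mu`, incremented `step_index`,
#'   `learnable = FALSE`, plus the attention weights as attribute `attn`.
#' @export
picaso_block <- function(hive, E, params = NULL, n_heads = 8L, seed = 1L) {
  if (ncol(hive$mu) != ncol(E)) {
    stop("HiVe width ", ncol(hive$mu), " does not match embedding width ", ncol(E))
  }
  if (is.null(params)) {
    params <- with_seed(seed, transformer_block_init(ncol(E), n_heads))
  }
  f <- transformer_block_fwd(hive$mu, E, params, n_heads)
  out <- structure(list(mu = f$out, step_index = hive$step_index + 1L,
                        learnable = FALSE),
                   class = "hive_state")
  attr(out, "attn") <- f$attn
  attr(out, "params") <- params
  out
}

# ---------------------------------------------------------------------------
# Parameter initialisation and forward/backward per operator
# ---------------------------------------------------------------------------

agg_init <- function(cfg) {
  d <- cfg$dim
  switch(cfg$operator,
    picaso = {
      n_blocks <- if (cfg$share_weights) 1L else cfg$n_steps
      list(mu0 = kaiming_matrix(cfg$n_hive, d, fan_in = d),
           blocks = lapply(seq_len(n_blocks), function(i)
             transformer_block_init(d, cfg$n_heads, cfg$ffn_mult)))
    },
    `deepset` = ,
    `deepset++` = {
      p <- list(phi1 = linear_init(d, d), phi2 = linear_init(d, d))
      if (cfg$operator == "deepset++") {
        p$eq <- list(W = kaiming_matrix(d, d), U = kaiming_matrix(d, d),
                     b = numeric(d))
      }
      if (cfg$weighted) {
        p$gate1 <- linear_init(d, d)
        p$gate2 <- linear_init(d, 1L)
      }
      p
    },
    `set_transformer` = ,
    `set_transformer++` = {
      list(seeds = kaiming_matrix(cfg$n_seeds, d, fan_in = d),
           sab = lapply(seq_len(cfg$n_sab), function(i)
             transformer_block_init(d, cfg$n_heads, cfg$ffn_mult)),
           pma = if (cfg$plain_pma) mha_init(d, cfg$n_heads)
                 else transformer_block_init(d, cfg$n_heads, cfg$ffn_mult))
    })
}

picaso_fwd <- function(E, cfg, params, trace = FALSE) {
  mu <- params$mu0
  caches <- vector("list", cfg$n_steps)
  attns <- if (trace) vector("list", cfg$n_steps) else NULL
  score_elems <- 0
  for (j in seq_len(cfg$n_steps)) {
    bp <- if (cfg$share_weights) params$blocks[[1]] else params$blocks[[j]]
    f <- transformer_block_fwd(mu, E, bp, cfg$n_heads)
    mu <- f$out
    caches[[j]] <- f$cache
    if (trace) attns[[j]] <- f$attn
    # every score matrix this step materialised: one N_HV x M matrix per head
    score_elems <- score_elems + cfg$n_heads * nrow(f$attn) * ncol(f$attn)
  }
  list(out = mu, caches = caches, attn_trace = attns,
       score_elements = score_elems)
}

picaso_bwd <- function(cfg, params, fwd, dout) {
  n_blocks <- if (cfg$share_weights) 1L else cfg$n_steps
  bgrads <- NULL
  dE <- NULL
  dmu <- dout
  for (j in rev(seq_len(cfg$n_steps))) {
    b <- transformer_block_backward(fwd$caches[[j]], dmu)
    dmu <- b$dmu
    dE <- if (is.null(dE)) b$dE else dE + b$dE
    if (cfg$share_weights) {
      bgrads <- if (is.null(bgrads)) list(b$grads) else
        list(tree_add(bgrads[[1]], b$grads))
    } else {
      if (is.null(bgrads)) bgrads <- vector("list", cfg$n_steps)
      bgrads[[j]] <- b$grads
    }
  }
  list(grads = list(mu0 = dmu, blocks = bgrads), dE = dE)
}

deepset_fwd <- function(E, cfg, params) {
  dEq <- NULL
  Ein <- E
  eq_cache <- NULL
  if (!is.null(params$eq)) {
    mbar <- colMeans(Ein)
    pre <- Ein %*% params$eq$W +
      matrix(mbar, nrow(Ein), length(mbar), byrow = TRUE) %*% params$eq$U
    pre <- sweep(pre, 2, params$eq$b, `+`)
    eq_cache <- list(Ein = Ein, pre = pre, mbar = mbar)
    Ein <- relu(pre)
  }
  z1 <- linear_fwd(Ein, params$phi1)
  h1 <- relu(z1)
  Fmat <- linear_fwd(h1, params$phi2)
  w <- NULL
  gate_cache <- NULL
  Fp <- Fmat
  if (cfg$weighted) {
    gz <- linear_fwd(Fmat, params$gate1)
    gh <- relu(gz)
    gl <- linear_fwd(gh, params$gate2) # M x 1 logits
    w <- drop(softmax_rows(t(gl)))    # softmax over the set
    gate_cache <- list(gz = gz, gh = gh, w = w)
    Fp <- Fmat * w
  }
  pooled <- switch(cfg$pool,
    max = apply(Fp, 2, max),
    mean = colMeans(Fp),
    sum = colSums(Fp))
  amax <- if (cfg$pool == "max") apply(Fp, 2, which.max) else NULL
  list(out = matrix(pooled, 1L),
       cache = list(E = E, Ein = Ein, eq = eq_cache, z1 = z1, h1 = h1,
                    Fmat = Fmat, Fp = Fp, gate = gate_cache, amax = amax,
                    M = nrow(E)))
}

deepset_bwd <- function(cfg, params, fwd, dout) {
  cc <- fwd$cache
  M <- cc$M
  dvec <- drop(dout)
  dFp <- matrix(0, M, length(dvec))
  if (cfg$pool == "max") {
    dFp[cbind(cc$amax, seq_along(dvec))] <- dvec
  } else if (cfg$pool == "mean") {
    dFp <- matrix(dvec / M, M, length(dvec), byrow = TRUE)
  } else {
    dFp <- matrix(dvec, M, length(dvec), byrow = TRUE)
  }
  grads <- list()
  if (cfg$weighted) {
    w <- cc$gate$w
    dF <- dFp * w
    dw <- rowSums(dFp * cc$Fmat)
    # softmax over the set: dl = w * (dw - sum(w * dw))
    dl <- w * (dw - sum(w * dw))
    g2 <- linear_bwd(cc$gate$gh, params$gate2, matrix(dl, M, 1L))
    dgh <- g2$dx * (cc$gate$gz > 0)
    g1 <- linear_bwd(cc$Fmat, params$gate1, dgh)
    dF <- dF + g1$dx
    grads$gate1 <- g1$grads
    grads$gate2 <- g2$grads
  } else {
    dF <- dFp
  }
  p2 <- linear_bwd(cc$h1, params$phi2, dF)
  dz1 <- p2$dx * (cc$z1 > 0)
  p1 <- linear_bwd(cc$Ein, params$phi1, dz1)
  grads$phi1 <- p1$grads
  grads$phi2 <- p2$grads
  dEin <- p1$dx
  if (!is.null(params$eq)) {
    dpre <- dEin * (cc$eq$pre > 0)
    grads$eq <- list(
      W = crossprod(cc$eq$Ein, dpre),
      U = crossprod(matrix(cc$eq$mbar, M, length(cc$eq$mbar), byrow = TRUE), dpre),
      b = colSums(dpre))
    dmean <- colSums(dpre %*% t(params$eq$U))
    dE <- dpre %*% t(params$eq$W) +
      matrix(dmean / M, M, length(dmean), byrow = TRUE)
  } else {
    dE <- dEin
  }
  # reorder grads to match param order for tree operations
  list(grads = grads[names(params)], dE = dE)
}

set_transformer_fwd <- function(E, cfg, params, trace = FALSE) {
  H <- E
  sab_caches <- vector("list", cfg$n_sab)
  for (s in seq_len(cfg$n_sab)) {
    f <- transformer_block_fwd(H, H, params$sab[[s]], cfg$n_heads)
    sab_caches[[s]] <- f$cache
    H <- f$out
  }
  if (cfg$plain_pma) {
    pm <- mha_fwd(params$seeds, H, params$pma, cfg$n_heads)
    out <- pm$out
    pma_cache <- pm$cache
    attn <- pm$attn
  } else {
    f <- transformer_block_fwd(params$seeds, H, params$pma, cfg$n_heads)
    out <- f$out
    pma_cache <- f$cache
    attn <- f$attn
  }
  list(out = out, caches = list(sab = sab_caches, pma = pma_cache),
       attn_trace = if (trace) list(attn) else NULL)
}

set_transformer_bwd <- function(cfg, params, fwd, dout) {
  if (cfg$plain_pma) {
    mb <- mha_bwd(fwd$caches$pma, dout)
    pma_grads <- mb$grads
    dseeds <- mb$d_query
    dH <- mb$d_kv
  } else {
    b <- transformer_block_backward(fwd$caches$pma, dout)
    pma_grads <- b$grads
    dseeds <- b$dmu
    dH <- b$dE
  }
  sab_grads <- vector("list", cfg$n_sab)
  for (s in rev(seq_len(cfg$n_sab))) {
    b <- transformer_block_backward(fwd$caches$sab[[s]], dH)
    sab_grads[[s]] <- b$grads
    dH <- b$dmu + b$dE # query and key/value are the same matrix
  }
  list(grads = list(seeds = dseeds, sab = sab_grads, pma = pma_grads),
       dE = dH)
}

agg_forward <- function(E, cfg, params, trace = FALSE) {
  switch(cfg$operator,
    picaso = picaso_fwd(E, cfg, params, trace),
    `deepset` = ,
    `deepset++` = deepset_fwd(E, cfg, params),
    `set_transformer` = ,
    `set_transformer++` = set_transformer_fwd(E, cfg, params, trace))
}

agg_backward <- function(cfg, params, fwd, dout) {
  switch(cfg$operator,
    picaso = picaso_bwd(cfg, params, fwd, dout),
    `deepset` = ,
    `deepset++` = deepset_bwd(cfg, params, fwd, dout),
    `set_transformer` = ,
    `set_transformer++` = set_transformer_bwd(cfg, params, fwd, dout))
}

# ---------------------------------------------------------------------------
# User-facing aggregator calls
# ---------------------------------------------------------------------------

#' Aggregate an instance set with the PICASO cascade
#'
#' Applies J cascaded Transformer blocks to the learnable initial HiVe mu0,
#' each using the current HiVe as query and the instance embeddings as key and
#' value. With `share_weights = TRUE` the same block parameters are reused at
#' every step, so the trainable parameter count is independent of J. The
#' attention score matrices are N_HV x M per head and step, hence compute and
#' storage grow linearly in the set size M.
#'
#' @param E Instance embeddings, M x d (M >= 1).
#' @param config An [aggregator_config()] with `operator = "picaso"`.
#' @param params Parameters from the internal initialiser; drawn fresh under
#'   `seed` when `NULL`.
#' @param trace If `TRUE`, record the J attention-weight matrices.
#' @param seed Seed used only when `params` is `NULL`.
#' @return List with `mu_final` (N_HV x d), `attention_trace` (list of
#'   N_HV x M matrices or `NULL`), `score_elements` (total attention-score
#'   entries materialised) and `params`.
#' @export
picaso_aggregate <- function(E, config, params = NULL, trace = FALSE,
                             seed = 1L) {
  stopifnot(inherits(config, "aggregator_config"), config$operator == "picaso")
  if (config$n_steps < 1) stop("n_steps (J) must be >= 1")
  if (is.null(params)) params <- with_seed(seed, agg_init(config))
  f <- picaso_fwd(E, config, params, trace)
  list(mu_final = f$out, attention_trace = f$attn_trace,
       score_elements = f$score_elements, params = params)
}

#' Aggregate an instance set with a DeepSet operator
#'
#' Per-instance feed-forward transform followed by symmetric pooling
#' (max/mean/sum). With `weighted = TRUE` a small gate network produces one
#' scalar per instance, softmax-normalised over the set and multiplied into
#' the instance features before pooling. The `"deepset++"` operator prepends a
#' permutation-equivariant layer mixing each instance with the set mean (a
#' documented simplified variant).
#'
#' @param E Instance embeddings, M x d.
#' @param pool `"max"`, `"mean"` or `"sum"`.
#' @param weighted Use softmax-normalised per-instance gates.
#' @param config Optional full [aggregator_config()]; built from the other
#'   arguments when `NULL`.
#' @param params,seed As in [picaso_aggregate()].
#' @return List with `out` (1 x d matrix) and `params`.
#' @export
deepset_aggregate <- function(E, pool = c("max", "mean", "sum"),
                              weighted = FALSE, config = NULL, params = NULL,
                              seed = 1L) {
  if (is.null(config)) {
    config <- aggregator_config("deepset", dim = ncol(E),
                                pool = match.arg(pool), weighted = weighted)
  }
  if (is.null(params)) params <- with_seed(seed, agg_init(config))
  f <- deepset_fwd(E, config, params)
  list(out = f$out, params = params)
}

#' Aggregate an instance set with a Set Transformer
#'
#' Self-attention block(s) over the instances followed by pooling by multihead
#' attention (PMA) onto `n_seeds` learnable seed vectors.
#'
#' @param E Instance embeddings, M x d.
#' @param n_seeds Number of learnable seeds.
#' @param config Optional full [aggregator_config()].
#' @param params,seed As in [picaso_aggregate()].
#' @return List with `out` (`n_seeds` x d) and `params`.
#' @export
set_transformer_aggregate <- function(E, n_seeds = 1L, config = NULL,
                                      params = NULL, seed = 1L) {
  if (is.null(config)) {
    config <- aggregator_config("set_transformer", dim = ncol(E),
                                n_seeds = n_seeds,
                                n_heads = if (ncol(E) %% 8 == 0) 8L else 1L)
  }
  if (is.null(params)) params <- with_seed(seed, agg_init(config))
  f <- set_transformer_fwd(E, config, params)
  list(out = f$out, params = params)
}

#' Soft K-means update in the attention limit
#'
#' The simplified attention update behind the K-means view of the cascade:
#' identity query/key/value projections, no feed-forward or residual path.
#' Scores between instance i and centroid k are either the negative squared
#' Euclidean distance or the dot product, divided by `temperature`; a softmax
#' over k per instance yields soft assignments, and each centroid is replaced
#' by its assignment-weighted mean of the instances. As `temperature -> 0`
#' with the distance score, this is exactly one Lloyd step of K-means (hard
#' nearest-centroid assignment, then cluster means); as
#' `temperature -> Inf` every centroid moves to the global mean.
#'
#' @param mu Centroid matrix, K x d.
#' @param X Instance matrix, M x d.
#' @param temperature Positive softness parameter.
#' @param score `"neg_sq_dist"` (default; makes the zero-temperature limit a
#'   Lloyd step) or `"dot"`.
#' @return Updated K x d centroid matrix. Centroids with (numerically) zero
#'   total assignment keep their previous value, matching the usual Lloyd
#'   convention for empty clusters.
#' @export
kmeans_limit_update <- function(mu, X, temperature,
                                score = c("neg_sq_dist", "dot")) {
  score <- match.arg(score)
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop("temperature must be a positive scalar")
  }
  if (ncol(mu) != ncol(X)) stop("mu and X widths differ")
  S <- if (score == "neg_sq_dist") {
    d2 <- outer(rowSums(X^2), rowSums(mu^2), `+`) - 2 * X %*% t(mu)
    -d2 / temperature
  } else {
    (X %*% t(mu)) / temperature
  }
  A <- softmax_rows(S) # M x K soft assignments
  w <- colSums(A)
  new_mu <- mu
  ok <- w > 0 # a centroid with exactly zero assignment keeps its value
  if (any(ok)) {
    new_mu[ok, ] <- (t(A[, ok, drop = FALSE]) %*% X) / w[ok]
  }
  new_mu
}

#' Iterate the soft K-means update to convergence
#'
#' @param X Instance matrix, M x d.
#' @param k Number of centroids.
#' @param temperature Softness; small values approach plain K-means.
#' @param max_iter,tol Iteration controls.
#' @param n_start Number of random restarts; the run with the lowest
#'   within-cluster sum of squares wins (the usual K-means practice, since
#'   the hard-assignment limit inherits K-means' local optima).
#' @param seed Seed for the initial centroids (random distinct rows of X).
#' @return List with `centers` (k x d), `cluster` (hard assignment per row of
#'   X), `withinss` (total within-cluster sum of squares) and `iterations`.
#' @export
kmeans_limit_cluster <- function(X, k, temperature = 1e-6, max_iter = 100L,
                                 tol = 1e-8, n_start = 10L, seed = 1L) {
  starts <- with_seed(seed, lapply(seq_len(n_start), function(s) {
    sample(nrow(X), k)
  }))
  best <- NULL
  for (st in starts) {
    mu <- X[st, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      mu_new <- kmeans_limit_update(mu, X, temperature)
      if (max(abs(mu_new - mu)) < tol) {
        mu <- mu_new
        break
      }
      mu <- mu_new
    }
    d2 <- outer(rowSums(X^2), rowSums(mu^2), `+`) - 2 * X %*% t(mu)
    cl <- max.col(-d2, ties.method = "first")
    wss <- sum(d2[cbind(seq_len(nrow(X)), cl)])
    if (is.null(best) || wss < best$withinss) {
      best <- list(centers = mu, cluster = cl, withinss = wss,
                   iterations = it)
    }
  }
  best
}
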