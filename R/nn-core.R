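# Minimal neural-network core: parameter initialisation, linear / layer-norm /
# multihead-attention layers with hand-derived backward passes, and Adam.
# Parameters live in plain named lists of numeric matrices/vectors so that a
# whole model can be traversed generically (counting, flattening, Adam).

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls do not perturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Kaiming (He) normal initialisation
#'
#' Draws an `n_out` x `n_in`-shaped matrix (rows = units reading `fan_in`
#' inputs) with zero mean and variance `2 / fan_in`, the scheme used for the
#' initial HiVe and all weight matrices.
#'
#' @param n_row,n_col Matrix shape.
#' @param fan_in Fan-in used for the variance; defaults to `n_col`.
#' @return A `n_row` x `n_col` numeric matrix.
#' @keywords internal
kaiming_matrix <- function(n_row, n_col, fan_in = n_col) {
  matrix(stats::rnorm(n_row * n_col, sd = sqrt(2 / fan_in)), n_row, n_col)
}

linear_init <- function(d_in, d_out) {
  list(W = kaiming_matrix(d_in, d_out, fan_in = d_in), b = numeric(d_out))
}

linear_fwd <- function(x, p) {
  x %*% p$W + rep(p$b, each = nrow(x))
}

# backward for y = x W + b given upstream dy; returns grads and dx
linear_bwd <- function(x, p, dy) {
  list(grads = list(W = crossprod(x, dy), b = colSums(dy)),
       dx = dy %*% t(p$W))
}

layernorm_init <- function(d) {
  list(g = rep(1, d), b = numeric(d))
}

# row-wise layer normalisation; population variance, eps for stability
layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(x)
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(out = y, cache = list(xhat = xhat, inv = inv, p = p))
}

layernorm_bwd <- function(cache, dy) {
  xhat <- cache$xhat
  dxhat <- dy * rep(cache$p$g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(grads = list(g = colSums(dy * xhat), b = colSums(dy)), dx = dx)
}

gelu <- function(x) {
  0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  u <- 0.7978845608028654 * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * 0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
}

relu <- function(x) pmax(x, 0)

#' Row-wise softmax
#' @param s Numeric matrix of scores.
#' @return Matrix of the same shape; each row nonnegative, summing to 1.
#' @keywords internal
softmax_rows <- function(s) {
  s <- s - s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---------------------------------------------------------------------------
# Multihead scaled-dot-product cross-attention
# ---------------------------------------------------------------------------

mha_init <- function(d, n_heads) {
  if (d %% n_heads != 0) {
    stop("model dimension ", d, " is not divisible by n_heads = ", n_heads)
  }
  list(Wq = kaiming_matrix(d, d), Wk = kaiming_matrix(d, d),
       Wv = kaiming_matrix(d, d), Wo = kaiming_matrix(d, d),
       bq = numeric(d), bk = numeric(d), bv = numeric(d), bo = numeric(d))
}

#' Multihead cross-attention between a query matrix and a set of key/values
#'
#' Standard scaled dot-product attention with separate query/key/value
#' projections and an output projection. Scores are scaled by
#' `1 / sqrt(d / n_heads)`. Because every key/value row enters only through a
#' row-wise softmax and a weighted sum, the output is invariant to any
#' permutation of the rows of `kv`.
#'
#' @param query Numeric matrix, `n_q` x `d` (for PICASO the HiVe).
#' @param kv Numeric matrix, `M` x `d` (the instance embeddings).
#' @param p Parameter list from `mha_init()`.
#' @param n_heads Number of attention heads; must divide `d`.
#' @return List with `out` (`n_q` x `d`), `attn` (head-averaged attention
#'   weights, `n_q` x `M`, rows on the probability simplex) and `cache` for the
#'   backward pass.
#' @keywords internal
mha_fwd <- function(query, kv, p, n_heads) {
  d <- ncol(query)
  if (d %% n_heads != 0) {
    stop("model dimension ", d, " is not divisible by n_heads = ", n_heads)
  }
  if (ncol(kv) != d) stop("query and kv dimensions differ: ", d, " vs ", ncol(kv))
  dh <- d %/% n_heads
  Q <- linear_fwd(query, list(W = p$Wq, b = p$bq))
  K <- linear_fwd(kv, list(W = p$Wk, b = p$bk))
  V <- linear_fwd(kv, list(W = p$Wv, b = p$bv))
  O <- matrix(0, nrow(query), d)
  A <- vector("list", n_heads)
  attn <- matrix(0, nrow(query), nrow(kv))
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    attn <- attn + A[[h]]
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- linear_fwd(O, list(W = p$Wo, b = p$bo))
  list(out = out, attn = attn / n_heads,
       cache = list(query = query, kv = kv, Q = Q, K = K, V = V, O = O,
                    A = A, p = p, n_heads = n_heads, dh = dh))
}

mha_bwd <- function(cache, dout) {
  p <- cache$p
  dh <- cache$dh
  n_heads <- cache$n_heads
  d <- ncol(cache$query)
  lo <- linear_bwd(cache$O, list(W = p$Wo, b = p$bo), dout)
  dO <- lo$dx
  dQ <- matrix(0, nrow(cache$Q), d)
  dK <- matrix(0, nrow(cache$K), d)
  dV <- matrix(0, nrow(cache$V), d)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(cache$V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  lq <- linear_bwd(cache$query, list(W = p$Wq, b = p$bq), dQ)
  lk <- linear_bwd(cache$kv, list(W = p$Wk, b = p$bk), dK)
  lv <- linear_bwd(cache$kv, list(W = p$Wv, b = p$bv), dV)
  list(grads = list(Wq = lq$grads$W, Wk = lk$grads$W, Wv = lv$grads$W,
                    Wo = lo$grads$W, bq = lq$grads$b, bk = lk$grads$b,
                    bv = lv$grads$b, bo = lo$grads$b),
       d_query = lq$dx, d_kv = lk$dx + lv$dx)
}

#' Multihead cross-attention (functional convenience wrapper)
#'
#' @inheritParams mha_fwd
#' @param params Parameter list from `mha_init()`; if `NULL`, fresh parameters
#'   are drawn under `seed`.
#' @param seed Seed used only when `params` is `NULL`.
#' @return List with `out` and `attn` (see [mha_fwd()]).
#' @export
multihead_cross_attention <- function(query, kv, n_heads, params = NULL,
                                      seed = 1L) {
  if (is.null(params)) {
    params <- with_seed(seed, mha_init(ncol(query), n_heads))
  }
  f <- mha_fwd(query, kv, params, n_heads)
  list(out = f$out, attn = f$attn, params = params)
}

# ---------------------------------------------------------------------------
# Parameter-tree utilities and Adam
# ---------------------------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros_like <- function(x) tree_map(function(e) e * 0, x)

tree_add <- function(x, y) tree_map2(`+`, x, y)

tree_scale <- function(x, s) tree_map(function(e) e * s, x)

#' Count trainable parameters in a parameter tree
#' @param params Nested list of numeric arrays.
#' @return Total number of scalar parameters.
#' @export
n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1))) else length(params)
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
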