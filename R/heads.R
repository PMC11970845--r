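# Prediction heads on top of an aggregated HiVe: a per-instance anomaly head
# (which glomerular crop carries the lesion) and a per-set binary head.

head_init <- function(type = c("instance", "set"), d, n_hive = 1L,
                      mode = c("vector", "scalar")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  if (type == "instance") {
    d_in <- if (mode == "vector") d else 1L
    list(w = matrix(stats::rnorm(d_in, sd = sqrt(2 / d_in)), d_in, 1L), b = 0)
  } else {
    d_in <- d * n_hive
    list(w = matrix(stats::rnorm(d_in, sd = sqrt(2 / d_in)), d_in, 1L), b = 0)
  }
}

instance_head_fwd <- function(E, mu, params, mode = "vector") {
  if (nrow(mu) != 1) {
    stop("the instance anomaly head requires N_HV = 1 (got ", nrow(mu), ")")
  }
  diff <- E - rep(drop(mu), each = nrow(E))
  dev_mat <- abs(diff)           # elementwise |E_i - mu|
  deviations <- rowSums(dev_mat) # per-instance L1 distance
  logits <- if (mode == "vector") {
    drop(dev_mat %*% params$w) + params$b
  } else {
    deviations * drop(params$w) + params$b
  }
  list(logits = logits, scores = sigmoid(logits), deviations = deviations,
       cache = list(sgn = sign(diff), dev_mat = dev_mat,
                    deviations = deviations, mode = mode))
}

instance_head_bwd <- function(params, cache, dlogits) {
  sgn <- cache$sgn
  if (cache$mode == "vector") {
    gw <- crossprod(cache$dev_mat, matrix(dlogits, ncol = 1L))
    ddev <- matrix(dlogits, ncol = 1L) %*% t(params$w) # M x d into |.|
  } else {
    gw <- matrix(sum(dlogits * cache$deviations), 1L, 1L)
    ddev <- matrix(dlogits * drop(params$w), nrow(sgn), ncol(sgn))
  }
  dE <- ddev * sgn
  dmu <- matrix(-colSums(dE), 1L)
  list(grads = list(w = gw, b = sum(dlogits)), dE = dE, dmu = dmu)
}

set_head_fwd <- function(mu, params) {
  x <- as.vector(t(mu)) # flatten N_HV x d row-wise
  logit <- sum(x * params$w) + params$b
  list(logit = logit, prob = sigmoid(logit),
       cache = list(x = x, shape = dim(mu)))
}

set_head_bwd <- function(params, cache, dlogit) {
  dmu <- matrix(drop(params$w) * dlogit, cache$shape[1], cache$shape[2],
                byrow = TRUE)
  list(grads = list(w = matrix(cache$x * dlogit, ncol = 1L), b = dlogit),
       dmu = dmu)
}

#' Per-instance anomaly scores from the L1 deviation to the aggregated HiVe
#'
#' For N_HV = 1 the final HiVe is an attention-weighted mean of the instance
#' embeddings, so an instance carrying a lesion stands out by its distance
#' from it. The head computes the elementwise absolute difference
#' `|E_i - mu|` per instance, feeds it through a shared affine output layer
#' (one logit per instance) and a sigmoid. `mode = "scalar"` instead feeds the
#' scalar L1 distance itself through the affine layer.
#'
#' @param E Instance embeddings, M x d (the same matrix the aggregator saw).
#' @param mu_final Aggregated HiVe, 1 x d.
#' @param params Head parameters (`w`, `b`); drawn under `seed` when `NULL`.
#' @param mode `"vector"` (default) or `"scalar"`.
#' @param case_id Optional identifier carried through to the result.
#' @param seed Seed used only when `params` is `NULL`.
#' @return An `instance_score_prediction`: list with `case_id`, `scores`
#'   (length-M probabilities), `deviations` (length-M nonnegative L1
#'   distances) and `logits`. Permuting the rows of `E` permutes all three
#'   identically.
#' @export
instance_anomaly_head <- function(E, mu_final, params = NULL,
                                  mode = c("vector", "scalar"),
                                  case_id = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(params)) {
    params <- with_seed(seed, head_init("instance", ncol(E), mode = mode))
  }
  f <- instance_head_fwd(E, mu_final, params, mode)
  structure(list(case_id = case_id, scores = f$scores,
                 deviations = f$deviations, logits = f$logits,
                 params = params),
            class = "instance_score_prediction")
}

#' Per-set binary probability from the aggregated HiVe
#'
#' Flattens the final HiVe, applies one affine layer and a sigmoid. The
#' predicted label is 1 when the probability is at least 0.5 (ties classified
#' positive).
#'
#' @param mu_final Aggregated HiVe, N_HV x d.
#' @param params Head parameters (`w`, `b`); drawn under `seed` when `NULL`.
#' @param case_id Optional identifier.
#' @param seed Seed used only when `params` is `NULL`.
#' @return A `set_label_prediction`: list with `case_id`, `probability` and
#'   `label_hat`.
#' @export
set_classification_head <- function(mu_final, params = NULL, case_id = NULL,
                                    seed = 1L) {
  if (is.null(params)) {
    params <- with_seed(seed, head_init("set", ncol(mu_final),
                                        n_hive = nrow(mu_final)))
  }
  f <- set_head_fwd(mu_final, params)
  structure(list(case_id = case_id, probability = f$prob,
                 label_hat = as.integer(f$prob >= 0.5), params = params),
            class = "set_label_prediction")
}
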