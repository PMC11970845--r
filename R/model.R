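# A full set model: per-instance encoder -> linear projection to the
# aggregator width -> permutation-invariant aggregator -> task head.

#' Build a set model
#'
#' Composes an encoder, a set aggregator and a task head into one trainable
#' model. A linear projection from the encoder width d_E to the aggregator
#' width d is inserted automatically when the two differ.
#'
#' @param encoder An [encoder_spec()].
#' @param aggregator An [aggregator_config()].
#' @param head `"instance"` (per-instance lesion probabilities from the L1
#'   deviation to the aggregated HiVe; requires an aggregator with a single
#'   output row) or `"set"` (one probability per set).
#' @param head_mode For the instance head: `"vector"` (elementwise absolute
#'   differences feed the output layer) or `"scalar"` (the scalar L1
#'   distance does).
#' @param seed Seed for all parameter initialisation.
#' @return An object of class `set_model`.
#' @export
set_model <- function(encoder, aggregator, head = c("instance", "set"),
                      head_mode = c("vector", "scalar"), seed = 1L) {
  head <- match.arg(head)
  head_mode <- match.arg(head_mode)
  stopifnot(inherits(encoder, "encoder_spec"),
            inherits(aggregator, "aggregator_config"))
  d <- aggregator$dim
  params <- with_seed(seed, {
    p <- list(encoder = encoder_init(encoder))
    if (encoder$out_dim != d) p$proj <- linear_init(encoder$out_dim, d)
    p$agg <- agg_init(aggregator)
    n_out_rows <- switch(aggregator$operator,
                         picaso = aggregator$n_hive,
                         deepset = , `deepset++` = 1L,
                         aggregator$n_seeds)
    p$head <- head_init(head, d, n_hive = n_out_rows, mode = head_mode)
    p
  })
  structure(list(encoder = encoder, aggregator = aggregator, head = head,
                 head_mode = head_mode, params = params, seed = seed),
            class = "set_model")
}

#' @export
print.set_model <- function(x, ...) {
  cat("<set_model> operator:", x$aggregator$operator,
      " d:", x$aggregator$dim,
      " J:", if (x$aggregator$operator == "picaso") x$aggregator$n_steps else NA,
      " head:", x$head,
      " params:", n_params(x$params), "\n")
  invisible(x)
}

model_forward <- function(model, x, trace = FALSE) {
  p <- model$params
  enc <- encoder_fwd(x, model$encoder, p$encoder)
  E0 <- enc$E
  E1 <- if (!is.null(p$proj)) linear_fwd(E0, p$proj) else E0
  ag <- agg_forward(E1, model$aggregator, p$agg, trace)
  mu <- ag$out
  if (model$head == "instance") {
    hf <- instance_head_fwd(E1, mu, p$head, model$head_mode)
    logits <- hf$logits
  } else {
    hf <- set_head_fwd(mu, p$head)
    logits <- hf$logit
  }
  list(logits = logits, probs = sigmoid(logits), mu = mu, E = E1,
       attn_trace = ag$attn_trace, score_elements = ag$score_elements,
       cache = list(enc = enc, E0 = E0, E1 = E1, ag = ag, head = hf))
}

model_backward <- function(model, fwd, dlogits) {
  p <- model$params
  cc <- fwd$cache
  if (model$head == "instance") {
    hb <- instance_head_bwd(p$head, cc$head$cache, dlogits)
    dmu <- hb$dmu
    dE1 <- hb$dE
  } else {
    hb <- set_head_bwd(p$head, cc$head$cache, dlogits)
    dmu <- hb$dmu
    dE1 <- 0
  }
  ab <- agg_backward(model$aggregator, p$agg, cc$ag, dmu)
  dE1 <- dE1 + ab$dE
  grads <- list(encoder = NULL, proj = NULL, agg = ab$grads, head = hb$grads)
  if (!is.null(p$proj)) {
    pb <- linear_bwd(cc$E0, p$proj, dE1)
    grads$proj <- pb$grads
    dE0 <- pb$dx
  } else {
    dE0 <- dE1
  }
  eb <- encoder_bwd(model$encoder, p$encoder, cc$enc, dE0)
  grads$encoder <- eb$grads
  grads[!vapply(grads, is.null, logical(1))]
}

#' Predict on one instance set
#'
#' @param model A trained [set_model()].
#' @param x A list of images or an M x d_E matrix, depending on the encoder.
#' @param case_id Optional identifier attached to the prediction.
#' @param trace Record attention weights (attention-based aggregators).
#' @return For an instance head, an `instance_score_prediction`; for a set
#'   head, a `set_label_prediction`. Attention traces, when requested, are in
#'   attribute `attn_trace`.
#' @export
predict_set <- function(model, x, case_id = NULL, trace = FALSE) {
  f <- model_forward(model, x, trace)
  out <- if (model$head == "instance") {
    structure(list(case_id = case_id, scores = f$probs,
                   deviations = f$cache$head$cache$deviations,
                   logits = f$logits),
              class = "instance_score_prediction")
  } else {
    structure(list(case_id = case_id, probability = f$probs,
                   label_hat = as.integer(f$probs >= 0.5)),
              class = "set_label_prediction")
  }
  if (trace) attr(out, "attn_trace") <- f$attn_trace
  out
}

# numerically stable binary cross entropy; returns loss and dlogits
bce_loss <- function(logits, y) {
  z <- as.numeric(logits)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, dlogits = (sigmoid(z) - y) / length(z))
}

# ---------------------------------------------------------------------------
# Config / checkpoint serialisation
# ---------------------------------------------------------------------------

#' Write a model configuration to YAML (or JSON)
#'
#' Serialises the encoder spec, aggregator config and head choice so an
#' identical architecture can be rebuilt elsewhere.
#'
#' @param model A [set_model()].
#' @param path Output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(encoder = unclass(model$encoder[c("name", "out_dim",
                                                "projection_dim", "channels",
                                                "input_size")]),
              aggregator = unclass(model$aggregator),
              head = model$head, head_mode = model$head_mode,
              seed = model$seed)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Rebuild an (untrained) model from a configuration file
#' @param path File written by [write_model_config()].
#' @return A fresh [set_model()] with parameters drawn under the stored seed.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  enc <- do.call(encoder_spec, cfg$encoder)
  agg_args <- cfg$aggregator
  if (identical(agg_args$operator, "set_transformer++")) {
    agg_args$n_sab <- agg_args$n_sab - 1L # constructor re-adds the extra block
  }
  agg <- do.call(aggregator_config, agg_args)
  set_model(enc, agg, head = cfg$head, head_mode = cfg$head_mode,
            seed = cfg$seed)
}

#' Save / load a trained model
#'
#' Standard R serialisation of the whole model object (architecture plus
#' parameters).
#'
#' @param model A [set_model()].
#' @param path Checkpoint file (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
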