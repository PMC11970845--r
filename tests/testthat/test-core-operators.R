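# Core set operators: HiVe initialisation, cross-attention, the PICASO
# cascade, and the baseline aggregators.

test_that("init_hive draws Kaiming-distributed, seed-reproducible HiVe", {
  h <- init_hive(1, 512, seed = 0)
  expect_identical(dim(h$mu), c(1L, 512L))
  expect_true(h$learnable)
  expect_identical(h$step_index, 0L)

  expect_identical(init_hive(3, 32, seed = 5)$mu, init_hive(3, 32, seed = 5)$mu)
  expect_false(identical(init_hive(3, 32, seed = 5)$mu,
                         init_hive(3, 32, seed = 6)$mu))

  # empirical variance over >= 1e4 entries should match 2 / fan_in
  h_big <- init_hive(40, 256, seed = 1)
  v <- stats::var(as.vector(h_big$mu))
  expect_gt(v, (2 / 256) * 0.7)
  expect_lt(v, (2 / 256) * 1.3)
  expect_lt(abs(mean(h_big$mu)), 0.005)

  expect_error(init_hive(0, 16), "must be >= 1")
  expect_error(init_hive(1, 0), "must be >= 1")
})

test_that("multihead cross-attention has softmax structure and is invariant
           to key/value permutation", {
  set.seed(11)
  q <- rand_embeddings(2, 16)

  # single key: softmax over one logit is exactly 1
  v <- rand_embeddings(1, 16)
  one <- multihead_cross_attention(q, v, n_heads = 4)
  expect_equal(as.vector(one$attn), c(1, 1))

  # identical keys: uniform weights, output equal to the M = 1 case
  rep8 <- multihead_cross_attention(q, v[rep(1, 8), ], n_heads = 4,
                                    params = one$params)
  expect_equal(rep8$attn, matrix(1 / 8, 2, 8))
  expect_equal(rep8$out, one$out, tolerance = 1e-10)

  # permutation invariance over random sets and permutations
  for (r in 1:20) {
    M <- sample(1:32, 1)
    E <- rand_embeddings(M, 16)
    f1 <- multihead_cross_attention(q, E, n_heads = 4, params = one$params)
    pi <- sample(M)
    f2 <- multihead_cross_attention(q, E[pi, , drop = FALSE], n_heads = 4,
                                    params = one$params)
    expect_lt(max(abs(f1$out - f2$out)), 1e-5)
    expect_equal(f1$attn, f2$attn[, order(pi), drop = FALSE],
                 tolerance = 1e-10)
  }

  expect_error(multihead_cross_attention(q, rand_embeddings(3, 16),
                                         n_heads = 5),
               "not divisible")
})

test_that("picaso_block updates the HiVe invariantly in set order and under
           instance duplication", {
  set.seed(21)
  h <- init_hive(1, 24, seed = 3)
  params <- with(list(), picaso:::with_seed(9,
    picaso:::transformer_block_init(24, 4)))
  for (M in c(1, 4, 8, 64)) {
    E <- rand_embeddings(M, 24)
    out <- picaso_block(h, E, params = params, n_heads = 4)
    expect_identical(dim(out$mu), c(1L, 24L))
    expect_identical(out$step_index, 1L)
    expect_false(out$learnable)
  }
  E <- rand_embeddings(3, 24)
  o1 <- picaso_block(h, E, params = params, n_heads = 4)
  o2 <- picaso_block(h, E[c(3, 1, 2), ], params = params, n_heads = 4)
  expect_lt(max(abs(o1$mu - o2$mu)), 1e-5)
  # duplicating every instance halves the softmax weights but leaves the
  # weighted sums unchanged
  o3 <- picaso_block(h, rbind(E, E), params = params, n_heads = 4)
  expect_lt(max(abs(o1$mu - o3$mu)), 1e-5)
  expect_error(picaso_block(h, rand_embeddings(3, 8), params = params),
               "width")
})

test_that("picaso_aggregate: weight sharing fixes the parameter count, the
           cascade stays permutation invariant, and attention rows are on the
           simplex", {
  cfgJ <- function(J, share = TRUE) {
    aggregator_config("picaso", dim = 32, n_heads = 4, n_steps = J,
                      share_weights = share)
  }
  counts <- vapply(c(1, 2, 4), function(J) {
    n_params(picaso:::with_seed(1, picaso:::agg_init(cfgJ(J))))
  }, numeric(1))
  expect_true(all(counts == counts[1]))

  # without sharing the count grows affinely in J
  counts_ns <- vapply(1:4, function(J) {
    n_params(picaso:::with_seed(1, picaso:::agg_init(cfgJ(J, FALSE))))
  }, numeric(1))
  expect_true(all(diff(diff(counts_ns)) == 0))
  expect_gt(diff(counts_ns)[1], 0)

  set.seed(5)
  E <- rand_embeddings(12, 32)
  a1 <- picaso_aggregate(E, cfgJ(3), trace = TRUE, seed = 2)
  a2 <- picaso_aggregate(E[sample(12), ], cfgJ(3), params = a1$params)
  expect_lt(max(abs(a1$mu_final - a2$mu_final)), 1e-5)
  expect_length(a1$attention_trace, 3)
  for (A in a1$attention_trace) {
    expect_true(all(A >= 0))
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  }
  expect_error(aggregator_config("picaso", dim = 32, n_heads = 4, n_steps = 0),
               "J")
})

test_that("attention score storage grows linearly in the set size", {
  cfg <- aggregator_config("picaso", dim = 32, n_heads = 4, n_steps = 3)
  params <- picaso:::with_seed(1, picaso:::agg_init(cfg))
  elems <- vapply(c(8, 64, 512), function(M) {
    picaso_aggregate(rand_embeddings(M, 32, seed = M), cfg,
                     params = params)$score_elements
  }, numeric(1))
  expect_equal(elems, 3 * 4 * 1 * c(8, 64, 512))
  expect_lt(elems[3], 512^2) # nothing quadratic in M is materialised
})

test_that("deepset pooling behaves symmetrically; sum is duplication
           sensitive while mean is not", {
  set.seed(31)
  d <- 16
  v <- rnorm(d)
  cfg_mean <- aggregator_config("deepset", dim = d, pool = "mean")
  params <- picaso:::with_seed(4, picaso:::agg_init(cfg_mean))

  # identical rows through mean pooling give the per-instance transform of v
  same <- matrix(v, 5, d, byrow = TRUE)
  out_same <- deepset_aggregate(same, config = cfg_mean, params = params)$out
  out_one <- deepset_aggregate(matrix(v, 1), config = cfg_mean,
                               params = params)$out
  expect_equal(out_same, out_one, tolerance = 1e-12)

  E <- rand_embeddings(6, d)
  for (pool in c("max", "mean", "sum")) {
    cfg <- aggregator_config("deepset", dim = d, pool = pool)
    p <- picaso:::with_seed(4, picaso:::agg_init(cfg))
    o1 <- deepset_aggregate(E, config = cfg, params = p)$out
    o2 <- deepset_aggregate(E[sample(6), ], config = cfg, params = p)$out
    expect_lt(max(abs(o1 - o2)), 1e-5)
  }

  E3 <- rand_embeddings(3, d)
  dup <- rbind(E3, E3[2, ])
  cfg_sum <- aggregator_config("deepset", dim = d, pool = "sum")
  p_sum <- picaso:::with_seed(4, picaso:::agg_init(cfg_sum))
  o_sum <- deepset_aggregate(E3, config = cfg_sum, params = p_sum)$out
  o_sum_dup <- deepset_aggregate(dup, config = cfg_sum, params = p_sum)$out
  expect_gt(max(abs(o_sum - o_sum_dup)), 1e-6)

  o_mean <- deepset_aggregate(E3, config = cfg_mean, params = params)$out
  o_mean_dup <- deepset_aggregate(rbind(E3, E3), config = cfg_mean,
                                  params = params)$out
  expect_lt(max(abs(o_mean - o_mean_dup)), 1e-10)

  # weighted and ++ variants keep permutation invariance
  for (op in list(aggregator_config("deepset", dim = d, pool = "max",
                                    weighted = TRUE),
                  aggregator_config("deepset++", dim = d, pool = "max"))) {
    p <- picaso:::with_seed(4, picaso:::agg_init(op))
    o1 <- deepset_aggregate(E, config = op, params = p)$out
    o2 <- deepset_aggregate(E[sample(6), ], config = op, params = p)$out
    expect_lt(max(abs(o1 - o2)), 1e-5)
  }
  expect_error(aggregator_config("deepset", dim = d, pool = "median"))
})

test_that("set transformer is permutation invariant, shape stable, and its
           plain pooling step equals raw cross-attention of the seeds", {
  d <- 16
  cfg <- aggregator_config("set_transformer", dim = d, n_heads = 4,
                           n_seeds = 2)
  p <- picaso:::with_seed(6, picaso:::agg_init(cfg))
  for (M in c(1, 2, 8, 64)) {
    o <- set_transformer_aggregate(rand_embeddings(M, d, seed = M),
                                   config = cfg, params = p)
    expect_identical(dim(o$out), c(2L, as.integer(d)))
  }
  set.seed(41)
  E <- rand_embeddings(9, d)
  o1 <- set_transformer_aggregate(E, config = cfg, params = p)$out
  o2 <- set_transformer_aggregate(E[sample(9), ], config = cfg, params = p)$out
  expect_lt(max(abs(o1 - o2)), 1e-5)

  # no self-attention + plain PMA with one seed == multihead cross-attention
  cfg0 <- aggregator_config("set_transformer", dim = d, n_heads = 4,
                            n_seeds = 1, n_sab = 0, plain_pma = TRUE)
  p0 <- picaso:::with_seed(6, picaso:::agg_init(cfg0))
  o_st <- set_transformer_aggregate(E, config = cfg0, params = p0)$out
  o_mha <- multihead_cross_attention(p0$seeds, E, n_heads = 4,
                                     params = p0$pma)$out
  expect_equal(o_st, o_mha, tolerance = 1e-12)

  # the ++ variant adds one self-attention block and stays invariant
  cfgpp <- aggregator_config("set_transformer++", dim = d, n_heads = 4)
  ppp <- picaso:::with_seed(6, picaso:::agg_init(cfgpp))
  expect_length(ppp$sab, 2)
  o1 <- picaso:::set_transformer_fwd(E, cfgpp, ppp)$out
  o2 <- picaso:::set_transformer_fwd(E[sample(9), ], cfgpp, ppp)$out
  expect_lt(max(abs(o1 - o2)), 1e-5)
})

test_that("the soft K-means update reproduces a Lloyd step at low
           temperature and collapses to the global mean at high temperature", {
  set.seed(51)
  for (r in 1:25) {
    M <- sample(5:50, 1)
    K <- sample(2:5, 1)
    d <- sample(2:4, 1)
    X <- matrix(rnorm(M * d, sd = 2), M, d)
    mu <- X[sample(M, K), , drop = FALSE] + rnorm(K * d, sd = 0.1)
    expect_lt(max(abs(kmeans_limit_update(mu, X, 1e-6) - lloyd_step(mu, X))),
              1e-4)
  }

  # identical points: every centroid moves onto the common point
  p <- c(1, -2, 3)
  Xp <- matrix(p, 10, 3, byrow = TRUE)
  mu <- matrix(rnorm(9), 3)
  expect_equal(kmeans_limit_update(mu, Xp, 0.5),
               matrix(p, 3, 3, byrow = TRUE), tolerance = 1e-8)

  # infinite-temperature limit: uniform assignment, global mean
  X <- matrix(rnorm(40), 20, 2)
  mu <- matrix(rnorm(6), 3)
  hot <- kmeans_limit_update(mu, X, 1e9)
  expect_equal(hot, matrix(colMeans(X), 3, 2, byrow = TRUE),
               tolerance = 1e-5)

  expect_error(kmeans_limit_update(mu, X, 0), "positive")
  expect_error(kmeans_limit_update(mu, X, -1), "positive")
  # dot-product score variant is exposed too
  expect_identical(dim(kmeans_limit_update(mu, X, 1, score = "dot")),
                   dim(mu))
})
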