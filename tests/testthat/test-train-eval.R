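# Metrics against independent oracles, bootstrap machinery, paired
# comparisons, training behaviour and the two sweeps.

test_that("rank-based AUROC matches the pairwise oracle and hand-computed
           toys", {
  # 1 positive vs 3 negatives: perfect ranking, then a positive that wins
  # exactly one of its three pairwise comparisons (0.2 beats only 0.1)
  expect_identical(auroc(c(0.9, 0.2, 0.3, 0.1), c(1, 0, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.3, 0.1), c(0, 1, 0, 0)), 1 / 3)
  expect_equal(auroc_pairwise(c(0.9, 0.2, 0.3, 0.1), c(0, 1, 0, 0)), 1 / 3)

  set.seed(12)
  for (r in 1:8) {
    n <- sample(50:400, 1)
    sc <- round(runif(n), 2) # rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(sc, y), auroc_pairwise(sc, y), tolerance = 1e-9)
    expect_equal(aupr(sc, y), aupr_threshold(sc, y), tolerance = 1e-9)
  }

  # perfect scores
  y <- rep(c(1, 0), 20)
  expect_identical(auroc(y, y), 1)
  expect_identical(aupr(y, y), 1)
  # chance level
  set.seed(13)
  sc <- runif(1000)
  y <- rep(0:1, 500)
  expect_lt(abs(auroc(sc, y) - 0.5), 0.05)
  expect_error(auroc(c(1, 2), c(1, 1)), "single-class")
  expect_error(aupr(c(1, 2), c(0, 0)), "single-class")
})

test_that("evaluate() reports coherent metrics and bootstrap CIs that cover
           the point estimate and shrink with n", {
  make_cache <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      y <- rbinom(1, 1, 0.5)
      list(scores = plogis(rnorm(1, mean = 1.2 * (2 * y - 1))), y = y)
    })
  }
  r100 <- picaso:::report_from_cache(make_cache(100, 1), "set",
                                     n_bootstrap = 400, seed = 2)
  r1000 <- picaso:::report_from_cache(make_cache(1000, 1), "set",
                                      n_bootstrap = 400, seed = 2)
  for (r in list(r100, r1000)) {
    expect_true(all(r$metrics >= 0 & r$metrics <= 1))
    for (m in names(r$metrics)) {
      ci <- r$ci[r$ci$metric == m, ]
      expect_lte(ci$low, r$metrics[[m]])
      expect_gte(ci$high, r$metrics[[m]])
    }
  }
  w100 <- with(r100$ci[r100$ci$metric == "auroc", ], high - low)
  w1000 <- with(r1000$ci[r1000$ci$metric == "auroc", ], high - low)
  expect_lt(w1000, w100)
})

test_that("paired comparison: self yields P = 1, a real gap yields
           P < 0.001, and the matrix is symmetric", {
  set.seed(14)
  n <- 500
  ys <- rbinom(n, 1, 0.5)
  perfect <- lapply(seq_len(n), function(i) {
    list(scores = ys[i] * 0.98 + 0.01, y = ys[i])
  })
  noise <- lapply(seq_len(n), function(i) {
    list(scores = runif(1), y = ys[i])
  })
  rp <- picaso:::report_from_cache(perfect, "set", n_bootstrap = 0)
  rn <- picaso:::report_from_cache(noise, "set", n_bootstrap = 0)
  expect_equal(unname(rp$metrics["auroc"]), 1)

  P <- compare_operators(list(perfect = rp, noise = rn), metric = "auroc",
                         n_bootstrap = 10000, seed = 3)
  expect_lt(P["perfect", "noise"], 0.001)
  expect_identical(P["perfect", "noise"], P["noise", "perfect"])

  Pself <- compare_operators(list(a = rp, b = rp), n_bootstrap = 500,
                             seed = 4)
  expect_identical(Pself["a", "b"], 1)

  bad <- picaso:::report_from_cache(noise[1:10], "set", n_bootstrap = 0)
  expect_error(compare_operators(list(rp, bad)), "not paired")
})

test_that("training is seed-reproducible and reduces the loss on a
           separable vector task", {
  set.seed(15)
  d <- 8
  sets <- lapply(1:40, function(i) {
    M <- sample(4:6, 1)
    E <- matrix(rnorm(M * d, sd = 0.3), M, d)
    pos <- sample(M, 1)
    E[pos, ] <- E[pos, ] + 1.5
    list(x = E, y = as.integer(seq_len(M) == pos))
  })
  build <- function() set_model(encoder_spec("identity", out_dim = d),
                                aggregator_config("picaso", dim = d,
                                                  n_heads = 2, n_steps = 2),
                                head = "instance", seed = 2)
  cfg <- train_config(lr = 2e-3, epochs = 5, batch_size = 8, seed = 9)
  t1 <- train(build(), sets, cfg)
  t2 <- train(build(), sets, cfg)
  expect_equal(t1$history$loss[1], t2$history$loss[1], tolerance = 1e-10)
  expect_identical(t1$history$loss, t2$history$loss)
  expect_lt(tail(t1$history$loss, 1), t1$history$loss[1])
  expect_error(train(build(), list()), "no training sets")
})

test_that("the steps sweep emits one row per (J, seed) with J = 1 included", {
  set.seed(16)
  d <- 6
  mk <- function(n) lapply(seq_len(n), function(i) {
    E <- matrix(rnorm(4 * d, sd = 0.3), 4, d)
    pos <- sample(4, 1)
    E[pos, ] <- E[pos, ] + 1.5
    list(x = E, y = as.integer(seq_len(4) == pos))
  })
  tab <- sweep_steps(mk(12), mk(8), J_values = c(1, 3), seeds = c(1, 2),
                     encoder = encoder_spec("identity", out_dim = d),
                     aggregator = aggregator_config("picaso", dim = d,
                                                    n_heads = 2),
                     config = train_config(lr = 1e-3, epochs = 2,
                                           batch_size = 6))
  expect_identical(nrow(tab), 4L)
  expect_setequal(tab$J, c(1, 3))
  expect_true(all(c("auroc", "aupr", "recall") %in% names(tab)))
  expect_true(all(is.finite(tab$auroc)))
})

test_that("the set-size sweep reuses the trained model and agrees with
           evaluate() at the training size", {
  set.seed(17)
  d <- 6
  mk <- function(n, M) lapply(seq_len(n), function(i) {
    E <- matrix(rnorm(M * d, sd = 0.3), M, d)
    pos <- sample(M, 1)
    E[pos, ] <- E[pos, ] + 1.5
    list(x = E, y = as.integer(seq_len(M) == pos))
  })
  model <- train(set_model(encoder_spec("identity", out_dim = d),
                           aggregator_config("picaso", dim = d, n_heads = 2,
                                             n_steps = 1),
                           head = "instance", seed = 3),
                 mk(20, 6), train_config(lr = 2e-3, epochs = 3,
                                         batch_size = 8))$model
  fixed <- list(`4` = mk(10, 4), `8` = mk(10, 8))
  tab <- sweep_set_size(model, c(4, 8), function(M) fixed[[as.character(M)]])
  expect_identical(tab$M, c(4, 8))
  direct <- evaluate(model, fixed[["8"]], n_bootstrap = 0)
  expect_equal(tab$auroc[2], unname(direct$metrics["auroc"]))

  # a set-level model accepts single-instance sets
  bmodel <- set_model(encoder_spec("identity", out_dim = d),
                      aggregator_config("deepset", dim = d, pool = "mean"),
                      head = "set", seed = 1)
  one <- list(list(x = matrix(rnorm(d), 1), y = 1),
              list(x = matrix(rnorm(d), 1), y = 0))
  tab1 <- sweep_set_size(bmodel, 1, function(M) one)
  expect_true(is.finite(tab1$auroc))
})

test_that("metric reports serialise to CSV and JSON", {
  cache <- lapply(1:30, function(i) list(scores = runif(1),
                                         y = rbinom(1, 1, 0.5)))
  rep <- picaso:::report_from_cache(cache, "set", n_bootstrap = 50)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_report(rep, csv, js)
  back <- utils::read.csv(csv)
  expect_setequal(back$metric, names(rep$metrics))
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$metrics$auroc, unname(rep$metrics["auroc"]))
})
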