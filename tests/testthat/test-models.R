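# Classifier construction, training contract, early stopping, ensemble
# aggregation, tuning, and persistence. Fits here are deliberately tiny
# (small n, few epochs, single restart) — learning quality is covered by
# the parameter-recovery acceptance test.

tiny_cfg <- function(arch, ...) {
  model_config(arch, max_epochs = 3L, n_restarts = 1L, ...)
}

tiny_split <- function(n = 40, seed = 3) {
  d <- generate_dataset(n = n, seed = seed)
  list(train = d[seq_len(n * 0.75), ], val = d[-seq_len(n * 0.75), ])
}

test_that("network gradients match finite differences", {
  ns <- asNamespace("phos1433")
  d <- generate_dataset(n = 6, seed = 2)
  y <- as.numeric(d$label)
  for (arch in c("mlp", "cnn", "gru")) {
    for (enc in c("blosum62_flag", "embedding_ids")) {
      cfg <- model_config(arch, encoding = enc, hidden = 4L,
                          embedding_dim = 3L, filters = 4L, kernel = 3L,
                          gru_hidden = 4L, gru_layers = 2L, seed = 9)
      set.seed(9)
      params <- ns$nn_init(cfg)
      X <- ns$model_input(d$sequence, cfg)
      fw <- ns$nn_forward(params, X, cfg)
      gr <- ns$nn_backward(params, fw$cache, (fw$prob - y) / length(y), cfg)
      pvec <- unlist(params)
      gvec <- unlist(gr)
      loss <- function(v)
        ns$bce_loss(y, ns$nn_forward(utils::relist(v, params), X, cfg)$prob)
      idx <- sample(length(pvec), 20)
      num <- vapply(idx, function(i) {
        e <- 1e-5
        v1 <- pvec; v1[i] <- v1[i] + e
        v2 <- pvec; v2[i] <- v2[i] - e
        (loss(v1) - loss(v2)) / (2 * e)
      }, numeric(1))
      rel <- abs(num - gvec[idx]) / pmax(1e-6, abs(num) + abs(gvec[idx]))
      expect_lt(max(rel), 1e-4)
    }
  }
})

test_that("architecture dimensions follow the encoding", {
  ns <- asNamespace("phos1433")
  cfg <- model_config("mlp", encoding = "onehot", seed = 1)
  set.seed(1)
  p <- ns$nn_init(cfg)
  expect_identical(nrow(p$dense$W[[1]]), 15L * 23L)  # 345 after flattening
  cfg2 <- model_config("gru", seed = 1)
  set.seed(1)
  p2 <- ns$nn_init(cfg2)
  expect_identical(nrow(p2$gru[[1]]$Wz), 22L)        # BLOSUM62 + flag width
})

test_that("the early-stopping rule follows best-epoch patience semantics", {
  tr <- trace_early_stop(c(.2, .3, .4, .5, .6, .6, .6, .6, .6, .6))
  expect_identical(tr$best_epoch, 5L)
  expect_identical(tr$stop_epoch, 10L)
  # an improvement resets the patience counter
  tr2 <- trace_early_stop(c(.2, .3, .4, .5, .6, .6, .6, .65, .65, .65, .65, .65, .66))
  expect_identical(tr2$best_epoch, 13L)
  expect_true(is.na(tr2$stop_epoch))
  tr2b <- trace_early_stop(c(.2, .3, .4, .5, .6, .6, .6, .65, .65, .65, .65, .65))
  expect_identical(tr2b$best_epoch, 8L)    # patience not yet exhausted
  expect_true(is.na(tr2b$stop_epoch))
  # stopping can trigger as soon as the minimum epoch is reached
  tr3 <- trace_early_stop(c(.9, .5, .5, .5, .5, .5))
  expect_identical(tr3$stop_epoch, 6L)
  expect_identical(tr3$best_epoch, 1L)
})

test_that("training is deterministic and predictions behave like probabilities", {
  sp <- tiny_split()
  for (arch in c("mlp", "cnn", "gru")) {
    f1 <- fit_binding_model(sp$train, sp$val, tiny_cfg(arch, seed = 5))
    f2 <- fit_binding_model(sp$train, sp$val, tiny_cfg(arch, seed = 5))
    p1 <- predict(f1, sp$val)
    expect_identical(p1, predict(f2, sp$val))        # same seed, same model
    expect_true(all(p1 > 0 & p1 < 1))
    # batch prediction equals per-window prediction, order preserved
    single <- vapply(sp$val$sequence, function(s) predict(f1, s), numeric(1))
    expect_equal(p1, unname(single), tolerance = 1e-12)
    expect_identical(predict(f1, character(0)), numeric(0))
  }
})

test_that("degenerate training inputs are rejected", {
  sp <- tiny_split()
  one_class <- sp$train[sp$train$label == 1, ]
  expect_error(fit_binding_model(one_class, sp$val, tiny_cfg("mlp")),
               "single class")
  expect_error(fit_binding_model(sp$train[0, ], sp$val, tiny_cfg("mlp")),
               "empty")
})

test_that("ensemble aggregation averages, votes and bounds correctly", {
  sp <- tiny_split(60, seed = 9)
  cfgs <- lapply(c(mlp = "mlp", cnn = "cnn", gru = "gru"), tiny_cfg)
  ens <- fit_binding_ensemble(sp$train, sp$val, seed = 2, configs = cfgs)
  pr <- predict(ens, sp$val)
  scores <- as.matrix(pr[c("score_mlp", "score_cnn", "score_gru")])
  expect_equal(pr$mean_score, unname(rowMeans(scores)), tolerance = 1e-12)
  expect_identical(pr$vote, as.integer(rowSums(scores > 0.5)))
  expect_identical(pr$classification, as.integer(pr$mean_score > 0.5))
  # the mean is bounded by member extremes and preserves dominance order
  expect_true(all(pr$mean_score >= apply(scores, 1, min) - 1e-12))
  expect_true(all(pr$mean_score <= apply(scores, 1, max) + 1e-12))
  dominated <- which(vapply(seq_len(nrow(scores) - 1L), function(i)
    all(scores[i, ] > scores[i + 1L, ]), logical(1)))
  for (i in dominated) expect_gt(pr$mean_score[i], pr$mean_score[i + 1L])
  # ensembles require exactly three members
  broken <- ens
  broken$members <- ens$members[1:2]
  expect_error(predict(broken, sp$val), "3 members")
})

test_that("two-stage tuning returns the brute-force best configuration", {
  d <- generate_dataset(n = 60, seed = 13)
  plan <- make_split_plan(d, seed = 13)
  grid1 <- list(list(hidden = 4L, max_epochs = 2L, n_restarts = 1L),
                list(hidden = 8L, max_epochs = 2L, n_restarts = 1L),
                list(hidden = 4L, learning_rate = 0.05, max_epochs = 2L, n_restarts = 1L),
                list(hidden = 8L, learning_rate = 0.05, max_epochs = 2L, n_restarts = 1L))
  best <- tune_hyperparameters(d, plan, "mlp", stage1_grid = grid1,
                               n_replicates = 2L, seed = 3)
  # brute force: re-evaluate every candidate the same way
  brute <- vapply(grid1, function(g) {
    cfg <- do.call(model_config,
                   c(list(architecture = "mlp", seed = 3), g))
    mean(vapply(plan$replicates[1:2], function(rp) {
      f <- fit_binding_model(d[rp$train, ], d[rp$val, ], cfg)
      max(f$history$val_f1)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(best$hidden, grid1[[which.max(brute)]]$hidden)
  expect_equal(max(attr(best, "search")$mean_val_f1), max(brute),
               tolerance = 1e-12)
  # a one-entry grid returns that entry
  one <- tune_hyperparameters(d, plan, "mlp",
                              stage1_grid = grid1[1], n_replicates = 1L, seed = 3)
  expect_identical(one$hidden, 4L)
  expect_error(tune_hyperparameters(d, plan, "mlp", stage1_grid = list()),
               "empty")
})

test_that("models and ensembles survive a save/load round trip", {
  sp <- tiny_split(40, seed = 21)
  cfgs <- lapply(c(mlp = "mlp", cnn = "cnn", gru = "gru"), tiny_cfg)
  ens <- fit_binding_ensemble(sp$train, sp$val, seed = 4, configs = cfgs)
  dir <- file.path(tempdir(), "ens_roundtrip")
  save_model(ens, dir)
  back <- load_model(dir)
  expect_equal(predict(back, sp$val), predict(ens, sp$val), tolerance = 1e-12)
  m <- ens$members$gru
  dir2 <- file.path(tempdir(), "gru_roundtrip")
  save_model(m, dir2)
  expect_equal(predict(load_model(dir2), sp$val$sequence),
               predict(m, sp$val$sequence), tolerance = 1e-12)
})
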