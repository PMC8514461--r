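tiny_cfg <- function(mode, seed = 5L) {
  model_config(k = 5L, m = 3L, mode = mode, embed_dim = 2L,
               branch_hidden = 3L, branch_out = 3L, merged_layers = 2L,
               merged_hidden = 3L, dropout_rate = 0, learning_rate = 0.01,
               batch_size = 4L, max_epochs = 2L, seed = seed)
}

test_that("backpropagation matches finite-difference gradients", {
  for (mode in c("full", "signal_only", "sequence_only")) {
    cfg <- tiny_cfg(mode)
    model <- build_model(cfg)
    toy <- make_toy_samples(6, k = 5L, m = 3L, seed = 23)
    batch <- squigglemeth:::make_batch(toy, 1:6, cfg)
    lg <- squigglemeth:::model_loss_grads(model, batch, training = FALSE)
    loss_at <- function(params) {
      m2 <- model; m2$params <- params
      squigglemeth:::model_loss_grads(m2, batch, training = FALSE)$loss
    }
    # probe two entries of every leaf parameter array
    check_leaf <- function(path) {
      leaf <- model$params[[path]]
      gleaf <- lg$grads[[path]]
      set.seed(sum(utf8ToInt(paste(path, collapse = ""))))
      for (j in sample(seq_along(leaf), min(2L, length(leaf)))) {
        h <- 1e-5
        pp <- model$params; pp[[path]][j] <- pp[[path]][j] + h
        pm <- model$params; pm[[path]][j] <- pm[[path]][j] - h
        num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
        expect_equal(gleaf[j], num, tolerance = 1e-4,
                     info = paste(mode, paste(path, collapse = "/"), j))
      }
    }
    paths <- list()
    collect <- function(x, prefix = character()) {
      if (is.list(x)) {
        for (nm in names(x)) collect(x[[nm]], c(prefix, nm))
      } else {
        paths[[length(paths) + 1L]] <<- prefix
      }
    }
    collect(model$params)
    for (p in paths) check_leaf(p)
  }
})

test_that("predictions are softmax-normalized and deterministic", {
  cfg <- tiny_cfg("full")
  model <- build_model(cfg)
  toy <- make_toy_samples(10, k = 5L, m = 3L, seed = 29)
  p <- predict(model, toy)
  expect_true(all(abs(p$p_methylated + p$p_unmethylated - 1) < 1e-6))
  expect_true(all(p$p_methylated >= 0 & p$p_methylated <= 1))
  # duplicated inputs get identical predictions
  dup <- bind_samples(toy, toy)
  pd <- predict(model, dup)
  expect_equal(pd[1:10, ], pd[11:20, ], ignore_attr = TRUE)
})

test_that("model building is seed-deterministic with a fixed parameter count", {
  cfg <- tiny_cfg("full")
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_equal(m1$params, m2$params)
  expect_equal(parameter_count(m1), parameter_count(m2))
  cfg2 <- tiny_cfg("full", seed = 99L)
  expect_equal(parameter_count(build_model(cfg2)), parameter_count(m1))
  expect_error(model_config(merged_layers = 0L), "merged_layers")
  expect_error(model_config(learning_rate = 0), "learning_rate")
})

test_that("training separates a two-Gaussian toy problem within 5 epochs", {
  toy <- make_toy_samples(2000, delta = 0.75, sigma = 0.25, seed = 31)
  cfg <- model_config(k = 13L, m = 16L, mode = "signal_only",
                      branch_hidden = 8L, branch_out = 8L, merged_layers = 1L,
                      merged_hidden = 8L, dropout_rate = 0, batch_size = 64L,
                      learning_rate = 0.01, max_epochs = 5L,
                      early_stopping = FALSE, seed = 7L)
  parts <- split_train_valid(toy, 0.9, seed = 3)
  model <- train_model(build_model(cfg), parts$train, parts$valid)
  expect_gt(max(model$history$valid_acc), 0.95)
  # training loss decreases over the first epochs
  expect_lt(model$history$train_loss[2], model$history$train_loss[1])
  # held-out AUC on separable data
  p <- predict(model, parts$valid)
  expect_gt(auc_score(p$p_methylated, parts$valid$info$label), 0.99)
  # fixed seed -> identical loss curve across runs
  model2 <- train_model(build_model(cfg), parts$train, parts$valid)
  expect_equal(model$history, model2$history)
})

test_that("empty or unlabelled training sets are rejected", {
  cfg <- tiny_cfg("full")
  model <- build_model(cfg)
  toy <- make_toy_samples(4, k = 5L, m = 3L, seed = 3)
  toy$info$label <- NA_integer_
  expect_error(train_model(model, toy), "label")
})

test_that("train/valid split is exhaustive, disjoint and 99:1 by default", {
  toy <- make_toy_samples(1000, k = 5L, m = 3L, seed = 37)
  parts <- split_train_valid(toy, 0.99, seed = 11)
  expect_equal(n_samples(parts$train), 990L)
  expect_equal(n_samples(parts$valid), 10L)
  expect_setequal(c(parts$train$info$sample_id, parts$valid$info$sample_id),
                  toy$info$sample_id)
  parts2 <- split_train_valid(toy, 0.99, seed = 11)
  expect_equal(parts$train$info$sample_id, parts2$train$info$sample_id)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- tiny_cfg("signal_only")
  model <- build_model(cfg)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p)
  back <- load_model(p)
  expect_equal(back$params, model$params)
  toy <- make_toy_samples(5, k = 5L, m = 3L, seed = 41)
  expect_equal(predict(back, toy), predict(model, toy))
})
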