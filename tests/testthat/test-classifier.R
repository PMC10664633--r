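fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(hidden_layers = 2L, units_per_layer = 32L, epochs = 30L,
         batch_size = 32L, seed = 1L),
    list(...))
  do.call(network_config, args)
}

test_that("default configuration carries the published operating point", {
  cfg <- network_config()
  expect_identical(cfg$hidden_layers, 5L)
  expect_identical(cfg$units_per_layer, 300L)
  expect_equal(cfg$dropout_rate, 0.3)
  expect_identical(cfg$batch_size, 64L)
  expect_identical(cfg$epochs, 200L)
  expect_identical(cfg$optimizer, "nadam")
  expect_error(network_config(dropout_rate = 1), "dropout_rate")
  expect_error(network_config(hidden_layers = -1), "invalid")
})

test_that("build_model lays out the dense stack and degenerate depths", {
  m <- build_model(10, network_config())
  expect_identical(m$dims, c(10L, rep(300L, 5), 1L))
  expect_length(m$params$W, 6)
  expect_identical(dim(m$params$W[[1]]), c(10L, 300L))
  expect_identical(dim(m$params$W[[6]]), c(300L, 1L))

  lr <- build_model(7, network_config(hidden_layers = 0))
  expect_length(lr$params$W, 1)
  expect_identical(dim(lr$params$W[[1]]), c(7L, 1L))
})

test_that("epochs = 0 returns the untrained model with empty history", {
  tab <- blob_table(n = 60)
  m <- build_model(10, fast_cfg(epochs = 0))
  m2 <- train(m, tab, m$cfg)
  expect_false(m2$trained)
  expect_identical(nrow(m2$history), 0L)
  expect_identical(m2$params, m$params)
})

test_that("training separates two Gaussian blobs quickly", {
  tab <- blob_table(n = 400, d = 10, sep = 3)
  cfg <- fast_cfg(epochs = 50)
  model <- train(build_model(10, cfg), tab, cfg)
  expect_gt(tail(model$history$train_acc, 1), 0.95)
  # loss is non-increasing on average over 20-epoch windows
  loss <- model$history$train_loss
  expect_lt(mean(loss[31:50]), mean(loss[1:20]))
  # fitted separation: positives score higher than negatives
  sc <- predict_scores(model, tab$features)
  expect_gt(mean(sc[tab$label == 1]), mean(sc[tab$label == 0]))
})

test_that("scores always lie in [0, 1] and are deterministic per model", {
  tab <- blob_table(n = 100)
  cfg <- fast_cfg(epochs = 5)
  model <- train(build_model(10, cfg), tab, cfg)
  X <- rbind(tab$features, tab$features[1, , drop = FALSE] * 100)
  sc <- predict_scores(model, X)
  expect_true(all(sc >= 0 & sc <= 1))
  # duplicated rows score identically
  dup <- predict_scores(model, tab$features[c(1, 1, 2, 2), ])
  expect_identical(dup[1], dup[2])
  expect_identical(dup[3], dup[4])
})

test_that("seeded training is exactly reproducible", {
  tab <- blob_table(n = 120)
  cfg <- fast_cfg(epochs = 8, seed = 99)
  a <- train(build_model(10, cfg), tab, cfg)
  b <- train(build_model(10, cfg), tab, cfg)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("feature width mismatches and single-class tables error", {
  tab <- blob_table(n = 60)
  cfg <- fast_cfg(epochs = 2)
  model <- train(build_model(10, cfg), tab, cfg)
  expect_error(predict_scores(model, matrix(0, 2, 7)), "width")
  bad <- make_table(tab$features, rep(1, length(tab$label)))
  expect_error(train(build_model(10, cfg), bad, cfg), "single class")
})

test_that("dropout off gives a deterministic forward pass", {
  cfg <- fast_cfg(dropout_rate = 0, epochs = 3)
  tab <- blob_table(n = 80)
  model <- train(build_model(10, cfg), tab, cfg)
  s1 <- predict_scores(model, tab$features)
  s2 <- predict_scores(model, tab$features)
  expect_identical(s1, s2)
})

test_that("the conv1d variant trains and keeps the score contract", {
  tab <- blob_table(n = 200, d = 20, sep = 3)
  cfg <- network_config(hidden_layers = 1L, units_per_layer = 16L,
                        epochs = 30L, batch_size = 32L,
                        architecture = "conv1d", conv_filters = 4L,
                        conv_kernel = 5L, pool_size = 2L, seed = 2L)
  model <- train(build_model(20, cfg), tab, cfg)
  sc <- predict_scores(model, tab$features)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(mean(sc[tab$label == 1]), mean(sc[tab$label == 0]))
  expect_error(build_model(3, cfg), "kernel")
})

test_that("training history exports the learning-curve columns", {
  tab <- blob_table(n = 60)
  cfg <- fast_cfg(epochs = 4)
  model <- train(build_model(10, cfg), tab, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_history(model, f)
  h <- read.csv(f)
  expect_identical(names(h),
                   c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_identical(nrow(h), 4L)
  expect_false(anyNA(h$val_loss))
})
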