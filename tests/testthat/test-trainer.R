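p_default <- neuron_params()

test_that("evaluation reads argmax with lowest-index tie-breaking", {
  # zero weights give all-zero outputs: every prediction is class 0
  sizes <- c(4, 3)
  zero_net <- snn_network(sizes, list(matrix(0, 4, 3)))
  X <- matrix(0, 4, 4)
  y <- c(0L, 1L, 2L, 0L)
  expect_equal(snn_evaluate(zero_net, p_default, X, y), 100 * mean(y == 0L))
  expect_error(snn_evaluate(zero_net, p_default, X[0, , drop = FALSE],
                            integer(0)), "empty")
})

test_that("a perfectly aligned network scores 100 percent", {
  # identity-ish map: input IS the one-hot pattern, weights pass it through
  net <- snn_network(c(3, 3), list(diag(3)))
  y <- c(0L, 1L, 2L)
  X <- one_hot(y, 3)
  expect_equal(snn_evaluate(net, p_default, X, y), 100)
})

test_that("training config validates its bounds", {
  expect_error(train_config(c(10)), "2 layers")
  expect_error(train_config(c(10, 5, 2), epochs = 0), "epochs")
  expect_error(train_config(c(10, 5, 2), batch_size = 0), "batch_size")
  expect_error(train_config(c(10, 5, 5, 2), n_feedback_layers = 2), "0..1")
  cfg <- train_config(c(10, 5, 5, 5, 2))
  expect_equal(cfg$n_feedback_layers, 2L)  # all eligible layers by default
})

test_that("zero weight learning rate leaves the network untouched", {
  d <- make_blobs(15, 6, 2, 6, 0.05, seed = 20)
  cfg <- train_config(c(6, 8, 2), epochs = 3, eta_w = 0, seed = 4)
  res <- snn_train(cfg, d$train, d$test)
  ref <- init_network(cfg$layer_sizes, lifnet:::derive_seed(4L, 1L), "orthogonal")
  expect_identical(res$network$weights, ref$weights)
  expect_equal(length(unique(res$train_acc)), 1L)
  expect_equal(length(unique(res$test_acc)), 1L)
})

test_that("identical config and seed reproduce the result bit-exactly", {
  d <- make_blobs(15, 6, 3, 6, 0.05, seed = 21)
  cfg <- train_config(c(6, 10, 8, 3), epochs = 4, seed = 7)
  r1 <- snn_train(cfg, d$train, d$test)
  r2 <- snn_train(cfg, d$train, d$test)
  expect_identical(r1$network$weights, r2$network$weights)
  expect_identical(r1$train_acc, r2$train_acc)
  expect_identical(r1$test_acc, r2$test_acc)
  expect_identical(r1$loss, r2$loss)
  r3 <- snn_train(train_config(c(6, 10, 8, 3), epochs = 4, seed = 8),
                  d$train, d$test)
  expect_false(identical(r1$network$weights, r3$network$weights))
})

test_that("training histories have one entry per epoch in percent range", {
  d <- make_blobs(15, 6, 2, 6, 0.05, seed = 22)
  cfg <- train_config(c(6, 8, 2), epochs = 5, seed = 1)
  res <- snn_train(cfg, d$train, d$test)
  for (series in list(res$train_acc, res$test_acc)) {
    expect_length(series, 5)
    expect_true(all(series >= 0 & series <= 100))
  }
  expect_length(res$loss, 5)
  expect_true(all(is.finite(res$loss)))
})

test_that("numerical divergence aborts with an epoch/batch diagnostic", {
  d <- make_blobs(15, 6, 2, 6, 0.05, seed = 30)
  cfg <- train_config(c(6, 8, 8, 2), epochs = 50, eta_w = 50, seed = 1)
  expect_error(snn_train(cfg, d$train), "diverged at epoch")
})

test_that("a separable two-class problem is learned quickly", {
  d <- make_blobs(60, 12, 2, 6, 0.05, seed = 23)
  cfg <- train_config(c(12, 16, 2), epochs = 20, seed = 0)
  res <- snn_train(cfg, d$train, d$test)
  expect_gte(max(res$test_acc), 90)
})

test_that("ablation freezes exactly the layers below the granted targets", {
  d <- make_blobs(24, 8, 3, 6, 0.05, seed = 24)
  cfg <- train_config(c(8, 6, 6, 6, 3), epochs = 2, seed = 3)
  res <- run_ablation(cfg, 0:2, d$train)
  init <- init_network(cfg$layer_sizes, lifnet:::derive_seed(3L, 1L), "orthogonal")
  # count 0: only the top two weight matrices may change
  expect_identical(res[["0"]]$network$weights[[1]], init$weights[[1]])
  expect_identical(res[["0"]]$network$weights[[2]], init$weights[[2]])
  expect_false(identical(res[["0"]]$network$weights[[3]], init$weights[[3]]))
  expect_false(identical(res[["0"]]$network$weights[[4]], init$weights[[4]]))
  # count 1 unfreezes the next shallower hidden layer only
  expect_identical(res[["1"]]$network$weights[[1]], init$weights[[1]])
  expect_false(identical(res[["1"]]$network$weights[[2]], init$weights[[2]]))
  # full feedback: everything moves
  for (l in 1:4) {
    expect_false(identical(res[["2"]]$network$weights[[l]], init$weights[[l]]))
  }
  expect_error(run_ablation(cfg, 3, d$train), "0..2")
})

test_that("the depth sweep tabulates one row per depth, reproducibly", {
  d <- make_blobs(15, 6, 2, 6, 0.05, seed = 25)
  cfg <- train_config(c(6, 8, 2), epochs = 2, seed = 5)
  tab <- depth_sweep(cfg, c(1, 2, 3), hidden_width = 8, d$train, d$test)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_hidden, c(1L, 2L, 3L))
  expect_equal(tab$layer_sizes[2], "6-8-8-2")
  tab2 <- depth_sweep(cfg, c(1, 2, 3), hidden_width = 8, d$train, d$test)
  expect_identical(tab$test_acc, tab2$test_acc)
  expect_error(depth_sweep(cfg, 15, 8, d$train), "simulation steps")
})

test_that("model archives round-trip weights and feedback bit-exactly", {
  sizes <- c(6, 8, 7, 3)
  net <- random_net(sizes, seed = 26)
  fb <- init_feedback(sizes, seed = 27, bias_scale = 0.01)
  path <- withr::local_tempfile()
  save_model(net, fb, path)
  m <- load_model(path)
  expect_identical(m$network$weights, net$weights)
  expect_identical(m$feedback$B, fb$B)
  expect_identical(m$feedback$b, fb$b)
  expect_error(load_model(withr::local_tempfile(lines = "x")), "archive")
})

test_that("config files round-trip and CLI-style overrides win", {
  path <- withr::local_tempfile()
  write_config_file(list(
    neuron = c(V_th = "0.0009", T = "0.1"),
    network = c(layer_sizes = "6,8,2", init_scheme = "orthogonal"),
    train = c(epochs = "7", eta_w = "0.015", seed = "3")
  ), path)
  cfg <- config_from_file(path)
  expect_equal(cfg$layer_sizes, c(6L, 8L, 2L))
  expect_equal(cfg$epochs, 7L)
  expect_equal(cfg$params$V_th, 0.0009)
  cfg2 <- config_from_file(path, overrides = list(epochs = 2, eta_t = 0.25,
                                                  V_th = 0.002))
  expect_equal(cfg2$epochs, 2L)
  expect_equal(cfg2$eta_t, 0.25)
  expect_equal(cfg2$params$V_th, 0.002)
  expect_error(config_from_file(NULL), "layer_sizes")
})

test_that("the CLI trains end-to-end from synthetic IDX files", {
  dir <- withr::local_tempdir()
  lifnet_cli(c("make-synthetic", "--out-dir", dir, "--n-per-class", "30",
               "--dim", "6", "--n-classes", "2", "--seed", "1"))
  expect_true(file.exists(file.path(dir, "train-images-idx3-ubyte")))
  model <- file.path(dir, "model.rds")
  hist <- file.path(dir, "history.tsv")
  out <- capture.output(lifnet_cli(c(
    "train",
    "--train-images", file.path(dir, "train-images-idx3-ubyte"),
    "--train-labels", file.path(dir, "train-labels-idx1-ubyte"),
    "--test-images", file.path(dir, "t10k-images-idx3-ubyte"),
    "--test-labels", file.path(dir, "t10k-labels-idx1-ubyte"),
    "--layer-sizes", "6,8,2", "--epochs", "3", "--seed", "0",
    "--model-out", model, "--history-out", hist)))
  expect_length(out, 3)  # one structured log line per epoch
  expect_match(out[1], "^epoch=1 train_acc=")
  expect_true(file.exists(model))
  h <- read.delim(hist)
  expect_equal(nrow(h), 3)
  eval_out <- capture.output(lifnet_cli(c(
    "eval", "--model", model,
    "--test-images", file.path(dir, "t10k-images-idx3-ubyte"),
    "--test-labels", file.path(dir, "t10k-labels-idx1-ubyte"))))
  expect_match(eval_out, "^test_acc=")
  expect_error(lifnet_cli("frobnicate"), "unknown command")
})
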