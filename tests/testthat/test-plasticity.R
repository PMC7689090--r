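p_default <- neuron_params()

test_that("the STDP update is the pre/post-difference outer product", {
  S_pre <- matrix(c(1, 2), 1)
  S_post <- matrix(c(0.1, -0.1), 1)
  hat <- matrix(0, 1, 2)
  expect_equal(stdp_delta(S_pre, S_post, hat),
               matrix(c(0.1, 0.2, -0.1, -0.2), 2, 2))
  expect_equal(stdp_delta(S_pre, S_post, S_post), matrix(0, 2, 2))
  # mean reduction averages the per-sample outer products
  S_pre2 <- rbind(c(1, 2), c(3, 1))
  S_post2 <- rbind(c(0.1, -0.1), c(0.2, 0))
  hat2 <- matrix(0, 2, 2)
  per_sample <- (outer(S_pre2[1, ], S_post2[1, ]) +
                 outer(S_pre2[2, ], S_post2[2, ])) / 2
  expect_equal(stdp_delta(S_pre2, S_post2, hat2, "mean"), per_sample)
  expect_equal(stdp_delta(S_pre2, S_post2, hat2, "sum"), per_sample * 2)
  expect_error(stdp_delta(S_pre2, S_post2, matrix(0, 3, 2)), "shape")
})

test_that("stdp_delta is linear in the forward/target difference", {
  set.seed(14)
  S_pre <- matrix(runif(12), 3, 4)
  S_post <- matrix(runif(15), 3, 5)
  d1 <- matrix(rnorm(15), 3, 5)
  d2 <- matrix(rnorm(15), 3, 5)
  lhs <- stdp_delta(S_pre, S_post, S_post - (2 * d1 + d2))
  rhs <- 2 * stdp_delta(S_pre, S_post, S_post - d1) +
    stdp_delta(S_pre, S_post, S_post - d2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("apply_update takes a plain reversible gradient step", {
  expect_equal(apply_update(matrix(1), matrix(1), 0.015), matrix(0.985))
  W <- matrix(rnorm(6), 2, 3)
  dW <- matrix(rnorm(6), 2, 3)
  expect_identical(apply_update(W, dW, 0), W)
  expect_identical(apply_update(apply_update(W, dW, 0.1), -dW, 0.1), W)
  expect_error(apply_update(W, matrix(0, 3, 2), 0.1), "shape")
  expect_error(apply_update(W, dW, -1), "eta_w")
})

test_that("a zero-error batch leaves every weight bit-identical", {
  sizes <- c(4, 5, 4, 2)
  net <- random_net(sizes, seed = 101)
  fb <- init_feedback(sizes, seed = 102)
  X <- matrix(runif(2 * 4), 2, 4)
  tr <- simulate_forward(net, X, p_default)
  tg <- compute_all_targets(tr, net, fb, labels = c(0, 1))
  # rebuild the target set as if the outputs were perfect
  tg$S_T <- tr$S_layers[[4]]
  e0 <- prediction_error(tr$S_layers[[4]], tg$S_T)
  tg$S_hat[[3]] <- penultimate_target(tr$S_layers[[3]], net$weights[[3]],
                                      e0, fb$eta_t)
  tg$S_hat[[2]] <- hidden_target(tr$S_layers[[2]], fb$B[[2]], fb$b[[2]], e0)
  out <- update_all_layers(net, tr, tg, eta_w = 0.015)
  expect_identical(out$weights, net$weights)
})

test_that("layers without targets are frozen bit-exactly", {
  sizes <- c(4, 5, 6, 5, 3)
  net <- random_net(sizes, seed = 111)
  fb <- init_feedback(sizes, seed = 112)
  X <- matrix(runif(3 * 4), 3, 4)
  tr <- simulate_forward(net, X, p_default)
  tg <- compute_all_targets(tr, net, fb, labels = c(0, 1, 2),
                            n_feedback_layers = 0L)
  out <- update_all_layers(net, tr, tg, eta_w = 0.015)
  expect_identical(out$weights[[1]], net$weights[[1]])
  expect_identical(out$weights[[2]], net$weights[[2]])
  expect_false(identical(out$weights[[3]], net$weights[[3]]))
  expect_false(identical(out$weights[[4]], net$weights[[4]]))
})

test_that("each weight update ignores other layers' targets", {
  sizes <- c(4, 5, 6, 5, 3)
  net <- random_net(sizes, seed = 121)
  fb <- init_feedback(sizes, seed = 122)
  X <- matrix(runif(3 * 4), 3, 4)
  tr <- simulate_forward(net, X, p_default)
  tg <- compute_all_targets(tr, net, fb, labels = c(0, 1, 2))
  out1 <- update_all_layers(net, tr, tg, eta_w = 0.015)
  tg2 <- tg
  tg2$S_hat[[3]] <- tg$S_hat[[3]] + 5  # perturb an unrelated layer's target
  out2 <- update_all_layers(net, tr, tg2, eta_w = 0.015)
  expect_identical(out1$weights[[1]], out2$weights[[1]])  # uses S_hat[[2]]
  expect_identical(out1$weights[[3]], out2$weights[[3]])  # uses S_hat[[4]]
  expect_identical(out1$weights[[4]], out2$weights[[4]])  # uses S_T
  expect_false(identical(out1$weights[[2]], out2$weights[[2]]))
})

test_that("one update step descends the loss for small learning rates", {
  descended <- 0
  total <- 0
  for (rep in 1:20) {
    sizes <- c(6, 8, 5, 3)
    net <- random_net(sizes, seed = 200 + rep)
    fb <- init_feedback(sizes, seed = 300 + rep)
    set.seed(400 + rep)
    X <- matrix(runif(6 * 6), 6, 6)
    y <- sample(0:2, 6, replace = TRUE)
    tr <- simulate_forward(net, X, p_default)
    loss0 <- l2_loss(tr$S_layers[[4]], one_hot(y, 3))
    for (eta_w in c(0.002, 0.005, 0.015)) {
      tg <- compute_all_targets(tr, net, fb, y)
      net2 <- update_all_layers(net, tr, tg, eta_w)
      tr2 <- simulate_forward(net2, X, p_default)
      loss1 <- l2_loss(tr2$S_layers[[4]], one_hot(y, 3))
      total <- total + 1
      if (loss1 <= loss0) descended <- descended + 1
    }
  }
  expect_gt(descended / total, 0.5)
})

test_that("a one-sample toy update reproduces the scalar-loop composition", {
  sizes <- c(3, 4, 3, 2)
  net <- random_net(sizes, seed = 131)
  fb <- init_feedback(sizes, seed = 132, bias_scale = 0.01)
  set.seed(133)
  x <- runif(3)
  tr <- simulate_forward(net, matrix(x, 1), p_default)
  tg <- compute_all_targets(tr, net, fb, labels = 1L)
  upd <- update_all_layers(net, tr, tg, eta_w = 0.015)
  ref <- oracle_one_update(net$weights, fb$B, fb$b, x, label = 1L,
                           n_classes = 2L, p_default,
                           eta_t = 0.5, eta_w = 0.015)
  for (l in 1:3) {
    expect_equal(upd$weights[[l]], ref[[l]], tolerance = 1e-12)
  }
})
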