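test_that("halving rule produces the closed-form floor sequence", {
  expect_equal(derive_layer_widths(128, 3), c(128L, 64L, 32L))
  expect_equal(derive_layer_widths(1, 4), rep(1L, 4))
  expect_equal(derive_layer_widths(5, 4), c(5L, 2L, 1L, 1L))  # floor(5/8)=0 clamped

  # property: non-increasing and >= 1 across the whole admissible range
  set.seed(1)
  for (N1 in c(1:20, sample(21:1024, 60))) for (L in 1:6) {
    w <- derive_layer_widths(N1, L)
    expect_equal(w, pmax(1L, as.integer(N1 %/% 2^(0:(L - 1)))))
    expect_true(all(diff(w) <= 0) && all(w >= 1))
  }
})

test_that("network construction is deterministic with a closed-form parameter count", {
  arch <- architecture_spec(n1 = 16, depths = 1, fusion_depth = 0)
  cfg <- train_config(seed = 11)
  net <- build_network(arch, 7L, cfg)
  # one block (7 -> 16, projection needed) + linear head:
  # W1 7*16 + b1 16 + 2 BN pairs (gamma,beta) 4*16 + W2 16*16 + b2 16 + P 7*16
  # + head 16 + 1
  expect_equal(n_params(net), 7 * 16 + 16 + 4 * 16 + 16 * 16 + 16 + 7 * 16 + 17)

  net2 <- build_network(arch, 7L, cfg)
  expect_identical(net, net2)                       # bit-identical init

  # shape contract: 3 modalities, one output per observation row
  arch3 <- architecture_spec(n1 = c(4, 8, 8), depths = c(1, 1, 1),
                             fusion_depth = 1, fusion_n1 = 6)
  net3 <- build_network(arch3, c(3L, 10L, 30L), cfg)
  xs <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(50), 5, 10),
             matrix(rnorm(150), 5, 30))
  expect_length(predict(net3, xs), 5)

  expect_error(build_network(arch, 0L, cfg), "zero-width")
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- architecture_spec(n1 = c(4, 6), depths = c(2, 1), fusion_depth = 1,
                            fusion_n1 = 5)
  cfg <- train_config(lambda_l2 = 1e-3, dropout = 0, seed = 3)
  net <- build_network(arch, c(3L, 5L), cfg, seed = 3)
  set.seed(42)
  xs <- list(matrix(rnorm(24), 8, 3), matrix(rnorm(40), 8, 5))
  y <- rnorm(8)
  loss_fn <- function(nn) {
    fw <- mmgp:::.net_forward(nn, xs, train = TRUE)
    mean((fw$yhat - y)^2) + cfg$lambda_l2 * mmgp:::.l2_penalty(nn)
  }
  fw <- mmgp:::.net_forward(net, xs, train = TRUE)
  gr <- mmgp:::.net_backward(net, fw$caches, fw$yhat, y)

  nudge <- function(obj, path, i, d) {
    if (length(path) == 1L) {
      obj[[path[[1]]]][i] <- obj[[path[[1]]]][i] + d
    } else {
      obj[[path[[1]]]] <- nudge(obj[[path[[1]]]], path[-1], i, d)
    }
    obj
  }
  probe <- list(
    list(g = gr$modalities[[1]][[1]]$W1, path = list("modalities", 1, "blocks", 1, "W1")),
    list(g = gr$modalities[[1]][[2]]$gamma2, path = list("modalities", 1, "blocks", 2, "gamma2")),
    list(g = gr$modalities[[2]][[1]]$W2, path = list("modalities", 2, "blocks", 1, "W2")),
    list(g = gr$fusion[[1]]$P, path = list("fusion", "blocks", 1, "P")),
    list(g = gr$fusion[[1]]$beta1, path = list("fusion", "blocks", 1, "beta1")),
    list(g = gr$head$W, path = list("head", "W")))
  h <- 1e-5
  for (pr in probe) {
    set.seed(7); idx <- sample(length(pr$g), min(3, length(pr$g)))
    for (i in idx) {
      num <- (loss_fn(nudge(net, pr$path, i, h)) -
                loss_fn(nudge(net, pr$path, i, -h))) / (2 * h)
      expect_equal(pr$g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("the network overfits a small linear target (capacity check)", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(40, 0, 0.05)
  arch <- architecture_spec(n1 = 64, depths = 1, fusion_depth = 0)
  cfg <- train_config(lambda_l2 = 1e-8, dropout = 0, lr0 = 0.02,
                      weight_decay_rate = 0, patience = 48, epochs = 48,
                      seed = 7)
  tr <- train_network(build_network(arch, 5L, cfg), list(X), y, cfg)
  mse <- mean((predict(tr$net, list(X)) - y)^2)
  expect_lt(mse, 0.05 * var(y))

  # fixed seed, fixed data: bit-identical loss history and weights
  tr2 <- train_network(build_network(arch, 5L, cfg), list(X), y, cfg)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$net, tr2$net)
})

test_that("early stopping waits out the configured patience", {
  set.seed(2)
  X <- matrix(rnorm(20 * 3), 20, 3)    # one batch per epoch: loss is
  y <- rnorm(20)                       # shuffle-invariant when lr = 0
  arch <- architecture_spec(n1 = 8, depths = 1, fusion_depth = 0)
  cfg <- train_config(lr0 = 0, dropout = 0, patience = 1, epochs = 48, seed = 5)
  tr <- train_network(build_network(arch, 3L, cfg), list(X), y, cfg)
  expect_equal(nrow(tr$history), 2L)
  expect_equal(tr$history$loss[1], tr$history$loss[2], tolerance = 1e-12)

  # patience >= epochs disables early stopping
  cfg2 <- train_config(lr0 = 0.01, dropout = 0, patience = 48, epochs = 10,
                       seed = 5)
  tr2 <- train_network(build_network(arch, 3L, cfg2), list(X), y, cfg2)
  expect_equal(nrow(tr2$history), 10L)
})

test_that("inference is deterministic: batch partitioning and dropout do not matter", {
  set.seed(3)
  arch <- architecture_spec(n1 = c(6, 12), depths = c(1, 2), fusion_depth = 1,
                            fusion_n1 = 8)
  cfg <- train_config(dropout = 0.3, lr0 = 0.01, epochs = 5, seed = 9)
  X1 <- matrix(rnorm(30 * 4), 30, 4); X2 <- matrix(rnorm(30 * 9), 30, 9)
  y <- rnorm(30)
  tr <- train_network(build_network(arch, c(4L, 9L), cfg), list(X1, X2), y, cfg)

  # whole-set vs row-by-row prediction
  all_at_once <- predict(tr$net, list(X1, X2))
  one_by_one <- vapply(1:30, function(i)
    predict(tr$net, list(X1[i, , drop = FALSE], X2[i, , drop = FALSE])),
    numeric(1))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-5)

  # dropout rate is irrelevant once weights are frozen
  net_d <- tr$net; net_d$cfg$dropout <- 0.49
  expect_identical(predict(net_d, list(X1, X2)), all_at_once)

  # duplicated input rows give identical predictions
  Xd1 <- X1[c(1, 1), , drop = FALSE]; Xd2 <- X2[c(1, 1), , drop = FALSE]
  pd <- predict(tr$net, list(Xd1, Xd2))
  expect_equal(pd[1], pd[2])
})

test_that("stronger L2 regularization yields smaller final weight norms", {
  set.seed(4)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- as.numeric(X %*% rnorm(6)) + rnorm(60, 0, 0.2)
  arch <- architecture_spec(n1 = 16, depths = 1, fusion_depth = 0)
  norms <- vapply(c(1e-8, 1e-4, 1e-2), function(lam) {
    cfg <- train_config(lambda_l2 = lam, dropout = 0, lr0 = 0.01,
                        epochs = 30, patience = 30, seed = 6)
    tr <- train_network(build_network(arch, 6L, cfg), list(X), y, cfg)
    mmgp:::.l2_penalty(tr$net)
  }, numeric(1))
  expect_lt(norms[2], norms[1] * 1.05)
  expect_lt(norms[3], norms[2] * 1.05)
})

test_that("training aborts on a non-finite loss with a diagnostic naming the epoch", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- c(rnorm(39), NaN)
  arch <- architecture_spec(n1 = 8, depths = 1, fusion_depth = 0)
  cfg <- train_config(lr0 = 0.01, dropout = 0, epochs = 5, seed = 2)
  expect_error(train_network(build_network(arch, 3L, cfg), list(X), y, cfg),
               "epoch 1")
})
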