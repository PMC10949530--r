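#' Layer widths under the halving rule
#'
#' Width of hidden level l is `floor(N1 / 2^(l-1))`, clamped below at 1, for
#' l = 1..L.
#'
#' @param N1 width of the first hidden level (>= 1).
#' @param L number of hidden levels (>= 1).
#' @return integer vector of L widths.
#' @export
derive_layer_widths <- function(N1, L) {
  stopifnot(N1 >= 1, L >= 1)
  pmax(1L, as.integer(floor(N1 / 2^(seq_len(L) - 1))))
}

#' Architecture of the multi-modal regressor
#'
#' One residual MLP per modality (depths and first-level widths per modality,
#' later levels follow the halving rule), late fusion by concatenation of the
#' modality representations, an optional fusion residual MLP, and a single
#' linear output neuron. `fusion_depth = 0` feeds the concatenation directly
#' to the output neuron.
#'
#' @param n1 integer vector: first-level width of each modality subnetwork.
#' @param depths integer vector (same length): residual-block count per
#'   modality; one hidden level = one residual block.
#' @param fusion_depth residual-block count of the fusion network (>= 0).
#' @param fusion_n1 first-level width of the fusion network (ignored when
#'   `fusion_depth` is 0).
#' @return an `architecture_spec`.
#' @export
architecture_spec <- function(n1, depths, fusion_depth = 0, fusion_n1 = 0) {
  stopifnot(length(n1) == length(depths), all(n1 >= 1), all(depths >= 1),
            fusion_depth >= 0, fusion_depth == 0 || fusion_n1 >= 1)
  structure(list(Q = length(n1), n1 = as.integer(n1),
                 depths = as.integer(depths),
                 fusion_depth = as.integer(fusion_depth),
                 fusion_n1 = as.integer(fusion_n1)),
            class = "architecture_spec")
}

#' Training protocol configuration
#'
#' Defaults follow the study protocol: minibatches of 32, at most 48 epochs,
#' Adam, an exponentially decaying learning rate
#' `lr(epoch) = lr0 * exp(-weight_decay_rate * (epoch - 1))`, and early
#' stopping on the training loss with the given patience.
#'
#' @param lambda_l2 L2 penalty on dense-layer and output weights.
#' @param dropout dropout rate in `[0, 1)` applied after each residual block.
#' @param lr0 initial Adam learning rate.
#' @param weight_decay_rate decay rate of the exponential LR schedule.
#' @param patience consecutive non-improving epochs tolerated before stopping;
#'   `patience >= epochs` disables early stopping.
#' @param batch_size minibatch size (default 32).
#' @param epochs maximum epochs (default 48).
#' @param seed RNG seed controlling initialization order, shuffling, dropout.
#' @param monitor `"train"` (protocol default) or `"val"` loss for early
#'   stopping.
#' @return a `train_config`.
#' @export
train_config <- function(lambda_l2 = 1e-4, dropout = 0, lr0 = 1e-3,
                         weight_decay_rate = 0.05, patience = 48,
                         batch_size = 32, epochs = 48, seed = 1L,
                         monitor = c("train", "val")) {
  monitor <- match.arg(monitor)
  stopifnot(lambda_l2 >= 0, dropout >= 0, dropout < 1, lr0 >= 0,
            weight_decay_rate >= 0, patience >= 1, batch_size >= 1, epochs >= 1)
  structure(list(lambda_l2 = lambda_l2, dropout = dropout, lr0 = lr0,
                 weight_decay_rate = weight_decay_rate,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 monitor = monitor),
            class = "train_config")
}

.bn_eps <- 1e-3
.bn_momentum <- 0.99

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

.new_block <- function(win, w) {
  proj <- if (win != w) .glorot(win, w) else NULL
  list(W1 = .glorot(win, w), b1 = rep(0, w),
       gamma1 = rep(1, w), beta1 = rep(0, w),
       rmean1 = rep(0, w), rvar1 = rep(1, w),
       W2 = .glorot(w, w), b2 = rep(0, w),
       gamma2 = rep(1, w), beta2 = rep(0, w),
       rmean2 = rep(0, w), rvar2 = rep(1, w),
       P = proj, win = win, w = w)
}

#' Build an untrained multi-modal network
#'
#' Each hidden level is one residual block: dense -> batch norm -> ReLU ->
#' dense -> batch norm -> add skip (a linear projection when the widths
#' differ) -> ReLU -> dropout. Batch normalization precedes each activation.
#' Weights are Glorot-uniform, drawn deterministically from `seed`.
#'
#' @param arch an [architecture_spec()].
#' @param input_widths integer vector of per-modality feature counts
#'   (length `arch$Q`).
#' @param cfg a [train_config()] (regularization/dropout rates are read at
#'   train and inference time).
#' @param seed initialization seed; defaults to `cfg$seed`.
#' @return an `mm_network`.
#' @export
build_network <- function(arch, input_widths, cfg = train_config(),
                          seed = cfg$seed) {
  stopifnot(inherits(arch, "architecture_spec"),
            length(input_widths) == arch$Q)
  if (any(input_widths < 1)) stop("zero-width input modality")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  modalities <- vector("list", arch$Q)
  rep_widths <- integer(arch$Q)
  for (q in seq_len(arch$Q)) {
    widths <- derive_layer_widths(arch$n1[q], arch$depths[q])
    blocks <- vector("list", length(widths))
    win <- input_widths[q]
    for (k in seq_along(widths)) {
      blocks[[k]] <- .new_block(win, widths[k])
      win <- widths[k]
    }
    modalities[[q]] <- list(blocks = blocks)
    rep_widths[q] <- win
  }
  fusion_in <- sum(rep_widths)
  fusion_blocks <- list()
  win <- fusion_in
  if (arch$fusion_depth > 0) {
    widths <- derive_layer_widths(arch$fusion_n1, arch$fusion_depth)
    fusion_blocks <- vector("list", length(widths))
    for (k in seq_along(widths)) {
      fusion_blocks[[k]] <- .new_block(win, widths[k])
      win <- widths[k]
    }
  }
  head <- list(W = .glorot(win, 1), b = 0)

  structure(list(arch = arch, input_widths = as.integer(input_widths),
                 rep_widths = rep_widths,
                 modalities = modalities,
                 fusion = list(blocks = fusion_blocks),
                 head = head, cfg = cfg,
                 y_center = 0, y_scale = 1, trained = FALSE),
            class = "mm_network")
}

#' @export
print.mm_network <- function(x, ...) {
  cat(sprintf("mm_network: %d modalities (inputs %s), %d parameters%s\n",
              x$arch$Q, paste(x$input_widths, collapse = "/"),
              n_params(x), if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net an `mm_network`.
#' @return integer count (dense weights, biases, batch-norm scale/shift).
#' @export
n_params <- function(net) {
  cnt <- function(b) {
    length(b$W1) + length(b$b1) + length(b$gamma1) + length(b$beta1) +
      length(b$W2) + length(b$b2) + length(b$gamma2) + length(b$beta2) +
      length(b$P)
  }
  s <- sum(vapply(net$modalities, function(m)
    sum(vapply(m$blocks, cnt, numeric(1))), numeric(1)))
  s <- s + sum(vapply(net$fusion$blocks, cnt, numeric(1)))
  as.integer(s + length(net$head$W) + length(net$head$b))
}

# ---- forward / backward primitives -------------------------------------

.bn_forward <- function(Z, gamma, beta, rmean, rvar, train) {
  if (train) {
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2L, mu, "-")
    v <- colMeans(Zc^2)
    istd <- 1 / sqrt(v + .bn_eps)
    xhat <- sweep(Zc, 2L, istd, "*")
    out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
    list(out = out, xhat = xhat, Zc = Zc, istd = istd,
         rmean = .bn_momentum * rmean + (1 - .bn_momentum) * mu,
         rvar = .bn_momentum * rvar + (1 - .bn_momentum) * v)
  } else {
    istd <- 1 / sqrt(rvar + .bn_eps)
    xhat <- sweep(sweep(Z, 2L, rmean, "-"), 2L, istd, "*")
    out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
    list(out = out)
  }
}

.bn_backward <- function(dY, cache, gamma) {
  m <- nrow(cache$xhat)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dZ <- sweep(t1 - t2, 2L, cache$istd, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

.block_forward <- function(b, X, train, dropout) {
  z1 <- sweep(X %*% b$W1, 2L, b$b1, "+")
  bn1 <- .bn_forward(z1, b$gamma1, b$beta1, b$rmean1, b$rvar1, train)
  a1 <- pmax(bn1$out, 0)
  z2 <- sweep(a1 %*% b$W2, 2L, b$b2, "+")
  bn2 <- .bn_forward(z2, b$gamma2, b$beta2, b$rmean2, b$rvar2, train)
  skip <- if (is.null(b$P)) X else X %*% b$P
  pre <- bn2$out + skip
  out <- pmax(pre, 0)
  mask <- NULL
  if (train && dropout > 0) {
    mask <- matrix(stats::runif(length(out)) >= dropout, nrow(out), ncol(out))
    out <- out * mask / (1 - dropout)
  }
  list(out = out, cache = list(X = X, bn1 = bn1, a1 = a1, bn2 = bn2,
                               pre = pre, mask = mask, dropout = dropout))
}

.block_backward <- function(b, dOut, cache) {
  if (!is.null(cache$mask))
    dOut <- dOut * cache$mask / (1 - cache$dropout)
  dpre <- dOut * (cache$pre > 0)
  bn2b <- .bn_backward(dpre, cache$bn2, b$gamma2)
  dz2 <- bn2b$dZ
  dW2 <- crossprod(cache$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, b$W2)
  dbn1 <- da1 * (cache$bn1$out > 0)
  bn1b <- .bn_backward(dbn1, cache$bn1, b$gamma1)
  dz1 <- bn1b$dZ
  dW1 <- crossprod(cache$X, dz1)
  db1 <- colSums(dz1)
  if (is.null(b$P)) {
    dX <- tcrossprod(dz1, b$W1) + dpre
    dP <- NULL
  } else {
    dX <- tcrossprod(dz1, b$W1) + tcrossprod(dpre, b$P)
    dP <- crossprod(cache$X, dpre)
  }
  list(dX = dX,
       grads = list(W1 = dW1, b1 = db1, gamma1 = bn1b$dgamma, beta1 = bn1b$dbeta,
                    W2 = dW2, b2 = db2, gamma2 = bn2b$dgamma, beta2 = bn2b$dbeta,
                    P = dP))
}

# full forward pass; returns yhat (standardized scale), caches, and updated
# running statistics when train = TRUE
.net_forward <- function(net, xs, train = FALSE) {
  dropout <- net$cfg$dropout
  reps <- vector("list", net$arch$Q)
  caches <- list(modalities = vector("list", net$arch$Q), fusion = NULL)
  for (q in seq_len(net$arch$Q)) {
    H <- xs[[q]]
    blocks <- net$modalities[[q]]$blocks
    bc <- vector("list", length(blocks))
    for (k in seq_along(blocks)) {
      fw <- .block_forward(blocks[[k]], H, train, dropout)
      H <- fw$out
      bc[[k]] <- fw$cache
      if (train) {
        net$modalities[[q]]$blocks[[k]]$rmean1 <- fw$cache$bn1$rmean
        net$modalities[[q]]$blocks[[k]]$rvar1 <- fw$cache$bn1$rvar
        net$modalities[[q]]$blocks[[k]]$rmean2 <- fw$cache$bn2$rmean
        net$modalities[[q]]$blocks[[k]]$rvar2 <- fw$cache$bn2$rvar
      }
    }
    reps[[q]] <- H
    caches$modalities[[q]] <- bc
  }
  H <- do.call(cbind, reps)
  fb <- net$fusion$blocks
  fc <- vector("list", length(fb))
  if (length(fb)) {
    for (k in seq_along(fb)) {
      fw <- .block_forward(fb[[k]], H, train, dropout)
      H <- fw$out
      fc[[k]] <- fw$cache
      if (train) {
        net$fusion$blocks[[k]]$rmean1 <- fw$cache$bn1$rmean
        net$fusion$blocks[[k]]$rvar1 <- fw$cache$bn1$rvar
        net$fusion$blocks[[k]]$rmean2 <- fw$cache$bn2$rmean
        net$fusion$blocks[[k]]$rvar2 <- fw$cache$bn2$rvar
      }
    }
  }
  caches$fusion <- fc
  caches$H <- H
  yhat <- as.numeric(H %*% net$head$W + net$head$b)
  list(yhat = yhat, caches = caches, net = net)
}

# L2 penalty over dense weights (W1, W2, P) and the output weights
.l2_penalty <- function(net) {
  s <- 0
  acc <- function(b) sum(b$W1^2) + sum(b$W2^2) + if (is.null(b$P)) 0 else sum(b$P^2)
  for (m in net$modalities) for (b in m$blocks) s <- s + acc(b)
  for (b in net$fusion$blocks) s <- s + acc(b)
  s + sum(net$head$W^2)
}

# gradients of MSE + lambda * l2 for one batch; returns nested grads
.net_backward <- function(net, caches, yhat, y) {
  n <- length(y)
  lambda <- net$cfg$lambda_l2
  dyhat <- matrix(2 * (yhat - y) / n, ncol = 1)
  gW_head <- crossprod(caches$H, dyhat) + 2 * lambda * net$head$W
  gb_head <- sum(dyhat)
  dH <- dyhat %*% t(net$head$W)

  g_fusion <- vector("list", length(net$fusion$blocks))
  for (k in rev(seq_along(net$fusion$blocks))) {
    bb <- .block_backward(net$fusion$blocks[[k]], dH, caches$fusion[[k]])
    g_fusion[[k]] <- bb$grads
    g_fusion[[k]]$W1 <- g_fusion[[k]]$W1 + 2 * lambda * net$fusion$blocks[[k]]$W1
    g_fusion[[k]]$W2 <- g_fusion[[k]]$W2 + 2 * lambda * net$fusion$blocks[[k]]$W2
    if (!is.null(g_fusion[[k]]$P))
      g_fusion[[k]]$P <- g_fusion[[k]]$P + 2 * lambda * net$fusion$blocks[[k]]$P
    dH <- bb$dX
  }

  g_mod <- vector("list", net$arch$Q)
  off <- 0L
  for (q in seq_len(net$arch$Q)) {
    w <- net$rep_widths[q]
    dRep <- dH[, off + seq_len(w), drop = FALSE]
    off <- off + w
    blocks <- net$modalities[[q]]$blocks
    gq <- vector("list", length(blocks))
    for (k in rev(seq_along(blocks))) {
      bb <- .block_backward(blocks[[k]], dRep, caches$modalities[[q]][[k]])
      gq[[k]] <- bb$grads
      gq[[k]]$W1 <- gq[[k]]$W1 + 2 * lambda * blocks[[k]]$W1
      gq[[k]]$W2 <- gq[[k]]$W2 + 2 * lambda * blocks[[k]]$W2
      if (!is.null(gq[[k]]$P)) gq[[k]]$P <- gq[[k]]$P + 2 * lambda * blocks[[k]]$P
      dRep <- bb$dX
    }
    g_mod[[q]] <- gq
  }
  list(modalities = g_mod, fusion = g_fusion,
       head = list(W = gW_head, b = gb_head))
}

# ---- Adam over the nested parameter structure ---------------------------

.param_keys <- c("W1", "b1", "gamma1", "beta1", "W2", "b2", "gamma2", "beta2", "P")

.zero_like_block <- function(b) {
  out <- lapply(.param_keys, function(k) if (is.null(b[[k]])) NULL else b[[k]] * 0)
  names(out) <- .param_keys
  out
}

.init_adam <- function(net) {
  zb <- function(blocks) lapply(blocks, .zero_like_block)
  st <- list(modalities = lapply(net$modalities, function(m) zb(m$blocks)),
             fusion = zb(net$fusion$blocks),
             head = list(W = net$head$W * 0, b = 0))
  list(m = st, v = st, t = 0L)
}

.adam_blocks <- function(blocks, grads, m, v, lr, t,
                         b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  for (k in seq_along(blocks)) {
    for (key in .param_keys) {
      g <- grads[[k]][[key]]
      if (is.null(g)) next
      m[[k]][[key]] <- b1 * m[[k]][[key]] + (1 - b1) * g
      v[[k]][[key]] <- b2 * v[[k]][[key]] + (1 - b2) * g^2
      mh <- m[[k]][[key]] / (1 - b1^t)
      vh <- v[[k]][[key]] / (1 - b2^t)
      blocks[[k]][[key]] <- blocks[[k]][[key]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(blocks = blocks, m = m, v = v)
}

.adam_step <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (q in seq_len(net$arch$Q)) {
    up <- .adam_blocks(net$modalities[[q]]$blocks, grads$modalities[[q]],
                       state$m$modalities[[q]], state$v$modalities[[q]], lr, t,
                       b1, b2, eps)
    net$modalities[[q]]$blocks <- up$blocks
    state$m$modalities[[q]] <- up$m
    state$v$modalities[[q]] <- up$v
  }
  if (length(net$fusion$blocks)) {
    up <- .adam_blocks(net$fusion$blocks, grads$fusion,
                       state$m$fusion, state$v$fusion, lr, t, b1, b2, eps)
    net$fusion$blocks <- up$blocks
    state$m$fusion <- up$m
    state$v$fusion <- up$v
  }
  for (key in c("W", "b")) {
    g <- grads$head[[key]]
    state$m$head[[key]] <- b1 * state$m$head[[key]] + (1 - b1) * g
    state$v$head[[key]] <- b2 * state$v$head[[key]] + (1 - b2) * g^2
    mh <- state$m$head[[key]] / (1 - b1^t)
    vh <- state$v$head[[key]] / (1 - b2^t)
    net$head[[key]] <- net$head[[key]] - lr * mh / (sqrt(vh) + eps)
  }
  list(net = net, state = state)
}

# coerce inputs to a plain list of matrices
.as_input_list <- function(inputs) {
  if (inherits(inputs, "modality_inputs"))
    stop("pass modality_list(inputs, predictor) so the modality subset is explicit")
  stopifnot(is.list(inputs))
  lapply(inputs, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
}

#' Select the modality blocks a predictor uses
#'
#' @param mi a `modality_inputs`.
#' @param predictor `"E+G+GE"` (X_E, X_L, X_EL), `"E+G"` (X_E, X_L) or `"G"`
#'   (X_L only; the single-modality network used under
#'   leave-one-environment-out).
#' @return named list of input matrices.
#' @export
modality_list <- function(mi, predictor = c("E+G+GE", "E+G", "G")) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(mi, "modality_inputs"))
  switch(predictor,
         "E+G+GE" = list(E = mi$X_E, L = mi$X_L, EL = mi$X_EL),
         "E+G" = list(E = mi$X_E, L = mi$X_L),
         "G" = list(L = mi$X_L))
}

#' Train a multi-modal network
#'
#' Minimizes mean squared error plus L2 penalties with Adam, minibatches of
#' `cfg$batch_size`, at most `cfg$epochs` epochs, learning rate
#' `lr0 * exp(-weight_decay_rate * (epoch - 1))`, stopping early after
#' `patience` consecutive epochs without improvement of the monitored loss.
#' Responses are standardized internally on the training set (zero mean, unit
#' variance) and predictions are returned on the original scale. The run is
#' deterministic given `cfg$seed`.
#'
#' @param net an untrained (or warm) `mm_network` from [build_network()].
#' @param inputs list of per-modality matrices (see [modality_list()]), equal
#'   row counts.
#' @param y numeric response vector.
#' @param cfg a [train_config()]; defaults to the one stored in `net`.
#' @param val_inputs,val_y optional validation set scored each epoch.
#' @return list with `net` (trained) and `history` (data.frame of per-epoch
#'   train/validation loss on the standardized scale, penalty included).
#' @export
train_network <- function(net, inputs, y, cfg = net$cfg,
                          val_inputs = NULL, val_y = NULL) {
  stopifnot(inherits(net, "mm_network"), inherits(cfg, "train_config"))
  xs <- .as_input_list(inputs)
  n <- length(y)
  stopifnot(all(vapply(xs, nrow, integer(1)) == n))
  net$cfg <- cfg

  net$y_center <- mean(y)
  net$y_scale <- stats::sd(y)
  if (!is.finite(net$y_scale) || net$y_scale <= 0) net$y_scale <- 1
  ys <- (y - net$y_center) / net$y_scale
  if (!is.null(val_inputs)) {
    vxs <- .as_input_list(val_inputs)
    vys <- (val_y - net$y_center) / net$y_scale
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)

  state <- .init_adam(net)
  best <- Inf; wait <- 0L
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 * exp(-cfg$weight_decay_rate * (epoch - 1))
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    batches <- lapply(starts, function(s) idx[s:min(s + cfg$batch_size - 1L, n)])
    nb <- length(batches)
    if (nb > 1L && length(batches[[nb]]) == 1L) {   # avoid degenerate BN batch
      batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
      batches[[nb]] <- NULL
    }
    sse <- 0
    for (bt in batches) {
      bx <- lapply(xs, function(m) m[bt, , drop = FALSE])
      fw <- .net_forward(net, bx, train = TRUE)
      net <- fw$net
      err <- fw$yhat - ys[bt]
      if (!all(is.finite(err)))
        stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                     epoch))
      grads <- .net_backward(net, fw$caches, fw$yhat, ys[bt])
      up <- .adam_step(net, grads, state, lr)
      net <- up$net; state <- up$state
      sse <- sse + sum(err^2)
    }
    pen <- cfg$lambda_l2 * .l2_penalty(net)
    loss <- sse / n + pen
    val_loss <- NA_real_
    if (!is.null(val_inputs)) {
      pv <- .net_forward(net, vxs, train = FALSE)$yhat
      val_loss <- mean((pv - vys)^2) + pen
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, loss)
    hist_val <- c(hist_val, val_loss)

    monitored <- if (cfg$monitor == "val" && !is.null(val_inputs)) val_loss else loss
    if (monitored < best) {
      best <- monitored; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  net$trained <- TRUE
  list(net = net,
       history = data.frame(epoch = hist_epoch, loss = hist_loss,
                            val_loss = hist_val))
}

#' Predict from a multi-modal network
#'
#' Deterministic inference pass: dropout disabled, batch normalization using
#' running statistics, predictions de-standardized to the response scale.
#'
#' @param object an `mm_network`.
#' @param inputs list of per-modality matrices with the trained widths.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mm_network <- function(object, inputs, ...) {
  xs <- .as_input_list(inputs)
  if (!identical(unname(vapply(xs, ncol, integer(1))),
                 unname(object$input_widths)))
    stop("input widths (", paste(vapply(xs, ncol, integer(1)), collapse = "/"),
         ") do not match the trained shapes (",
         paste(object$input_widths, collapse = "/"), ")")
  yhat <- .net_forward(object, xs, train = FALSE)$yhat
  yhat * object$y_scale + object$y_center
}
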