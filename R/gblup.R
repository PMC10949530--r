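#' Configuration for the Bayesian GBLUP Gibbs sampler
#'
#' @param n_iter total Gibbs iterations (default 6000).
#' @param burn_in iterations discarded (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 5).
#' @param df0 prior degrees of freedom of the scaled-inverse-chi-squared
#'   variance priors (default 5).
#' @param R2 prior fraction of the phenotypic variance assigned to the random
#'   terms, split equally among them; the remainder goes to the residual
#'   (default 0.5). Prior scales are set so the prior mode of each variance
#'   matches its share.
#' @param seed RNG seed for the chain.
#' @return a `gblup_config` list.
#' @export
gblup_config <- function(n_iter = 6000, burn_in = 1000, thin = 5,
                         df0 = 5, R2 = 0.5, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, df0 > 0, R2 > 0, R2 < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df0 = df0, R2 = R2,
                 seed = as.integer(seed)),
            class = "gblup_config")
}

# Shared design setup for the sampler and the closed-form solver.
# Fixed effects are parameterized as intercept + (I-1) environment contrasts
# (treatment coding) to avoid rank deficiency; reported effects are
# re-expressed as mu + centered full environment effects.
.gblup_design <- function(y, obs, G, predictor) {
  stopifnot(inherits(G, "grm"))
  obs <- as.data.frame(obs)
  stopifnot(all(c("env", "line") %in% names(obs)), length(y) == nrow(obs))
  env <- as.character(obs$env)
  line <- as.character(obs$line)
  li <- match(line, G$line_ids)
  if (anyNA(li))
    stop("lines not indexed in G: ",
         paste(utils::head(unique(line[is.na(li)]), 5), collapse = ", "))
  env_levels <- sort(unique(env))
  I <- length(env_levels)
  include_E <- predictor %in% c("E+G", "E+G+GE") && I >= 2
  if (predictor %in% c("E+G", "E+G+GE") && I < 2)
    stop("environment effects requested but fewer than 2 environments observed")
  ei <- match(env, env_levels)
  X <- matrix(1, length(y), 1)
  if (include_E) {
    for (i in 2:I) X <- cbind(X, as.numeric(ei == i))
  }
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design; drop an environment level")
  list(y = as.numeric(y), env = env, line = line, li = li, ei = ei,
       env_levels = env_levels, I = I, include_E = include_E,
       include_gE = (predictor == "E+G+GE"), X = X)
}

# env-mean re-expression: beta (intercept + contrasts) -> (mu, full env effects)
.reexpress_env <- function(beta, env_levels, include_E) {
  I <- length(env_levels)
  if (!include_E) {
    mu <- beta[1]
    env_eff <- stats::setNames(rep(0, I), env_levels)
  } else {
    means <- beta[1] + c(0, beta[-1])
    mu <- mean(means)
    env_eff <- stats::setNames(means - mu, env_levels)
  }
  list(mu = mu, env_effects = env_eff)
}

#' Fit the Bayesian GBLUP mixed model by Gibbs sampling
#'
#' Fits `Y_ij = mu + E_i + g_j + gE_ij + e_ij` with flat priors on the general
#' mean and environment effects, `g ~ N(0, sigma_g^2 G)`,
#' `gE ~ N(0, sigma_gE^2 (I kron G))`, independent errors, and
#' scaled-inverse-chi-squared priors on the three variances. The random
#' effects are reparameterized as `g = B u` with `B = U D^(1/2)` from the
#' eigendecomposition of G (so `u` has iid prior coordinates), and the Gram
#' matrix of each term's observed feature block is eigendecomposed once, which
#' makes every full-conditional update a pair of matrix-vector products.
#' The interaction term is updated per environment, exploiting the block
#' diagonal structure of `I kron G`; no (I*J)^2 array is ever formed.
#'
#' @param y numeric response vector.
#' @param obs data.frame with columns `env`, `line`, one row per element of `y`.
#' @param G a `grm` indexing every observed line (prediction may involve
#'   additional lines of G unobserved in training).
#' @param config a [gblup_config()].
#' @param predictor one of `"E+G+GE"`, `"E+G"`, `"G"`.
#' @return a `gblup_fit` with posterior means (`mu`, `env_effects`, `g`, `gE`,
#'   `var_g`, `var_gE`, `var_e`), thinned posterior samples, and the fit index.
#' @export
fit_gblup <- function(y, obs, G, config = gblup_config(),
                      predictor = c("E+G+GE", "E+G", "G")) {
  predictor <- match.arg(predictor)
  d <- .gblup_design(y, obs, G, predictor)
  n <- length(d$y); J <- length(G$line_ids); I <- d$I

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  eg <- eigen(G$G, symmetric = TRUE)
  dvals <- pmax(eg$values, max(eg$values) * 1e-12)
  B <- eg$vectors %*% diag(sqrt(dvals), J)          # g = B u, u ~ N(0, sg2 I)
  Bl <- B[d$li, , drop = FALSE]

  eig_g <- eigen(crossprod(Bl), symmetric = TRUE)
  Vg <- eig_g$vectors; lg <- pmax(eig_g$values, 0)

  env_rows <- split(seq_len(n), d$ei)
  if (d$include_gE) {
    eig_ge <- lapply(env_rows, function(r) {
      e <- eigen(crossprod(Bl[r, , drop = FALSE]), symmetric = TRUE)
      list(V = e$vectors, l = pmax(e$values, 0))
    })
  }

  X <- d$X
  XtX <- crossprod(X)
  Rx <- chol(XtX)

  vy <- stats::var(d$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  n_rand <- 1L + d$include_gE
  df0 <- config$df0
  mdG <- mean(dvals)                                 # mean eigenvalue = mean diag G
  S0_g <- vy * config$R2 / n_rand * (df0 + 2) / df0 / mdG
  S0_e <- vy * (1 - config$R2) * (df0 + 2) / df0

  beta <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, d$y)))
  u <- rep(0, J)
  uE <- matrix(0, J, I)
  var_g <- vy * config$R2 / n_rand * mdG
  var_gE <- if (d$include_gE) var_g else 0
  var_e <- vy * (1 - config$R2)
  fit_g <- rep(0, n); fit_gE <- rep(0, n)

  keep <- seq(config$burn_in + config$thin, config$n_iter, by = config$thin)
  n_keep <- length(keep)
  s_mu <- numeric(n_keep); s_env <- matrix(0, n_keep, I)
  s_var <- matrix(0, n_keep, 3, dimnames = list(NULL, c("var_g", "var_gE", "var_e")))
  s_g <- matrix(0, J, n_keep)
  s_gE <- if (d$include_gE) array(0, c(I, J, n_keep)) else NULL
  k <- 0L

  for (it in seq_len(config$n_iter)) {
    # fixed effects
    e0 <- d$y - fit_g - fit_gE
    bhat <- backsolve(Rx, forwardsolve(t(Rx), crossprod(X, e0)))
    beta <- bhat + sqrt(var_e) * backsolve(Rx, stats::rnorm(ncol(X)))
    xb <- as.numeric(X %*% beta)

    # line effects u | rest
    e1 <- d$y - xb - fit_gE
    rhs <- crossprod(Bl, e1) / var_e
    t1 <- crossprod(Vg, rhs)
    w <- 1 / (lg / var_e + 1 / var_g)
    u <- as.numeric(Vg %*% (t1 * w + sqrt(w) * stats::rnorm(J)))
    fit_g <- as.numeric(Bl %*% u)

    # interaction effects per environment block
    if (d$include_gE) {
      e2 <- d$y - xb - fit_g
      for (i in seq_len(I)) {
        r <- env_rows[[i]]
        rhs_i <- crossprod(Bl[r, , drop = FALSE], e2[r]) / var_e
        t2 <- crossprod(eig_ge[[i]]$V, rhs_i)
        wi <- 1 / (eig_ge[[i]]$l / var_e + 1 / var_gE)
        uE[, i] <- as.numeric(eig_ge[[i]]$V %*% (t2 * wi + sqrt(wi) * stats::rnorm(J)))
        fit_gE[r] <- Bl[r, , drop = FALSE] %*% uE[, i]
      }
    }

    # variances
    var_g <- (sum(u^2) + df0 * S0_g) / stats::rchisq(1, J + df0)
    if (d$include_gE)
      var_gE <- (sum(uE^2) + df0 * S0_g) / stats::rchisq(1, I * J + df0)
    resid <- d$y - xb - fit_g - fit_gE
    var_e <- (sum(resid^2) + df0 * S0_e) / stats::rchisq(1, n + df0)

    if (it %in% keep) {
      k <- k + 1L
      re <- .reexpress_env(beta, d$env_levels, d$include_E)
      s_mu[k] <- re$mu; s_env[k, ] <- re$env_effects
      s_var[k, ] <- c(var_g, var_gE, var_e)
      s_g[, k] <- B %*% u
      if (d$include_gE) for (i in seq_len(I)) s_gE[i, , k] <- B %*% uE[, i]
    }
  }

  gE_mean <- if (d$include_gE) apply(s_gE, c(1, 2), mean) else matrix(0, I, J)
  dimnames(gE_mean) <- list(d$env_levels, G$line_ids)
  structure(list(
    mu = mean(s_mu),
    env_effects = stats::setNames(colMeans(s_env), d$env_levels),
    g = stats::setNames(rowMeans(s_g), G$line_ids),
    gE = gE_mean,
    var_g = mean(s_var[, "var_g"]),
    var_gE = mean(s_var[, "var_gE"]),
    var_e = mean(s_var[, "var_e"]),
    posterior_samples = list(mu = s_mu, env_effects = s_env, variances = s_var,
                             g = s_g),
    predictor = predictor, include_E = d$include_E,
    env_levels = d$env_levels, line_ids = G$line_ids,
    config = config, method = "gibbs"
  ), class = "gblup_fit")
}

#' Closed-form BLUP at fixed variance components
#'
#' Solves Henderson's mixed-model equations for
#' `Y_ij = mu + E_i + g_j + gE_ij + e_ij` at the given variances; this is the
#' deterministic oracle against which the Gibbs sampler is validated.
#'
#' @inheritParams fit_gblup
#' @param sigma_g2,sigma_gE2,sigma_e2 fixed variance components; set
#'   `sigma_gE2 = 0` (with a predictor lacking GE) to drop the interaction.
#' @return a `gblup_fit` (method `"mme"`) with exact `mu`, `env_effects`, `g`,
#'   `gE` and no posterior samples.
#' @export
blup_closed_form <- function(y, obs, G, sigma_g2, sigma_gE2 = 0, sigma_e2,
                             predictor = c("E+G+GE", "E+G", "G")) {
  predictor <- match.arg(predictor)
  stopifnot(sigma_g2 > 0, sigma_e2 > 0, sigma_gE2 >= 0)
  d <- .gblup_design(y, obs, G, predictor)
  if (d$include_gE && sigma_gE2 <= 0)
    stop("predictor includes GE but sigma_gE2 is 0")
  n <- length(d$y); J <- length(G$line_ids); I <- d$I
  X <- d$X; p <- ncol(X)

  Zg <- matrix(0, n, J); Zg[cbind(seq_len(n), d$li)] <- 1
  Ginv <- chol2inv(chol(G$G))

  blocks <- list(X, Zg)
  pen <- list(matrix(0, p, p), Ginv * (sigma_e2 / sigma_g2))
  if (d$include_gE) {
    Zge <- matrix(0, n, I * J)
    Zge[cbind(seq_len(n), (d$ei - 1L) * J + d$li)] <- 1
    blocks <- c(blocks, list(Zge))
    Pge <- matrix(0, I * J, I * J)
    for (i in seq_len(I)) {
      idx <- ((i - 1L) * J + 1L):(i * J)
      Pge[idx, idx] <- Ginv * (sigma_e2 / sigma_gE2)
    }
    pen <- c(pen, list(Pge))
  }
  W <- do.call(cbind, blocks)
  C <- crossprod(W) + as.matrix(Matrix_bdiag(pen))
  sol <- solve(C, crossprod(W, d$y))

  beta <- sol[seq_len(p)]
  g <- stats::setNames(sol[p + seq_len(J)], G$line_ids)
  gE <- matrix(0, I, J, dimnames = list(d$env_levels, G$line_ids))
  if (d$include_gE)
    gE[] <- matrix(sol[p + J + seq_len(I * J)], I, J, byrow = TRUE)
  re <- .reexpress_env(beta, d$env_levels, d$include_E)
  structure(list(
    mu = re$mu, env_effects = re$env_effects, g = g, gE = gE,
    var_g = sigma_g2, var_gE = sigma_gE2, var_e = sigma_e2,
    posterior_samples = NULL,
    predictor = predictor, include_E = d$include_E,
    env_levels = d$env_levels, line_ids = G$line_ids,
    config = NULL, method = "mme"
  ), class = "gblup_fit")
}

# small block-diagonal helper (dense; desk scale only)
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  off <- 0L
  for (m in mats) {
    idx <- off + seq_len(nrow(m))
    out[idx, idx] <- m
    off <- off + nrow(m)
  }
  out
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("gblup_fit (%s, predictor %s): var_g=%.4f var_gE=%.4f var_e=%.4f\n",
              x$method, x$predictor, x$var_g, x$var_gE, x$var_e))
  invisible(x)
}

#' Predict observations from a fitted GBLUP model
#'
#' `yhat = mu + E_i + g_j + gE_ij`, omitting terms absent from the fitted
#' predictor. Lines must be indexed in G (information is borrowed through G
#' even for lines unobserved in training). Environments unseen in training
#' (the leave-one-environment-out case) contribute neither an environment nor
#' an interaction term.
#'
#' @param object a `gblup_fit`.
#' @param newobs data.frame with columns `env`, `line`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gblup_fit <- function(object, newobs, ...) {
  newobs <- as.data.frame(newobs)
  env <- as.character(newobs$env)
  line <- as.character(newobs$line)
  li <- match(line, object$line_ids)
  if (anyNA(li))
    stop("unknown line(s): ",
         paste(utils::head(unique(line[is.na(li)]), 5), collapse = ", "))
  ei <- match(env, object$env_levels)
  yhat <- rep(object$mu, nrow(newobs)) + object$g[li]
  known <- !is.na(ei)
  if (object$include_E)
    yhat[known] <- yhat[known] + object$env_effects[ei[known]]
  if (object$predictor == "E+G+GE")
    yhat[known] <- yhat[known] + object$gE[cbind(ei[known], li[known])]
  unname(yhat)
}
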