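#' The default hyperparameter search space
#'
#' Bounds for the multi-modal network: per-modality depths L1 in (1,4), L2 and
#' L3 in (1,6); fusion depth L in (0,4); first-level widths N1(1) in (0,128),
#' N2(1) and N3(1) in (1,1024), fusion width N(1) in (0,200); L2 penalty
#' lambda in (1e-8, 1e-2); dropout DO in (1e-4, 0.5); log weight decay lwd in
#' (ln 4e-5, ln 4e-1); patience Pat in (0,128); log learning rate llr in
#' (ln 1e-8, ln 1e-2). Integer dimensions are rounded then clamped at decode
#' time (widths and Pat to >= 1, L to >= 0: a fusion depth of 0 is a
#' meaningful solution).
#'
#' @return a `search_space` data.frame with columns `name`, `lower`, `upper`,
#'   `integer`, `exp_transform`.
#' @export
default_search_space <- function() {
  ss <- data.frame(
    name = c("L1", "L2", "L3", "L", "N1", "N2", "N3", "N",
             "lambda", "DO", "lwd", "Pat", "llr"),
    lower = c(1, 1, 1, 0, 0, 1, 1, 0, 1e-8, 1e-4, log(4e-5), 0, log(1e-8)),
    upper = c(4, 6, 6, 4, 128, 1024, 1024, 200, 1e-2, 0.5, log(4e-1), 128,
              log(1e-2)),
    integer = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE, TRUE, FALSE),
    exp_transform = c(rep(FALSE, 10), TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  class(ss) <- c("search_space", class(ss))
  ss
}

#' Make a custom search space
#' @param name,lower,upper,integer,exp_transform per-dimension vectors;
#'   `exp_transform` marks log-scale dimensions exponentiated at decode time.
#' @return a `search_space` data.frame.
#' @export
search_space <- function(name, lower, upper, integer = rep(FALSE, length(name)),
                         exp_transform = rep(FALSE, length(name))) {
  stopifnot(length(lower) == length(name), length(upper) == length(name),
            all(lower < upper))
  ss <- data.frame(name = name, lower = lower, upper = upper,
                   integer = integer, exp_transform = exp_transform,
                   stringsAsFactors = FALSE)
  class(ss) <- c("search_space", class(ss))
  ss
}

#' Decode a raw search-space point
#'
#' Integer dimensions are rounded to the nearest integer and clamped inside
#' their meaningful range (widths and patience to >= 1; depths named `"L"` may
#' be 0); log-scale dimensions are exponentiated.
#'
#' @param raw named numeric vector within the bounds of `space`.
#' @param space a `search_space`.
#' @return named list of decoded values.
#' @export
decode_point <- function(raw, space) {
  stopifnot(length(raw) == nrow(space))
  if (is.null(names(raw))) names(raw) <- space$name
  raw <- raw[space$name]
  out_of <- raw < space$lower - 1e-9 | raw > space$upper + 1e-9
  if (any(out_of))
    stop("raw point outside bounds in dimension(s): ",
         paste(space$name[out_of], collapse = ", "))
  vals <- as.list(raw)
  for (i in seq_len(nrow(space))) {
    v <- raw[i]
    if (space$integer[i]) {
      v <- round(v)
      floor_at <- if (space$name[i] == "L") 0 else 1
      v <- max(floor_at, min(v, round(space$upper[i])))
    } else if (space$exp_transform[i]) {
      v <- exp(v)
    }
    vals[[i]] <- as.vector(v)
  }
  names(vals) <- space$name
  vals
}

#' Decode a raw point of the default space into network configuration
#'
#' @param raw named numeric vector over [default_search_space()].
#' @param space the search space (default space by default).
#' @return list with `arch` (an [architecture_spec()] for the three modalities
#'   E, L, EL) and `train` (a [train_config()]); `lwd` and `llr` arrive
#'   exponentiated as `weight_decay_rate` and `lr0`.
#' @export
decode_dl_config <- function(raw, space = default_search_space()) {
  v <- decode_point(raw, space)
  arch <- architecture_spec(n1 = c(v$N1, v$N2, v$N3),
                            depths = c(v$L1, v$L2, v$L3),
                            fusion_depth = v$L,
                            fusion_n1 = if (v$L > 0) v$N else 0)
  cfg <- train_config(lambda_l2 = v$lambda, dropout = v$DO,
                      lr0 = v$llr, weight_decay_rate = v$lwd,
                      patience = v$Pat)
  list(arch = arch, train = cfg)
}

#' Inner train/validation split for hyperparameter scoring
#'
#' Partitions the training index into 10 seeded folds; folds 1-2 (20%) form
#' the validation set and folds 3-10 the sub-training set.
#'
#' @param train_index integer (or id) vector of training observations.
#' @param seed split seed.
#' @param n_folds number of inner folds (default 10).
#' @param n_val_folds folds used for validation (default 2).
#' @return list with `subtrain` and `val`, disjoint with union `train_index`.
#' @export
make_inner_split <- function(train_index, seed, n_folds = 10, n_val_folds = 2) {
  n <- length(train_index)
  if (n < n_folds)
    stop("need at least ", n_folds, " training observations, got ", n)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  list(subtrain = train_index[fold > n_val_folds],
       val = train_index[fold <= n_val_folds])
}

# ---- Gaussian-process expected-improvement optimizer --------------------

.matern52 <- function(D) (1 + sqrt(5) * D + 5 * D^2 / 3) * exp(-sqrt(5) * D)

.unit_scale <- function(X, space) {
  sweep(sweep(X, 2L, space$lower, "-"), 2L, space$upper - space$lower, "/")
}

.gp_fit <- function(X, y, lengthscales = c(0.1, 0.2, 0.5, 1)) {
  ys <- scale(y)
  mu <- attr(ys, "scaled:center"); sdy <- attr(ys, "scaled:scale")
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- as.numeric((y - mu) / sdy)
  n <- length(ys)
  best <- NULL; best_ml <- -Inf
  for (ell in lengthscales) {
    D <- as.matrix(stats::dist(X / ell))
    K <- .matern52(D) + diag(1e-6, n)
    R <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(R)) next
    alpha <- backsolve(R, forwardsolve(t(R), ys))
    ml <- -0.5 * sum(ys * alpha) - sum(log(diag(R)))
    if (ml > best_ml) {
      best_ml <- ml
      best <- list(X = X, R = R, alpha = alpha, ell = ell, mu = mu, sdy = sdy)
    }
  }
  best
}

.gp_predict <- function(gp, Xnew) {
  Dx <- sqrt(outer(rowSums(Xnew^2), rep(1, nrow(gp$X))) +
               outer(rep(1, nrow(Xnew)), rowSums(gp$X^2)) -
               2 * tcrossprod(Xnew, gp$X))
  Dx[!is.finite(Dx) | Dx < 0] <- 0
  Kx <- .matern52(Dx / gp$ell)
  mean_s <- as.numeric(Kx %*% gp$alpha)
  Vx <- forwardsolve(t(gp$R), t(Kx))
  var_s <- pmax(1 + 1e-6 - colSums(Vx^2), 1e-12)
  list(mean = mean_s * gp$sdy + gp$mu, sd = sqrt(var_s) * gp$sdy)
}

.expected_improvement <- function(mean_, sd_, best) {
  z <- (best - mean_) / sd_
  (best - mean_) * stats::pnorm(z) + sd_ * stats::dnorm(z)
}

#' Bayesian optimization over a box-bounded search space
#'
#' Minimizes `objective(raw)` where `raw` is a named numeric vector within the
#' bounds of `space`. Strategy `"gp"` runs a Gaussian-process
#' (Matern-5/2, shared lengthscale chosen by marginal likelihood) expected-
#' improvement loop: `n_init` seeded space-filling points followed by
#' EI-maximizing proposals (candidate search), with the budget counting all
#' objective evaluations. Strategy `"random"` evaluates the same budget of
#' seeded uniform points. Deterministic given `seed` and a deterministic
#' objective.
#'
#' @param objective function(raw named vector) -> finite numeric score
#'   (lower is better); may return `NA`/`Inf` for a failed trial.
#' @param space a `search_space`.
#' @param n_iter total objective evaluations (default 50).
#' @param n_init initial space-filling evaluations (default 10, capped at
#'   `n_iter`).
#' @param seed RNG seed.
#' @param strategy `"gp"` or `"random"`.
#' @return list with `best` (list `raw`, `score`, `trial`) and `history`
#'   (data.frame: trial, the raw coordinates, score, incumbent score).
#' @export
bayes_optimize <- function(objective, space, n_iter = 50, n_init = 10,
                           seed = 1L, strategy = c("gp", "random")) {
  strategy <- match.arg(strategy)
  stopifnot(n_iter >= 1)
  n_init <- min(n_init, n_iter)
  d <- nrow(space)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  runif_box <- function(n) {
    m <- matrix(stats::runif(n * d), n, d)
    sweep(sweep(m, 2L, space$upper - space$lower, "*"), 2L, space$lower, "+")
  }
  # stratified (Latin-hypercube style) initial design
  lhs_box <- function(n) {
    m <- vapply(seq_len(d), function(j)
      (sample.int(n) - stats::runif(n)) / n, numeric(n))
    m <- matrix(m, n, d)
    sweep(sweep(m, 2L, space$upper - space$lower, "*"), 2L, space$lower, "+")
  }

  X <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, space$name))
  scores <- rep(NA_real_, n_iter)
  n_planned_init <- if (strategy == "gp") n_init else n_iter
  init_pts <- lhs_box(n_planned_init)

  eval_at <- function(x) {
    s <- tryCatch(objective(stats::setNames(as.numeric(x), space$name)),
                  error = function(e) NA_real_)
    if (!is.finite(s)) NA_real_ else s
  }

  for (t in seq_len(n_iter)) {
    if (t <= n_planned_init) {
      x <- init_pts[t, ]
    } else {
      done <- !is.na(scores[seq_len(t - 1)])
      if (sum(done) >= 2) {
        Xu <- .unit_scale(X[seq_len(t - 1), , drop = FALSE][done, , drop = FALSE],
                          space)
        gp <- .gp_fit(Xu, scores[seq_len(t - 1)][done])
      } else gp <- NULL
      if (is.null(gp)) {
        x <- runif_box(1)[1, ]
      } else {
        cand <- runif_box(max(500, 200 * d))
        # local candidates around the incumbent
        inc <- X[which.min(scores[seq_len(t - 1)]), ]
        loc <- matrix(rep(inc, each = 100), 100, d) +
          matrix(stats::rnorm(100 * d), 100, d) *
          matrix(rep(0.05 * (space$upper - space$lower), each = 100), 100, d)
        loc <- pmin(pmax(loc, matrix(rep(space$lower, each = 100), 100, d)),
                    matrix(rep(space$upper, each = 100), 100, d))
        cand <- rbind(cand, loc)
        pr <- .gp_predict(gp, .unit_scale(cand, space))
        ei <- .expected_improvement(pr$mean, pr$sd,
                                    min(scores, na.rm = TRUE))
        x <- cand[which.max(ei), ]
      }
    }
    X[t, ] <- x
    scores[t] <- eval_at(x)
  }

  if (all(is.na(scores)))
    stop("all trials failed; inspect the history of raw points")
  best_t <- which.min(scores)
  incumbent <- cummin(ifelse(is.na(scores), Inf, scores))
  history <- data.frame(trial = seq_len(n_iter), X, score = scores,
                        incumbent = incumbent, check.names = FALSE)
  list(best = list(raw = stats::setNames(X[best_t, ], space$name),
                   score = scores[best_t], trial = best_t),
       history = history, strategy = strategy, seed = seed)
}
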