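#' Seeded k-fold assignment over observations
#'
#' Balanced partition into k folds, stratified by environment so each fold
#' mirrors the environment composition. In normal mode a fold's role is test
#' (train on the other k-1); with `invert_roles = TRUE` the roles flip: train
#' on the single fold, test on the other k-1 (the small-training-fraction
#' protocol, e.g. k = 20 gives a 5% training fraction). `repeats` re-randomize
#' the partition with seeds derived from `seed`.
#'
#' @param obs data.frame with columns `env`, `line`.
#' @param k number of folds (>= 2, <= number of observations).
#' @param seed partition seed.
#' @param invert_roles train on one fold instead of k-1.
#' @param repeats independent re-randomizations (default 1).
#' @return a `fold_assignment`: list with `scheme`, `k`, `folds` (n x repeats
#'   integer matrix of fold labels), `invert_roles`, `seed`, `obs`.
#' @export
kfold_split <- function(obs, k = 5, seed = 1L, invert_roles = FALSE,
                        repeats = 1L) {
  obs <- as.data.frame(obs)
  n <- nrow(obs)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of observations")
  env <- as.character(obs$env)
  folds <- matrix(0L, n, repeats)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * (r - 1L))
    f <- integer(n)
    for (e in unique(env)) {
      idx <- which(env == e)
      f[idx] <- sample(rep_len(sample.int(k), length(idx)))
    }
    # rebalance across strata: total fold sizes may differ by > 1 after
    # stratification; move observations from the largest to the smallest fold
    repeat {
      sizes <- tabulate(f, k)
      if (max(sizes) - min(sizes) <= 1L) break
      from <- which.max(sizes); to <- which.min(sizes)
      mv <- which(f == from)[1]
      f[mv] <- to
    }
    folds[, r] <- f
  }
  structure(list(scheme = if (invert_roles) "kfold_inverted" else "kfold",
                 k = as.integer(k), folds = folds,
                 invert_roles = invert_roles, seed = as.integer(seed),
                 obs = obs),
            class = "fold_assignment")
}

#' Train/test indices for one fold of an assignment
#' @param fa a `fold_assignment` from [kfold_split()].
#' @param fold fold label in 1..k.
#' @param rep repeat column (default 1).
#' @return list with integer vectors `train` and `test`.
#' @export
fold_indices <- function(fa, fold, rep = 1L) {
  stopifnot(inherits(fa, "fold_assignment"), fold >= 1, fold <= fa$k)
  in_fold <- fa$folds[, rep] == fold
  if (fa$invert_roles) list(train = which(in_fold), test = which(!in_fold))
  else list(train = which(!in_fold), test = which(in_fold))
}

#' Leave-one-environment-out assignments
#'
#' One assignment per environment: the whole environment is the test set, all
#' other environments the training set. Environments with zero observations
#' are excluded with a warning. Interaction predictors are meaningless here
#' (the held-out environment has no training interaction term); callers fit
#' with predictor `"G"` or `"E+G"` only.
#'
#' @param obs data.frame with columns `env`, `line`.
#' @param env_levels optional environment set to iterate over.
#' @return list of elements `list(test_env, train, test)` (integer indices).
#' @export
loeo_split <- function(obs, env_levels = NULL) {
  obs <- as.data.frame(obs)
  env <- as.character(obs$env)
  if (is.null(env_levels)) env_levels <- sort(unique(env))
  counts <- table(factor(env, levels = env_levels))
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("excluding environment(s) with zero observations: ",
            paste(empty, collapse = ", "))
    env_levels <- setdiff(env_levels, empty)
  }
  if (length(env_levels) < 2) stop("need at least 2 non-empty environments")
  lapply(env_levels, function(e) {
    list(test_env = e, train = which(env != e), test = which(env == e)) })
}

#' Normalized root mean squared error
#'
#' RMSE divided by a normalizer of the observed values: their mean (default),
#' range, or standard deviation.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @param normalizer `"mean"`, `"range"`, or `"sd"`.
#' @return nonnegative scalar.
#' @export
nrmse <- function(observed, predicted, normalizer = c("mean", "range", "sd")) {
  normalizer <- match.arg(normalizer)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  rmse <- sqrt(mean((observed - predicted)^2))
  norm <- switch(normalizer,
                 mean = mean(observed),
                 range = diff(range(observed)),
                 sd = stats::sd(observed))
  if (!is.finite(norm) || norm == 0)
    stop("zero '", normalizer, "' normalizer; choose another normalizer")
  rmse / abs(norm)
}

#' Pearson correlation between observed and predicted values
#'
#' Errors on constant input rather than silently returning 0 or NA.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3).
#' @return correlation in [-1, 1].
#' @export
pearson_cor <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0) stop("observed vector is constant")
  if (stats::sd(predicted) == 0) stop("predicted vector is constant")
  stats::cor(observed, predicted)
}

#' Aggregate per-unit metric records
#'
#' Group means and sample standard deviations of `nrmse` and `cor` across
#' units (folds or environments), grouped by (model, trait, predictor), rows
#' ordered lexicographically by trait, model, predictor.
#'
#' @param records data.frame with columns `model`, `trait`, `predictor`,
#'   `unit`, `nrmse`, `cor`.
#' @return data.frame with per-group `nrmse`, `nrmse_sd`, `cor`, `cor_sd`,
#'   `n_units`, values rounded to 4 decimals.
#' @export
aggregate_metrics <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("model", "trait", "predictor", "nrmse", "cor") %in%
                  names(records)))
  key <- interaction(records$trait, records$model, records$predictor,
                     drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    r <- records[key == k, , drop = FALSE]
    data.frame(model = r$model[1], trait = r$trait[1],
               predictor = r$predictor[1],
               nrmse = round(mean(r$nrmse), 4),
               nrmse_sd = round(stats::sd(r$nrmse), 4),
               cor = round(mean(r$cor), 4),
               cor_sd = round(stats::sd(r$cor), 4),
               n_units = nrow(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare two matched metric tables
#'
#' Tables must carry identical (trait, predictor, unit) keys and columns
#' `nrmse` and `cor`. Win counts use strict inequality (a tie favors
#' neither): `b` wins NRMSE where `b$nrmse < a$nrmse` and wins Cor where
#' `b$cor > a$cor`. Relative differences are `100 * (x / y - 1)`, reported in
#' both directions per key. Grand means pool all rows of each table.
#'
#' @param a,b data.frames with key columns (`trait`, `predictor`, optionally
#'   `unit`) and metric columns `nrmse`, `cor`; `a` is the baseline.
#' @return a `comparison_summary`: list with `n_units`, `wins`, `rel_diff`
#'   (per-key data.frame with percentage columns rounded to 2 decimals),
#'   `grand_means`.
#' @export
compare_models <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  keys <- intersect(c("trait", "predictor", "unit"), names(a))
  stopifnot(length(keys) >= 1, all(keys %in% names(b)),
            all(c("nrmse", "cor") %in% names(a)),
            all(c("nrmse", "cor") %in% names(b)))
  ka <- do.call(paste, c(a[keys], sep = "\r"))
  kb <- do.call(paste, c(b[keys], sep = "\r"))
  if (anyDuplicated(ka) || anyDuplicated(kb)) stop("duplicate keys in a table")
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if (length(only_a) || length(only_b))
    stop("unmatched keys; only in a: [",
         paste(gsub("\r", "/", only_a), collapse = "; "),
         "], only in b: [", paste(gsub("\r", "/", only_b), collapse = "; "), "]")
  b <- b[match(ka, kb), , drop = FALSE]

  rel <- a[keys]
  rel$nrmse_b_vs_a_pct <- round(100 * (b$nrmse / a$nrmse - 1), 2)
  rel$nrmse_a_vs_b_pct <- round(100 * (a$nrmse / b$nrmse - 1), 2)
  rel$cor_b_vs_a_pct <- round(100 * (b$cor / a$cor - 1), 2)
  rel$cor_a_vs_b_pct <- round(100 * (a$cor / b$cor - 1), 2)

  structure(list(
    n_units = nrow(a),
    wins = list(
      nrmse = c(a = sum(a$nrmse < b$nrmse), b = sum(b$nrmse < a$nrmse),
                ties = sum(a$nrmse == b$nrmse)),
      cor = c(a = sum(a$cor > b$cor), b = sum(b$cor > a$cor),
              ties = sum(a$cor == b$cor))),
    rel_diff = rel,
    grand_means = list(
      a = c(nrmse = mean(a$nrmse), cor = mean(a$cor)),
      b = c(nrmse = mean(b$nrmse), cor = mean(b$cor)),
      pooled = c(nrmse = mean(c(a$nrmse, b$nrmse)),
                 cor = mean(c(a$cor, b$cor))))
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("comparison over %d matched units\n", x$n_units))
  cat(sprintf("  NRMSE wins: a=%d b=%d ties=%d | Cor wins: a=%d b=%d ties=%d\n",
              x$wins$nrmse["a"], x$wins$nrmse["b"], x$wins$nrmse["ties"],
              x$wins$cor["a"], x$wins$cor["b"], x$wins$cor["ties"]))
  cat(sprintf("  pooled grand means: NRMSE %.4f, Cor %.4f\n",
              x$grand_means$pooled["nrmse"], x$grand_means$pooled["cor"]))
  invisible(x)
}

#' Summarize per-fold optimal hyperparameter configurations
#'
#' Integer-valued hyperparameters are summarized by their mode (smallest value
#' on ties), real-valued ones by their arithmetic mean.
#'
#' @param trials data.frame, one row per fold/unit, hyperparameters in
#'   columns.
#' @param integer_cols,real_cols column names to summarize.
#' @return named list of summaries.
#' @export
summarize_hyperparams <- function(trials, integer_cols = character(),
                                  real_cols = character()) {
  trials <- as.data.frame(trials)
  stopifnot(nrow(trials) >= 1,
            all(c(integer_cols, real_cols) %in% names(trials)))
  mode_int <- function(x) {
    tab <- table(x)
    vals <- as.numeric(names(tab))
    vals[tab == max(tab)][which.min(vals[tab == max(tab)])]
  }
  out <- c(lapply(trials[integer_cols], mode_int),
           lapply(trials[real_cols], mean))
  out[c(integer_cols, real_cols)]
}

#' Bundled published 5-fold cross-validation metric table
#'
#' Transcription of the per-(model, trait, predictor) fold-averaged NRMSE and
#' Pearson-correlation summaries reported by a published large wheat
#' multi-environment genomic-prediction study (4,464 lines, five traits, two
#' predictors, GBLUP vs a multi-modal deep-learning model). Used as a worked
#' example for the aggregation and comparison utilities; these numbers are
#' inputs, not outputs, of this package.
#'
#' @return data.frame with columns `model`, `trait`, `predictor`, `nrmse`,
#'   `nrmse_sd`, `cor`, `cor_sd`.
#' @export
published_5fcv_metrics <- function() {
  path <- system.file("extdata", "published_5fcv_metrics.csv", package = "mmgp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled published leave-one-environment-out metric table
#'
#' Per-environment NRMSE and Pearson correlation of GBLUP and the multi-modal
#' deep-learning model under leave-one-environment-out prediction, from the
#' same published study as [published_5fcv_metrics()]. Long format: one row
#' per (model, trait, predictor, environment).
#'
#' @return data.frame with columns `model`, `trait`, `predictor`, `unit`
#'   (environment), `nrmse`, `cor`.
#' @export
published_loeo_metrics <- function() {
  path <- system.file("extdata", "published_loeo_metrics.csv", package = "mmgp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
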