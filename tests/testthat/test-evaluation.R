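test_that("k-fold splits are balanced, exhaustive, seeded, and invertible", {
  obs <- grid_obs(c("E1", "E2"), paste0("L", 1:5))   # 10 observations
  fa <- kfold_split(obs, k = 5, seed = 2)
  expect_equal(unname(sort(tabulate(fa$folds[, 1], 5))), rep(2L, 5))
  # partition property across folds
  test_sets <- lapply(1:5, function(f) fold_indices(fa, f)$test)
  expect_setequal(unlist(test_sets), seq_len(10))
  expect_equal(sum(lengths(test_sets)), 10L)

  # inverted roles: k = 20 trains on 1/20 = 5% of the data
  obs2 <- grid_obs(paste0("E", 1:2), paste0("L", 1:100))
  fi <- kfold_split(obs2, k = 20, seed = 5, invert_roles = TRUE)
  idx <- fold_indices(fi, 1)
  expect_equal(length(idx$train) / nrow(obs2), 0.05, tolerance = 0.01)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_setequal(c(idx$train, idx$test), seq_len(nrow(obs2)))

  # determinism and repeats
  fb <- kfold_split(obs, k = 5, seed = 2)
  expect_identical(fa$folds, fb$folds)
  fr <- kfold_split(obs2, k = 4, seed = 2, repeats = 3)
  expect_equal(ncol(fr$folds), 3L)
  for (r in 1:3)
    expect_setequal(unlist(lapply(1:4, function(f)
      which(fr$folds[, r] == f))), seq_len(nrow(obs2)))
  expect_error(kfold_split(obs, k = 1), "at least 2")
  expect_error(kfold_split(obs, k = 11), "exceeds")

  # property: random observation tables, every scheme partitions
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(20:60, 1); k <- sample(2:6, 1)
    o <- data.frame(env = sample(paste0("E", 1:3), n, replace = TRUE),
                    line = paste0("L", seq_len(n)))
    f <- kfold_split(o, k = k, seed = rep, invert_roles = rep %% 2 == 0)
    sizes <- tabulate(f$folds[, 1], k)
    expect_lte(max(sizes) - min(sizes), 1L)
    all_test <- unlist(lapply(1:k, function(j) fold_indices(f, j)$test))
    expect_equal(sort(unique(all_test)), seq_len(n))
  }
})

test_that("leave-one-environment-out holds out whole environments", {
  obs <- grid_obs(paste0("E", 1:4), paste0("L", 1:6))
  sp <- loeo_split(obs)
  expect_length(sp, 4)
  for (s in sp) {
    expect_setequal(c(s$train, s$test), seq_len(nrow(obs)))
    expect_length(intersect(s$train, s$test), 0)
    expect_true(all(obs$env[s$test] == s$test_env))
    expect_true(all(obs$env[s$train] != s$test_env))
  }
  expect_warning(loeo_split(obs, env_levels = c(paste0("E", 1:4), "E9")),
                 "zero observations")
  expect_error(loeo_split(obs[obs$env == "E1", ]), "at least 2")
})

test_that("NRMSE normalizes the RMSE by the chosen statistic", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(2, 2, 2, 2), c(1, 3, 1, 3)), 0.5)  # RMSE 1 / mean 2
  # scale invariance under the mean normalizer
  set.seed(3); o <- runif(20, 5, 10); p <- o + rnorm(20)
  expect_equal(nrmse(o, p), nrmse(10 * o, 10 * p), tolerance = 1e-12)
  expect_equal(nrmse(o, p, "sd"), sqrt(mean((o - p)^2)) / sd(o))
  expect_equal(nrmse(o, p, "range"), sqrt(mean((o - p)^2)) / diff(range(o)))
  expect_error(nrmse(c(-1, 1), c(0, 0)), "normalizer")
  # permutation invariance
  perm <- sample(20)
  expect_equal(nrmse(o[perm], p[perm]), nrmse(o, p))
})

test_that("Pearson correlation handles the canonical cases and rejects constants", {
  o <- c(1, 2, 3)
  expect_equal(pearson_cor(o, 2 * o + 1), 1)
  expect_equal(pearson_cor(o, -o), -1)
  expect_equal(pearson_cor(o, c(1, 3, 2)), 0.5)   # hand covariance/variances
  expect_error(pearson_cor(c(1, 1, 1), o), "constant")
  expect_error(pearson_cor(o, c(2, 2, 2)), "constant")
  set.seed(4); oo <- rnorm(15); pp <- rnorm(15); perm <- sample(15)
  expect_equal(pearson_cor(oo[perm], pp[perm]), pearson_cor(oo, pp))
})

test_that("aggregation reports group means and fold SDs in fixed order", {
  rec <- data.frame(model = "GBLUP", trait = "t", predictor = "E+G",
                    unit = c("f1", "f2"), nrmse = c(0.09, 0.11),
                    cor = c(0.5, 0.5))
  ag <- aggregate_metrics(rec)
  expect_equal(ag$nrmse, 0.10)
  expect_equal(ag$nrmse_sd, round(sd(c(0.09, 0.11)), 4))  # ~0.0141
  expect_equal(ag$cor_sd, 0)

  rec2 <- rbind(rec,
                transform(rec, model = "DL", nrmse = nrmse + 0.01),
                transform(rec, trait = "a"))
  ag2 <- aggregate_metrics(rec2)
  expect_equal(ag2$trait, c("a", "t", "t"))
  expect_equal(ag2$model, c("GBLUP", "DL", "GBLUP"))
})

test_that("model comparison counts strict wins and matched keys only", {
  a <- data.frame(trait = c("t1", "t1", "t2"), predictor = "G",
                  unit = c("u1", "u2", "u1"),
                  nrmse = c(0.10, 0.20, 0.30), cor = c(0.5, 0.6, 0.7))
  b <- a; b$nrmse <- c(0.09, 0.20, 0.31); b$cor <- c(0.55, 0.6, 0.65)
  cmp <- compare_models(a, b)
  expect_equal(unname(cmp$wins$nrmse), c(1, 1, 1))  # a wins, b wins, tie
  expect_equal(unname(cmp$wins$cor), c(1, 1, 1))
  # identical tables: zero wins everywhere, zero relative differences
  cmp0 <- compare_models(a, a)
  expect_equal(unname(cmp0$wins$nrmse[c("a", "b")]), c(0, 0))
  expect_true(all(cmp0$rel_diff$cor_b_vs_a_pct == 0))
  # unmatched keys error names the difference
  expect_error(compare_models(a, b[-1, ]), "unmatched keys")
})

test_that("hyperparameter summaries use mode for integers and mean for reals", {
  tr <- data.frame(L1 = c(1, 1, 2, 3, 1), lambda = c(0.002, 0.006, 0.004,
                                                     0.004, 0.004))
  s <- summarize_hyperparams(tr, integer_cols = "L1", real_cols = "lambda")
  expect_equal(s$L1, 1)
  expect_equal(s$lambda, 0.004)
  # smallest-on-tie rule
  s2 <- summarize_hyperparams(data.frame(L = c(2, 2, 3, 3)), integer_cols = "L")
  expect_equal(s2$L, 2)
  expect_equal(summarize_hyperparams(data.frame(x = c(0.002, 0.006)),
                                     real_cols = "x")$x, 0.004)
})
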