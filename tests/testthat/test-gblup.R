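# Henderson closed form is the deterministic oracle; the Gibbs sampler is
# validated against it and against parameter-recovery simulations.

test_that("closed-form BLUP matches a hand-built two-line system and shrinks correctly", {
  ids <- c("L1", "L2")
  G <- structure(list(G = diag(2), line_ids = ids, jitter = 0), class = "grm")
  dimnames(G$G) <- list(ids, ids)
  obs <- data.frame(env = c("E1", "E1"), line = ids)
  y <- c(1, 3)
  sg2 <- 0.8; se2 <- 0.4; lam <- se2 / sg2
  # hand system for (mu, g1, g2): [[2,1,1],[1,1+lam,0],[1,0,1+lam]]
  A <- matrix(c(2, 1, 1, 1, 1 + lam, 0, 1, 0, 1 + lam), 3, 3, byrow = TRUE)
  sol <- solve(A, c(sum(y), y))
  fit <- blup_closed_form(y, obs, G, sigma_g2 = sg2, sigma_e2 = se2,
                          predictor = "G")
  expect_equal(fit$mu, sol[1], tolerance = 1e-10)
  expect_equal(unname(fit$g), sol[2:3], tolerance = 1e-10)

  # sigma_g2 -> 0: effects vanish, predictions equal environment means
  obs2 <- grid_obs(c("E1", "E2"), paste0("L", 1:6))
  G6 <- structure(list(G = random_pd(6, 2), line_ids = paste0("L", 1:6),
                       jitter = 0), class = "grm")
  dimnames(G6$G) <- list(G6$line_ids, G6$line_ids)
  set.seed(3); y2 <- rnorm(12, rep(c(5, 9), each = 6))
  shr <- blup_closed_form(y2, obs2, G6, sigma_g2 = 1e-10, sigma_e2 = 1,
                          predictor = "E+G")
  expect_lt(max(abs(shr$g)), 1e-6)
  pred <- predict(shr, obs2)
  env_means <- ave(y2, obs2$env)
  expect_equal(pred, env_means, tolerance = 1e-5)

  # residual orthogonality to the fixed-effect design (normal equations)
  fit2 <- blup_closed_form(y2, obs2, G6, sigma_g2 = 0.7, sigma_gE2 = 0.3,
                           sigma_e2 = 0.5, predictor = "E+G+GE")
  resid <- y2 - predict(fit2, obs2)
  X <- cbind(1, as.numeric(obs2$env == "E2"))
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("closed-form BLUP is equivariant under line relabeling", {
  met <- simulate_met(sim_config(J = 30, I = 2, M = 150, seed = 7))
  G <- compute_grm(met$markers)
  obs <- met$phenotypes[, c("env", "line")]
  y <- met$phenotypes$value
  fit <- blup_closed_form(y, obs, G, sigma_g2 = 1, sigma_gE2 = 0.5,
                          sigma_e2 = 0.5)
  perm <- sample(30)
  Gp <- structure(list(G = G$G[perm, perm], line_ids = G$line_ids[perm],
                       jitter = G$jitter), class = "grm")
  fitp <- blup_closed_form(y, obs, Gp, sigma_g2 = 1, sigma_gE2 = 0.5,
                           sigma_e2 = 0.5)
  expect_equal(fitp$g[G$line_ids], fit$g, tolerance = 1e-8)
  expect_equal(predict(fitp, obs), predict(fit, obs), tolerance = 1e-8)
})

test_that("sampler interpolates noiseless data and matches ridge under G = I", {
  # noiseless limit: fitted values reproduce y nearly exactly
  met <- simulate_met(sim_config(J = 80, I = 2, M = 300, sigma_g2 = 1,
                                 sigma_gE2 = 0.3, sigma_e2 = 0, seed = 5))
  G <- compute_grm(met$markers)
  obs <- met$phenotypes[, c("env", "line")]
  y <- met$phenotypes$value
  fit <- fit_gblup(y, obs, G, gblup_config(n_iter = 1500, burn_in = 300,
                                           thin = 3, R2 = 0.999, seed = 2))
  expect_gt(cor(predict(fit, obs), y), 0.999)

  # G = identity, single environment, no interaction: ridge closed form
  J <- 120; ids <- sprintf("L%03d", 1:J)
  Gi <- structure(list(G = diag(J), line_ids = ids, jitter = 0), class = "grm")
  dimnames(Gi$G) <- list(ids, ids)
  set.seed(8)
  g_true <- rnorm(J)
  yr <- 2 + g_true + rnorm(J, 0, 0.5)
  obr <- data.frame(env = "E1", line = ids)
  fr <- fit_gblup(yr, obr, Gi, gblup_config(n_iter = 4000, burn_in = 1000,
                                            seed = 4), predictor = "G")
  lam <- fr$var_e / fr$var_g
  # independent ridge solve for (mu, g)
  X <- cbind(1, diag(J))
  P <- diag(c(0, rep(lam, J)))
  sol <- solve(crossprod(X) + P, crossprod(X, yr))
  g_ridge <- sol[-1]
  expect_lt(sqrt(mean((fr$g - g_ridge)^2)) / sd(g_ridge), 0.05)
})

test_that("sampler recovers variance components and agrees with the closed form", {
  # parameter recovery, 5 seed-fixed replicates at J=300, I=3. Marker count
  # 400 keeps G far from the identity: separating the G-structured
  # interaction variance from the iid residual requires real relatedness
  # structure, and with M >> J the simulated panel degenerates toward G = I
  # where that split is unidentifiable for any sampler.
  truth <- c(var_g = 1.0, var_gE = 0.5, var_e = 1.0)
  est <- matrix(0, 5, 3, dimnames = list(NULL, names(truth)))
  for (r in 1:5) {
    met <- simulate_met(sim_config(J = 300, I = 3, M = 400, sigma_g2 = 1,
                                   sigma_gE2 = 0.5, sigma_e2 = 1,
                                   seed = 100 + r))
    G <- compute_grm(met$markers)
    fit <- fit_gblup(met$phenotypes$value, met$phenotypes[, c("env", "line")],
                     G, gblup_config(n_iter = 2500, burn_in = 500, thin = 5,
                                     seed = r))
    est[r, ] <- c(fit$var_g, fit$var_gE, fit$var_e)
  }
  avg <- colMeans(est)
  expect_true(all(abs(avg / truth - 1) < 0.25),
              info = paste("posterior means:", paste(round(avg, 3), collapse = " ")))

  # closed-form equivalence at the sampler's posterior-mean variances (n=600)
  met <- simulate_met(sim_config(J = 200, I = 3, M = 400, sigma_g2 = 1,
                                 sigma_gE2 = 0.5, sigma_e2 = 1, seed = 42))
  G <- compute_grm(met$markers)
  obs <- met$phenotypes[, c("env", "line")]
  y <- met$phenotypes$value
  fit <- fit_gblup(y, obs, G, gblup_config(n_iter = 9000, burn_in = 1000,
                                           thin = 2, seed = 9))
  cf <- blup_closed_form(y, obs, G, sigma_g2 = fit$var_g,
                         sigma_gE2 = fit$var_gE, sigma_e2 = fit$var_e)
  expect_gt(cor(predict(fit, obs), predict(cf, obs)), 0.99)

  # two chains with different seeds agree on posterior-mean predictions
  fit2 <- fit_gblup(y, obs, G, gblup_config(n_iter = 9000, burn_in = 1000,
                                            thin = 2, seed = 10))
  p1 <- predict(fit, obs); p2 <- predict(fit2, obs)
  expect_lt(sqrt(mean((p1 - p2)^2)) / sd(p1), 0.02)
})

test_that("prediction uses only fitted terms and shrinks unlinked lines to the mean", {
  met <- simulate_met(sim_config(J = 50, I = 2, M = 300, seed = 13))
  G <- compute_grm(met$markers)
  obs <- met$phenotypes[, c("env", "line")]
  y <- met$phenotypes$value
  fitG <- fit_gblup(y, obs, G, gblup_config(n_iter = 800, burn_in = 200, seed = 1),
                    predictor = "G")
  newo <- grid_obs(c("E01", "E02"), G$line_ids[1:5])
  pg <- matrix(predict(fitG, newo), ncol = 2)
  expect_equal(pg[, 1], pg[, 2], tolerance = 1e-12)  # no environment term

  # a line uncorrelated to all training lines gets g ~ 0
  J <- 40; ids <- sprintf("L%03d", 1:J)
  Gi <- structure(list(G = diag(J), line_ids = ids, jitter = 0), class = "grm")
  dimnames(Gi$G) <- list(ids, ids)
  set.seed(2)
  obs_tr <- data.frame(env = "E1", line = ids[1:(J - 1)])
  ytr <- 5 + rnorm(J - 1)
  fi <- fit_gblup(ytr, obs_tr, Gi, gblup_config(n_iter = 800, burn_in = 200,
                                                seed = 3), predictor = "G")
  expect_lt(abs(fi$g[J]), 0.05 * sd(fi$g[1:(J - 1)]) + 1e-3)
  expect_equal(predict(fi, data.frame(env = "E1", line = ids[J])),
               fi$mu + fi$g[[J]], tolerance = 1e-10)

  expect_error(predict(fi, data.frame(env = "E1", line = "stranger")),
               "unknown line")
})

test_that("posterior bookkeeping and configuration guards hold", {
  cfgok <- gblup_config(n_iter = 600, burn_in = 100, thin = 5)
  expect_error(gblup_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(gblup_config(R2 = 1.2), "R2")
  met <- simulate_met(sim_config(J = 30, I = 2, M = 150, seed = 3))
  G <- compute_grm(met$markers)
  fit <- fit_gblup(met$phenotypes$value, met$phenotypes[, c("env", "line")], G,
                   cfgok)
  expect_equal(length(fit$posterior_samples$mu), (600 - 100) / 5)
  expect_true(all(fit$posterior_samples$variances > 0))
  # single environment forbids environment effects
  obs1 <- data.frame(env = "E01", line = met$phenotypes$line[1:30])
  expect_error(fit_gblup(rnorm(30), obs1, G, cfgok, predictor = "E+G"),
               "fewer than 2 environments")
})
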