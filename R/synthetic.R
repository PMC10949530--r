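#' Configuration for the synthetic multi-environment trial generator
#'
#' Defaults are the desk-scale profile: 300 lines, 3 environments, 2000
#' markers, allele frequencies in (0.1, 0.9), grand mean 10, environment-
#' effect SD 1, variance components (sigma_g2, sigma_gE2, sigma_e2) =
#' (1, 0.5, 0.5), i.e. realized narrow-sense heritability about 0.5.
#'
#' @param J line count. @param I environment count. @param M marker count.
#' @param freq_range allele-frequency sampling range, inside (0, 1).
#' @param mu grand mean of the trait.
#' @param env_effect_sd SD of the environment main effects.
#' @param sigma_g2,sigma_gE2,sigma_e2 variance components of the line,
#'   line-by-environment, and residual terms.
#' @param missing_pheno_fraction fraction of (environment, line) cells dropped
#'   at random from the phenotype table.
#' @param seed generator seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(J = 300, I = 3, M = 2000, freq_range = c(0.1, 0.9),
                       mu = 10, env_effect_sd = 1,
                       sigma_g2 = 1, sigma_gE2 = 0.5, sigma_e2 = 0.5,
                       missing_pheno_fraction = 0, seed = 1L) {
  stopifnot(J >= 1, I >= 1, M >= 1,
            freq_range[1] > 0, freq_range[2] < 1, freq_range[1] <= freq_range[2],
            sigma_g2 >= 0, sigma_gE2 >= 0, sigma_e2 >= 0,
            missing_pheno_fraction >= 0, missing_pheno_fraction < 1)
  structure(list(J = as.integer(J), I = as.integer(I), M = as.integer(M),
                 freq_range = freq_range, mu = mu,
                 env_effect_sd = env_effect_sd,
                 sigma_g2 = sigma_g2, sigma_gE2 = sigma_gE2,
                 sigma_e2 = sigma_e2,
                 missing_pheno_fraction = missing_pheno_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes
#'
#' Per marker an allele frequency p is drawn uniformly from the configured
#' range; line dosages are Binomial(2, p) mapped to \{-1, 0, +1\}.
#'
#' @param cfg a [sim_config()].
#' @return a recoded `marker_matrix` of dimensions J x M.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  p <- stats::runif(cfg$M, cfg$freq_range[1], cfg$freq_range[2])
  v <- vapply(seq_len(cfg$M), function(k)
    stats::rbinom(cfg$J, 2L, p[k]) - 1, numeric(cfg$J))
  v <- matrix(v, cfg$J, cfg$M)
  marker_matrix(v, line_ids = sprintf("L%04d", seq_len(cfg$J)),
                marker_ids = sprintf("M%05d", seq_len(cfg$M)),
                coding = "recoded")
}

#' Simulate phenotypes with the mixed-model structure
#'
#' Assembles `Y_ij = mu + E_i + g_j + gE_ij + e_ij`. The line effects are
#' drawn through marker effects, `g = W alpha` with
#' `alpha ~ N(0, sigma_g2 / c I_M)` on the centered marker matrix W and the
#' VanRaden scale c used by [compute_grm()], so that `cov(g | W) = sigma_g2 G`
#' exactly (up to G's diagonal jitter) while the draw commutes with any
#' relabeling of lines. Interaction effects are drawn the same way,
#' independently per environment, which realizes the `I kron G` covariance
#' block structure. Environment effects are N(0, env_effect_sd^2) and errors
#' iid N(0, sigma_e2). Effects are generated in sorted-line-id order so the
#' output is reproducible under row permutations of the marker matrix.
#'
#' @param markers a recoded, fully observed `marker_matrix` (J lines).
#' @param cfg a [sim_config()] (its J must match the marker matrix).
#' @return a `simulated_met`: list with `markers`, `phenotypes` (data.frame
#'   `env`, `line`, `trait`, `value`), and `truth` (mu, env_effects, g, gE
#'   matrix, variance components, seed).
#' @export
simulate_phenotypes <- function(markers, cfg) {
  stopifnot(inherits(markers, "marker_matrix"), inherits(cfg, "sim_config"))
  if (anyNA(markers$values)) stop("marker matrix has missing entries")
  J <- nrow(markers$values)
  stopifnot(J == cfg$J)
  ord <- order(markers$line_ids)
  ids <- markers$line_ids[ord]
  v <- markers$values[ord, , drop = FALSE]
  M <- ncol(v)
  W <- sweep(v, 2L, colMeans(v), "-")
  p <- (colMeans(v) + 1) / 2
  c_scale <- sum(2 * p * (1 - p))
  if (c_scale <= .Machine$double.eps) stop("all markers monomorphic")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed + 1L)

  env_ids <- sprintf("E%02d", seq_len(cfg$I))
  env_eff <- stats::rnorm(cfg$I, 0, cfg$env_effect_sd)
  g <- if (cfg$sigma_g2 > 0)
    as.numeric(W %*% stats::rnorm(M, 0, sqrt(cfg$sigma_g2 / c_scale)))
  else rep(0, J)
  gE <- matrix(0, cfg$I, J, dimnames = list(env_ids, ids))
  if (cfg$sigma_gE2 > 0) {
    for (i in seq_len(cfg$I))
      gE[i, ] <- as.numeric(W %*% stats::rnorm(M, 0, sqrt(cfg$sigma_gE2 / c_scale)))
  }
  eps <- matrix(stats::rnorm(cfg$I * J, 0, sqrt(cfg$sigma_e2)), cfg$I, J)

  ph <- expand.grid(line = ids, env = env_ids, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)[, c("env", "line")]
  ei <- match(ph$env, env_ids); li <- match(ph$line, ids)
  ph$trait <- "sim_trait"
  ph$value <- cfg$mu + env_eff[ei] + g[li] + gE[cbind(ei, li)] + eps[cbind(ei, li)]
  if (cfg$missing_pheno_fraction > 0) {
    keep <- stats::runif(nrow(ph)) >= cfg$missing_pheno_fraction
    ph <- ph[keep, , drop = FALSE]
    rownames(ph) <- NULL
  }
  structure(list(markers = markers, phenotypes = ph,
                 truth = list(mu = cfg$mu,
                              env_effects = stats::setNames(env_eff, env_ids),
                              g = stats::setNames(g, ids), gE = gE,
                              sigma_g2 = cfg$sigma_g2,
                              sigma_gE2 = cfg$sigma_gE2,
                              sigma_e2 = cfg$sigma_e2,
                              seed = cfg$seed)),
            class = "simulated_met")
}

#' Simulate a complete MET dataset
#' @param cfg a [sim_config()].
#' @return a `simulated_met` (see [simulate_phenotypes()]).
#' @export
simulate_met <- function(cfg = sim_config()) {
  simulate_phenotypes(simulate_genotypes(cfg), cfg)
}

#' @export
print.simulated_met <- function(x, ...) {
  cat(sprintf("simulated_met: %d phenotype records, %d lines x %d markers, h2 = %.3f\n",
              nrow(x$phenotypes), nrow(x$markers$values),
              ncol(x$markers$values), realized_h2(x)))
  invisible(x)
}

#' Realized heritability of a simulated MET
#'
#' Ratio of the variance of the realized line effects to the average
#' within-environment variance of `Y - mu - E_i` (line + interaction +
#' error), computed from the recorded truth.
#'
#' @param met a `simulated_met`.
#' @return fraction in [0, 1].
#' @export
realized_h2 <- function(met) {
  stopifnot(inherits(met, "simulated_met"))
  tr <- met$truth
  ph <- met$phenotypes
  ei <- match(ph$env, names(tr$env_effects))
  dev <- ph$value - tr$mu - tr$env_effects[ei]
  denom <- mean(tapply(dev, ph$env, stats::var))
  if (!is.finite(denom) || denom == 0) stop("zero phenotypic variance")
  num <- stats::var(tr$g)
  max(0, min(1, num / denom))
}
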