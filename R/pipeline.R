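#' Validate and normalize a run configuration
#'
#' A run configuration (R list or YAML file) drives [run_pipeline()]. Fields:
#' `seed`; `scheme` (`"5fcv"`, `"kfold_inverted"`, `"loeo"`); `k` (folds, for
#' the k-fold schemes); `model` (`"gblup"`, `"dl"`, `"both"`); `predictor`
#' (`"G"`, `"E+G"`, `"E+G+GE"`); `out_dir`; either `simulate` (a list of
#' [sim_config()] fields) or `genotypes`/`phenotypes` paths (marker CSV from
#' [write_marker_csv()] and a long phenotype CSV with columns env, line,
#' trait, value); optional `gblup` ([gblup_config()] fields) and `dl` (fields
#' `n1`, `depths`, `fusion_depth`, `fusion_n1` plus [train_config()] fields);
#' optional `qc` (`maf_threshold`, `missing_threshold`). The
#' leave-one-environment-out scheme forbids the interaction predictor: the
#' held-out environment has no training interaction term.
#'
#' @param config list or path to a YAML file.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, scheme = "5fcv", k = 5L, model = "both",
                   predictor = "E+G+GE", out_dir = "mmgp_results",
                   qc = list(maf_threshold = 0.05, missing_threshold = 0.5),
                   gblup = list(), dl = list())
  config <- utils::modifyList(defaults, config)
  config$scheme <- match.arg(config$scheme, c("5fcv", "kfold_inverted", "loeo"))
  config$model <- match.arg(config$model, c("both", "gblup", "dl"))
  config$predictor <- match.arg(config$predictor, c("E+G+GE", "E+G", "G"))
  if (config$scheme == "loeo" && config$predictor == "E+G+GE")
    stop("invalid config: scheme 'loeo' is incompatible with predictor ",
         "'E+G+GE' (no interaction term can be trained for a held-out ",
         "environment); use 'G' or 'E+G'")
  if (is.null(config$simulate) &&
      (is.null(config$genotypes) || is.null(config$phenotypes)))
    stop("config needs either 'simulate' or both 'genotypes' and 'phenotypes'")
  if (!is.null(config$genotypes) && !file.exists(config$genotypes))
    stop("genotypes file not found: ", config$genotypes)
  if (!is.null(config$phenotypes) && !file.exists(config$phenotypes))
    stop("phenotypes file not found: ", config$phenotypes)
  class(config) <- c("run_config", "list")
  config
}

# default desk-scale DL settings used when the config gives none
.dl_settings <- function(dl, predictor, seed) {
  arch_fields <- c("n1", "depths", "fusion_depth", "fusion_n1")
  q <- switch(predictor, "E+G+GE" = 3L, "E+G" = 2L, "G" = 1L)
  def_n1 <- c(8, 64, 64)[seq_len(q)]
  arch <- architecture_spec(
    n1 = if (!is.null(dl$n1)) dl$n1 else def_n1,
    depths = if (!is.null(dl$depths)) dl$depths else rep(1L, q),
    fusion_depth = if (!is.null(dl$fusion_depth)) dl$fusion_depth else 1L,
    fusion_n1 = if (!is.null(dl$fusion_n1)) dl$fusion_n1 else 32L)
  tc_args <- dl[setdiff(names(dl), arch_fields)]
  tc_args$seed <- seed
  if (is.null(tc_args$lr0)) tc_args$lr0 <- 0.01
  if (is.null(tc_args$weight_decay_rate)) tc_args$weight_decay_rate <- 0.02
  if (is.null(tc_args$lambda_l2)) tc_args$lambda_l2 <- 1e-4
  cfg <- do.call(train_config, tc_args)
  list(arch = arch, cfg = cfg)
}

# fit both model families on one train/test split; returns metric rows
.fit_one_split <- function(y, obs, idx, G, Fg, config, unit, trait) {
  tr <- idx$train; te <- idx$test
  train_obs <- obs[tr, , drop = FALSE]
  test_obs <- obs[te, , drop = FALSE]
  rows <- list()
  seed_i <- config$seed + 17L * unit

  if (config$model %in% c("both", "gblup")) {
    gc_args <- config$gblup; gc_args$seed <- seed_i
    gcfg <- do.call(gblup_config, gc_args)
    fit <- fit_gblup(y[tr], train_obs, G, gcfg, predictor = config$predictor)
    pred <- predict(fit, test_obs)
    rows[[length(rows) + 1L]] <- data.frame(
      model = "GBLUP", trait = trait, predictor = config$predictor,
      unit = as.character(unit), nrmse = nrmse(y[te], pred),
      cor = pearson_cor(y[te], pred), stringsAsFactors = FALSE)
  }
  if (config$model %in% c("both", "dl")) {
    env_levels <- sort(unique(train_obs$env))
    mi_tr <- build_modality_inputs(train_obs, Fg, env_levels = env_levels)
    mi_te <- build_modality_inputs(test_obs, Fg, env_levels = env_levels,
                                   unknown_env = "zero")
    dls <- .dl_settings(config$dl, config$predictor, seed_i)
    net <- build_network(dls$arch,
                         vapply(modality_list(mi_tr, config$predictor), ncol,
                                integer(1)),
                         dls$cfg)
    trained <- train_network(net, modality_list(mi_tr, config$predictor),
                             y[tr], dls$cfg)
    pred <- predict(trained$net, modality_list(mi_te, config$predictor))
    rows[[length(rows) + 1L]] <- data.frame(
      model = "DL", trait = trait, predictor = config$predictor,
      unit = as.character(unit), nrmse = nrmse(y[te], pred),
      cor = pearson_cor(y[te], pred), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full prediction pipeline from a configuration
#'
#' Executes QC, relationship-matrix construction, splitting, model fitting
#' and metric computation, and writes `metrics.csv` (one row per model per
#' fold/environment), `summary.csv` (aggregated), `qc_report.json` and
#' `run_info.json` to the output directory.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @return invisibly, a list with `metrics`, `summary`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, config$simulate)
    met <- simulate_met(scfg)
    markers <- met$markers
    ph <- met$phenotypes
  } else {
    markers <- read_marker_csv(config$genotypes)
    ph <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
    stopifnot(all(c("env", "line", "value") %in% names(ph)))
    if (is.null(ph$trait)) ph$trait <- "trait"
    if (!is.null(config$trait)) ph <- ph[ph$trait == config$trait, , drop = FALSE]
  }
  trait <- ph$trait[1]

  fm <- filter_markers(markers, config$qc$maf_threshold,
                       config$qc$missing_threshold)
  write_qc_report(fm$report, file.path(config$out_dir, "qc_report.json"))
  imputed <- impute_mean(fm$markers)
  G <- compute_grm(imputed)
  Fg <- chol_factor(G, orientation = "gram")

  obs <- ph[, c("env", "line")]
  y <- ph$value
  if (config$scheme == "loeo") {
    splits <- loeo_split(obs)
    metrics <- do.call(rbind, lapply(seq_along(splits), function(i) {
      m <- .fit_one_split(y, obs, splits[[i]], G, Fg, config, i, trait)
      m$unit <- splits[[i]]$test_env
      m
    }))
  } else {
    fa <- kfold_split(obs, k = config$k, seed = config$seed,
                      invert_roles = config$scheme == "kfold_inverted")
    metrics <- do.call(rbind, lapply(seq_len(fa$k), function(f)
      .fit_one_split(y, obs, fold_indices(fa, f), G, Fg, config, f, trait)))
  }
  rownames(metrics) <- NULL
  summary <- aggregate_metrics(metrics)

  num_fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 6) else col)
    df
  }
  utils::write.csv(num_fmt(metrics), file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(num_fmt(summary), file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  info <- list(seed = config$seed, scheme = config$scheme,
               predictor = config$predictor, model = config$model,
               r_version = as.character(getRversion()),
               config_hash = substr(paste(
                 as.hexmode(utils::head(utf8ToInt(paste(
                   deparse(config[order(names(config))]), collapse = "")), 64)),
                 collapse = ""), 1, 40))
  jsonlite::write_json(info, file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(metrics = metrics, summary = summary,
                 out_dir = config$out_dir))
}
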