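#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds G = W W' / c from a recoded, fully imputed marker matrix, where W has
#' marker columns centered at their means and c = sum_k 2 p_k (1 - p_k) with
#' p_k the `+1`-allele frequency of marker k on the 0/1/2 dosage scale. A small
#' diagonal jitter (`jitter_scale * mean(diag(G))`) is added so the matrix is
#' positive definite even with duplicated lines.
#'
#' @param m a recoded `marker_matrix` with no missing entries.
#' @param jitter_scale relative diagonal jitter; default `1e-6`.
#' @return an object of class `grm`: list with `G` (J x J symmetric matrix with
#'   line ids as dimnames), `line_ids`, `jitter` (the absolute value added to
#'   the diagonal).
#' @export
compute_grm <- function(m, jitter_scale = 1e-6) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$coding != "recoded") stop("compute_grm expects coding 'recoded'")
  v <- m$values
  if (anyNA(v)) stop("marker matrix has missing entries; run impute_mean() first")
  if (ncol(v) < 2L) stop("need at least 2 markers")
  p <- (colMeans(v) + 1) / 2           # +1-allele frequency on dosage/2 scale
  c_scale <- sum(2 * p * (1 - p))
  if (c_scale <= .Machine$double.eps)
    stop("all markers monomorphic: VanRaden denominator sum(2p(1-p)) is zero")
  W <- sweep(v, 2L, colMeans(v), "-")
  G <- tcrossprod(W) / c_scale
  G <- (G + t(G)) / 2
  jitter <- jitter_scale * mean(diag(G))
  diag(G) <- diag(G) + jitter
  dimnames(G) <- list(m$line_ids, m$line_ids)
  structure(list(G = G, line_ids = m$line_ids, jitter = jitter), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d, mean diagonal %.4f, jitter %.3g\n",
              nrow(x$G), ncol(x$G), mean(diag(x$G)), x$jitter))
  invisible(x)
}

#' Triangular (Cholesky) factor of a relationship matrix
#'
#' Two orientations are supported. `"gram"` (default) returns the lower
#' triangular F with F F' = G, so the Gram matrix of the rows of F is G itself
#' and a linear model on the rows reproduces the GBLUP covariance structure.
#' `"upper_GtLL"` returns the upper triangular F with F' F = G, the literal
#' "upper triangular part of the Cholesky decomposition" phrasing used when the
#' features are written Z_L L_G.
#'
#' @param G a `grm` or a symmetric positive-definite matrix.
#' @param orientation `"gram"` or `"upper_GtLL"`.
#' @return an object of class `chol_factor`: list with `F` (J x J triangular
#'   matrix, line ids as dimnames), `orientation`, `line_ids`.
#' @export
chol_factor <- function(G, orientation = c("gram", "upper_GtLL")) {
  orientation <- match.arg(orientation)
  mat <- if (inherits(G, "grm")) G$G else as.matrix(G)
  ids <- if (inherits(G, "grm")) G$line_ids else rownames(mat)
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(mat)))
  R <- tryCatch(chol(mat), error = function(e)
    stop("Cholesky factorization failed (", conditionMessage(e),
         "); increase the diagonal jitter of G", call. = FALSE))
  Fm <- if (orientation == "gram") t(R) else R
  dimnames(Fm) <- list(ids, ids)
  structure(list(F = Fm, orientation = orientation, line_ids = ids),
            class = "chol_factor")
}

#' @export
print.chol_factor <- function(x, ...) {
  cat(sprintf("chol_factor: %d x %d, orientation '%s'\n",
              nrow(x$F), ncol(x$F), x$orientation))
  invisible(x)
}

#' Build the three modality input blocks X_E, X_L, X_EL
#'
#' For observations indexed by (environment, line) pairs this realizes the
#' network inputs: `X_E` the one-hot environment design (environments ordered
#' lexicographically), `X_L` the genomic features Z_L F (row of the triangular
#' factor for the observation's line), and `X_EL` the interaction features
#' Z_EL (I kron F), materialized row-block-wise so no (I*J) x (I*J) array is
#' ever allocated: the X_EL row of observation (i, j) is zero outside the i-th
#' J-column block and equals the X_L row of line j inside it.
#'
#' @param obs data.frame with columns `env` and `line`.
#' @param F a `chol_factor` whose line index covers every line in `obs`.
#' @param env_levels optional character vector fixing the environment order
#'   (and hence I); defaults to the sorted unique environments of `obs`. Pass
#'   the training levels when building inputs for held-out data.
#' @param unknown_env how to handle an environment absent from `env_levels`:
#'   `"error"` (default) or `"zero"` (all-zero X_E and X_EL rows, used by the
#'   leave-one-environment-out protocol where the held-out environment has no
#'   design column).
#' @return an object of class `modality_inputs`: list with matrices `X_E`
#'   (n x I), `X_L` (n x J), `X_EL` (n x I*J), the `obs` index, `env_levels`,
#'   and `line_ids`.
#' @export
build_modality_inputs <- function(obs, F, env_levels = NULL,
                                  unknown_env = c("error", "zero")) {
  unknown_env <- match.arg(unknown_env)
  stopifnot(inherits(F, "chol_factor"))
  obs <- as.data.frame(obs)
  stopifnot(all(c("env", "line") %in% names(obs)))
  env <- as.character(obs$env)
  line <- as.character(obs$line)
  if (is.null(env_levels)) env_levels <- sort(unique(env))
  env_levels <- as.character(env_levels)
  I <- length(env_levels)
  J <- length(F$line_ids)
  n <- nrow(obs)

  li <- match(line, F$line_ids)
  if (anyNA(li))
    stop("unknown line identifier(s): ",
         paste(utils::head(unique(line[is.na(li)]), 5), collapse = ", "))
  ei <- match(env, env_levels)
  if (anyNA(ei)) {
    if (unknown_env == "error")
      stop("unknown environment identifier(s): ",
           paste(utils::head(unique(env[is.na(ei)]), 5), collapse = ", "))
  }

  X_E <- matrix(0, n, I, dimnames = list(NULL, env_levels))
  known <- !is.na(ei)
  X_E[cbind(which(known), ei[known])] <- 1

  X_L <- F$F[li, , drop = FALSE]
  rownames(X_L) <- NULL

  X_EL <- matrix(0, n, I * J)
  for (i in seq_len(I)) {
    rows <- which(known & ei == i)
    if (length(rows)) {
      cols <- ((i - 1L) * J + 1L):(i * J)
      X_EL[rows, cols] <- X_L[rows, , drop = FALSE]
    }
  }
  colnames(X_EL) <- paste(rep(env_levels, each = J), rep(F$line_ids, I), sep = ":")

  structure(list(X_E = X_E, X_L = X_L, X_EL = X_EL,
                 obs = data.frame(env = env, line = line,
                                  stringsAsFactors = FALSE),
                 env_levels = env_levels, line_ids = F$line_ids,
                 orientation = F$orientation),
            class = "modality_inputs")
}

#' @export
print.modality_inputs <- function(x, ...) {
  cat(sprintf("modality_inputs: %d observations, I=%d environments, J=%d lines\n",
              nrow(x$X_E), ncol(x$X_E), ncol(x$X_L)))
  invisible(x)
}
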