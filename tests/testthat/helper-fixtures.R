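# shared in-code fixtures; everything is generated, nothing read from disk

# tiny recoded marker matrix with optional missing cells
tiny_markers <- function(values, line_ids = NULL, marker_ids = NULL) {
  v <- as.matrix(values)
  marker_matrix(v,
                line_ids = line_ids %||% paste0("L", seq_len(nrow(v))),
                marker_ids = marker_ids %||% paste0("M", seq_len(ncol(v))),
                coding = "recoded")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random recoded matrix with controlled missingness, for property tests
random_markers <- function(J, M, missing_frac = 0, seed = 1) {
  set.seed(seed)
  v <- matrix(sample(c(-1, 0, 1), J * M, replace = TRUE), J, M)
  if (missing_frac > 0)
    v[runif(J * M) < missing_frac] <- NA
  tiny_markers(v)
}

# a small positive-definite matrix with unit-scale diagonal
random_pd <- function(J, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(J * (J + 2)), J, J + 2)
  G <- tcrossprod(A) / (J + 2)
  G + diag(1e-8, J)
}

# write a hapmap-style numeric file; rows = character vectors of fields
write_hapmap_fixture <- function(rows, sep = "\t") {
  path <- tempfile(fileext = ".txt")
  writeLines(vapply(rows, paste, character(1), collapse = sep), path)
  path
}

# complete MET observation grid
grid_obs <- function(envs, lines) {
  expand.grid(line = lines, env = envs, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)[, c("env", "line")]
}
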