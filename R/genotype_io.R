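#' Marker matrix constructor
#'
#' A `marker_matrix` holds a lines x markers genotype grid together with its
#' identifiers and a coding tag. Two codings are used: `"tassel_numeric"`
#' (entries in \{1, 0.5, 0\}: homozygous major, heterozygous, homozygous minor)
#' and `"recoded"` (entries in \{-1, 0, +1\}: homozygous major, heterozygous,
#' homozygous minor). Missing genotypes are `NA`.
#'
#' @param values numeric matrix, lines in rows, markers in columns; `NA` marks
#'   missing calls.
#' @param line_ids character vector of unique line identifiers (rows).
#' @param marker_ids character vector of unique marker identifiers (columns).
#' @param coding one of `"tassel_numeric"`, `"recoded"`.
#' @return an object of class `marker_matrix`.
#' @export
marker_matrix <- function(values, line_ids = rownames(values),
                          marker_ids = colnames(values),
                          coding = c("tassel_numeric", "recoded")) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (length(line_ids) != nrow(values))
    stop("line_ids length does not match the number of rows")
  if (length(marker_ids) != ncol(values))
    stop("marker_ids length does not match the number of columns")
  if (anyDuplicated(line_ids)) stop("duplicate line_ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker_ids")
  dimnames(values) <- list(line_ids, marker_ids)
  allowed <- if (coding == "tassel_numeric") c(1, 0.5, 0) else c(-1, 0, 1)
  bad <- !is.na(values) & !(values %in% allowed)
  if (any(bad)) {
    stop(sprintf("genotype values outside {%s} for coding '%s' (first offender: %g)",
                 paste(allowed, collapse = ", "), coding,
                 values[which(bad)[1]]))
  }
  structure(list(values = values, line_ids = line_ids, marker_ids = marker_ids,
                 coding = coding),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers, coding '%s', %d missing cells\n",
              nrow(x$values), ncol(x$values), x$coding, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$values)

#' Read a HapMap-style numeric genotype table
#'
#' Reads a tab-delimited genotype table in the TASSEL numeric coding
#' (1 = homozygous major, 0.5 = heterozygous, 0 = homozygous minor). By the
#' HapMap convention markers are in rows and lines in columns; the first field
#' of each row is the marker identifier. A header row of line identifiers is
#' auto-detected (any non-numeric, non-missing token in the first row).
#'
#' @param path path to the tab-delimited text file.
#' @param orientation `"markers_in_rows"` (default, HapMap convention) or
#'   `"lines_in_rows"`.
#' @param missing_tokens character vector of tokens treated as missing.
#' @param sep field separator, default tab.
#' @return a `marker_matrix` with coding `"tassel_numeric"`.
#' @export
read_hapmap_numeric <- function(path, orientation = c("markers_in_rows", "lines_in_rows"),
                                missing_tokens = c("NA", "NaN", ""), sep = "\t") {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty genotype file: ", path)
  rows <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("parse error at line %d of %s: %d fields where %d expected",
                 bad, path, widths[bad], widths[1]))
  }
  if (widths[1] < 2L) stop("parse error: each row needs an id field and at least one genotype")

  parse_cell <- function(tok) {
    tok <- trimws(tok)
    if (tok %in% missing_tokens) return(NA_real_)
    val <- suppressWarnings(as.numeric(tok))
    if (is.na(val)) stop(sprintf("unknown genotype token '%s'", tok))
    val
  }
  first_payload <- trimws(rows[[1]][-1])
  is_header <- any(is.na(suppressWarnings(as.numeric(first_payload))) &
                     !(first_payload %in% missing_tokens))
  col_ids <- NULL
  if (is_header) {
    col_ids <- first_payload
    rows <- rows[-1]
    if (length(rows) == 0L) stop("parse error: header but no data rows in ", path)
  }
  row_ids <- vapply(rows, function(r) trimws(r[1]), character(1))
  vals <- t(vapply(rows, function(r) vapply(r[-1], parse_cell, numeric(1)),
                   numeric(widths[1] - 1L)))
  if (widths[1] == 2L) vals <- matrix(vals, ncol = 1L)  # vapply collapsed
  n_cols <- ncol(vals)
  if (is.null(col_ids)) {
    col_ids <- if (orientation == "markers_in_rows") paste0("L", seq_len(n_cols))
               else paste0("M", seq_len(n_cols))
  }
  if (orientation == "markers_in_rows") {
    marker_matrix(t(vals), line_ids = col_ids, marker_ids = row_ids,
                  coding = "tassel_numeric")
  } else {
    marker_matrix(vals, line_ids = row_ids, marker_ids = col_ids,
                  coding = "tassel_numeric")
  }
}

#' Recode TASSEL numeric genotypes to \{-1, 0, +1\}
#'
#' Entrywise map 1 -> -1 (homozygous major), 0.5 -> 0 (heterozygous),
#' 0 -> +1 (homozygous minor); missing stays missing. The map is a bijection on
#' \{1, 0.5, 0\} so the original coding can be recovered exactly.
#'
#' @param m a `marker_matrix` with coding `"tassel_numeric"`.
#' @return a `marker_matrix` with coding `"recoded"`.
#' @export
recode_tassel <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$coding != "tassel_numeric")
    stop("recode_tassel expects coding 'tassel_numeric', got '", m$coding, "'")
  v <- m$values
  out <- v
  out[!is.na(v) & v == 1]   <- -1
  out[!is.na(v) & v == 0.5] <- 0
  out[!is.na(v) & v == 0]   <- 1
  marker_matrix(out, m$line_ids, m$marker_ids, coding = "recoded")
}

#' Per-marker minor allele frequency
#'
#' Treats the \{-1, 0, +1\} coding as dosage 0/1/2 of the `+1` allele and folds
#' the frequency to be at most 0.5. Computed on non-missing calls only; markers
#' with no non-missing calls get `NA`.
#'
#' @param m a recoded `marker_matrix`.
#' @return numeric vector of folded minor allele frequencies, one per marker.
#' @export
marker_maf <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$coding != "recoded") stop("marker_maf expects coding 'recoded'")
  v <- m$values
  n_obs <- colSums(!is.na(v))
  dosage_sum <- colSums(v == 1, na.rm = TRUE) * 2 + colSums(v == 0, na.rm = TRUE)
  p <- ifelse(n_obs > 0, dosage_sum / (2 * n_obs), NA_real_)
  pmin(p, 1 - p)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Applies the standard SNP quality-control rules: first remove markers whose
#' missing-call fraction is at least `missing_threshold`, then remove markers
#' whose folded minor allele frequency (computed on non-missing calls of the
#' survivors) is below `maf_threshold`. A marker failing both rules is counted
#' once, under missingness. Markers with zero non-missing calls always fall
#' under the missingness rule, never a division by zero.
#'
#' @param m a recoded `marker_matrix`.
#' @param maf_threshold markers with MAF strictly below this are removed;
#'   default 0.05.
#' @param missing_threshold markers with missing fraction at or above this are
#'   removed; default 0.5.
#' @return list with elements `markers` (the filtered `marker_matrix`) and
#'   `report` (a `qc_report`).
#' @export
filter_markers <- function(m, maf_threshold = 0.05, missing_threshold = 0.5) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$coding != "recoded") stop("filter_markers expects coding 'recoded'")
  if (nrow(m$values) < 1L) stop("need at least one line")
  stopifnot(maf_threshold > 0, maf_threshold < 1,
            missing_threshold > 0, missing_threshold < 1)
  n_in <- ncol(m$values)
  miss_frac <- colMeans(is.na(m$values))
  drop_missing <- miss_frac >= missing_threshold
  keep1 <- m$values[, !drop_missing, drop = FALSE]
  m1 <- marker_matrix(keep1, m$line_ids, m$marker_ids[!drop_missing], "recoded")
  maf <- marker_maf(m1)
  drop_maf <- maf < maf_threshold
  out <- marker_matrix(m1$values[, !drop_maf, drop = FALSE], m$line_ids,
                       m1$marker_ids[!drop_maf], "recoded")
  report <- structure(list(
    n_markers_in = n_in,
    n_removed_missing = sum(drop_missing),
    n_removed_maf = sum(drop_maf),
    n_markers_out = ncol(out$values),
    maf_threshold = maf_threshold,
    missing_threshold = missing_threshold,
    order = "missingness filter applied before MAF filter"
  ), class = "qc_report")
  stopifnot(report$n_markers_out ==
              report$n_markers_in - report$n_removed_maf - report$n_removed_missing)
  list(markers = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("marker QC: %d in, %d removed for missingness (>= %.2f), ",
                     "%d removed for MAF (< %.2f), %d out\n"),
              x$n_markers_in, x$n_removed_missing, x$missing_threshold,
              x$n_removed_maf, x$maf_threshold, x$n_markers_out))
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing cell by the mean of the non-missing values of its
#' marker column, so per-marker means are preserved exactly.
#'
#' @param m a recoded `marker_matrix`.
#' @return a `marker_matrix` with no missing entries.
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (m$coding != "recoded") stop("impute_mean expects coding 'recoded'")
  v <- m$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop("markers with all calls missing: ",
         paste(utils::head(m$marker_ids[all_missing], 5), collapse = ", "),
         "; run filter_markers() first")
  }
  if (anyNA(v)) {
    means <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- means[idx[, 2]]
  }
  out <- structure(list(values = v, line_ids = m$line_ids,
                        marker_ids = m$marker_ids, coding = "recoded"),
                   class = "marker_matrix")
  out
}

#' Write a marker matrix as CSV
#'
#' Lines in rows (first column `line_id`), markers in columns.
#' @param m a `marker_matrix`.
#' @param path output file path.
#' @export
write_marker_csv <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- data.frame(line_id = m$line_ids, m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a marker matrix from CSV written by [write_marker_csv()]
#' @param path input file path.
#' @param coding coding tag of the stored values.
#' @return a `marker_matrix`.
#' @export
read_marker_csv <- function(path, coding = "recoded") {
  df <- utils::read.csv(path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  marker_matrix(v, line_ids = df[[1]], marker_ids = colnames(v), coding = coding)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
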