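#' Read a gene expression matrix
#'
#' Reads a tab-separated matrix of log2-scale normalised expression with
#' genes in rows and samples in columns. The first column holds gene
#' symbols, the header row holds sample identifiers. Gzip-compressed files
#' are read transparently.
#'
#' Duplicate gene rows are collapsed by keeping the row with the highest
#' mean expression; each collapse is reported as a message so the choice is
#' auditable.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @return A numeric matrix with gene symbols as row names and sample
#'   identifiers as column names.
#' @export
read_expression <- function(path) {
  mat <- read_feature_matrix(path, feature = "gene")
  mat <- collapse_duplicate_rows(mat)
  mat
}

#' Read a CpG beta-value matrix
#'
#' Reads a tab-separated matrix of methylation beta values (probes in rows,
#' samples in columns). Beta values live in \[0, 1\]; values outside
#' \[-0.01, 1.01\] abort with a scale error because they indicate M-values
#' or otherwise mis-scaled input. Values are clamped to
#' \[eps, 1 - eps\] (eps = 1e-3) because the beta likelihood used by
#' [fit_beta_mixture()] is undefined at the boundaries; clamping (rather
#' than dropping) preserves sample counts, and the number of clamped
#' entries is reported.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @param eps Boundary clamp width.
#' @return A numeric matrix of beta values in \[eps, 1 - eps\].
#' @export
read_methylation <- function(path, eps = 1e-3) {
  mat <- read_feature_matrix(path, feature = "probe")
  vals <- mat[!is.na(mat)]
  if (any(vals < -0.01 | vals > 1.01)) {
    rlang::abort(sprintf(
      "methylation values outside [-0.01, 1.01] (range %.3g..%.3g): not beta values",
      min(vals), max(vals)))
  }
  n_clamped <- sum(vals < eps | vals > 1 - eps)
  mat[] <- pmin(pmax(mat, eps), 1 - eps)
  if (n_clamped > 0) {
    md_inform(sprintf("clamped %d beta value(s) to [%g, %g]", n_clamped, eps, 1 - eps))
  }
  mat
}

# Shared TSV-matrix reader: first column feature ids, header row sample ids.
read_feature_matrix <- function(path, feature = "feature") {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) rlang::abort(
      sprintf("malformed %s matrix '%s': %s", feature, path, conditionMessage(e)))
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    rlang::abort(sprintf("%s matrix '%s' is empty or has no sample columns", feature, path))
  }
  ids <- as.character(df[[1]])
  if (anyNA(ids) || any(ids == "")) {
    rlang::abort(sprintf("missing %s identifiers in '%s'", feature, path))
  }
  body <- df[, -1, drop = FALSE]
  n_missing_in <- sum(vapply(body, function(col) sum(is.na(col) | col == "NA"), 0L))
  mat <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(body)))
  if (sum(is.na(mat)) > n_missing_in) {
    rlang::abort(sprintf("non-numeric values in %s matrix '%s'", feature, path))
  }
  if (any(is.infinite(mat))) {
    rlang::abort(sprintf("non-finite values in %s matrix '%s'", feature, path))
  }
  if (anyDuplicated(colnames(mat))) {
    rlang::abort(sprintf("duplicate sample identifiers in '%s'", path))
  }
  rownames(mat) <- ids
  mat
}

collapse_duplicate_rows <- function(mat) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) return(mat)
  if (length(unique(ids)) == 1 && nrow(mat) > 1) {
    rlang::abort("all feature identifiers are identical; refusing to collapse")
  }
  means <- rowMeans(mat, na.rm = TRUE)
  ord <- order(ids, -means)
  keep <- !duplicated(ids[ord])
  dropped <- sum(!keep)
  md_inform(sprintf(
    "collapsed %d duplicate row(s); kept the highest-mean row per id", dropped))
  out <- mat[ord, , drop = FALSE][keep, , drop = FALSE]
  out[match(unique(ids), rownames(out)), , drop = FALSE]
}

#' Read a sample sheet
#'
#' Tab-separated table with columns `sample_id` and `group`, where `group`
#' is `"tumor"` or `"normal"`.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("sample_id", "group")
  if (!all(req %in% names(df))) {
    rlang::abort(sprintf("sample sheet must have columns %s", paste(req, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[req])
  if (anyDuplicated(df$sample_id)) rlang::abort("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(df$group), c("tumor", "normal"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown group value(s): %s", paste(bad, collapse = ", ")))
  }
  df
}

#' Read a CpG probe manifest
#'
#' Maps probes to gene symbols and genomic region classes. Two layouts are
#' accepted:
#' \itemize{
#'   \item a TSV with header columns `probe_id`, `gene_symbol`, `chrom`,
#'     `start`, `end`, `region_class` (`promoter` or `other`);
#'   \item a headerless 6-column BED file (0-based half-open coordinates)
#'     whose name field packs `probe_id:gene_symbol:region_class`.
#' }
#' A probe may map to several genes; each probe-gene pair is one row.
#'
#' @param path Path to the manifest file.
#' @return A tibble with columns `probe_id`, `gene_symbol`, `chrom`,
#'   `start`, `end`, `region_class`.
#' @export
read_probe_manifest <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) == 0) rlang::abort("empty manifest file")
  if (grepl("probe_id", first, fixed = TRUE)) {
    df <- readr::read_tsv(path, col_types = readr::cols(
      probe_id = readr::col_character(), gene_symbol = readr::col_character(),
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), region_class = readr::col_character()))
  } else {
    df <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "cddccc")
    parts <- strsplit(df$name, ":", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      rlang::abort("BED manifest name field must be probe_id:gene_symbol:region_class")
    }
    df <- tibble::tibble(
      probe_id = vapply(parts, `[[`, "", 1L),
      gene_symbol = vapply(parts, `[[`, "", 2L),
      chrom = df$chrom, start = df$start, end = df$end,
      region_class = vapply(parts, `[[`, "", 3L))
  }
  req <- c("probe_id", "gene_symbol", "chrom", "start", "end", "region_class")
  if (!all(req %in% names(df))) {
    rlang::abort(sprintf("manifest must have columns %s", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(df$region_class), c("promoter", "other"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown region_class value(s): %s", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(df[req])
}

#' Read biological-process signatures
#'
#' Tab-separated table with columns `process`, `gene` and `direction`
#' (`increase` or `decrease`), listing the expected change of each
#' signature gene when the process is activated.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @return A tibble with columns `process`, `gene`, `direction`.
#' @export
read_signatures <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("process", "gene", "direction")
  if (!all(req %in% names(df))) {
    rlang::abort(sprintf("signature file must have columns %s", paste(req, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[req])
  bad <- setdiff(unique(df$direction), c("increase", "decrease"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown direction value(s): %s", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df[c("process", "gene")])) {
    rlang::abort("duplicate gene within a process signature")
  }
  df
}

#' Read a reference driver-gene census
#'
#' Plain text, one gene symbol per line (for example an export of a curated
#' cancer gene census).
#'
#' @param path Path to the file.
#' @return A character vector of unique gene symbols.
#' @export
read_census <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  unique(x[x != ""])
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param mat Numeric matrix with feature row names and sample column names.
#' @param path Output path (`.gz` suffix compresses).
#' @param feature_col Name of the first (identifier) column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature_id") {
  df <- tibble::as_tibble(mat, rownames = feature_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Align expression, methylation and sample annotations into one cohort
#'
#' Intersects the samples present in the expression matrix, the methylation
#' matrix and the sample sheet, partitions them into tumor and normal, and
#' returns a cohort object whose matrices are subset to the shared samples
#' in lexicographic order. The deterministic ordering makes every seeded
#' downstream step reproducible regardless of input file row order.
#'
#' @param expr Expression matrix from [read_expression()].
#' @param meth Methylation matrix from [read_methylation()].
#' @param samples Sample sheet tibble from [read_sample_sheet()].
#' @param min_tumor,min_normal Minimum group sizes after intersection.
#' @return An object of class `meth_cohort`: a list with elements `expr`,
#'   `meth`, `samples` (tibble), `tumor_ids`, `normal_ids`.
#' @export
align_cohort <- function(expr, meth, samples, min_tumor = 5, min_normal = 5) {
  shared <- intersect(intersect(colnames(expr), colnames(meth)), samples$sample_id)
  shared <- sort_c(shared)
  sheet <- samples[match(shared, samples$sample_id), , drop = FALSE]
  tumor <- sheet$sample_id[sheet$group == "tumor"]
  normal <- sheet$sample_id[sheet$group == "normal"]
  if (length(tumor) < min_tumor || length(normal) < min_normal) {
    rlang::abort(sprintf(
      "cohort too small after sample intersection: %d tumor (need >= %d), %d normal (need >= %d)",
      length(tumor), min_tumor, length(normal), min_normal))
  }
  structure(list(
    expr = expr[, shared, drop = FALSE],
    meth = meth[, shared, drop = FALSE],
    samples = tibble::as_tibble(sheet),
    tumor_ids = tumor,
    normal_ids = normal
  ), class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(
    "<meth_cohort> %d genes x %d samples (expression), %d probes (methylation); %d tumor / %d normal\n",
    nrow(x$expr), ncol(x$expr), nrow(x$meth),
    length(x$tumor_ids), length(x$normal_ids)))
  invisible(x)
}
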