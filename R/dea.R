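#' Differential expression between tumor and normal samples
#'
#' Per-gene Wilcoxon rank-sum test on log2 expression (tumor vs normal)
#' with Benjamini-Hochberg correction across all genes. A gene is flagged
#' as differentially expressed (DEG) when `fdr <= fdr_max` and
#' `|log2fc| >= lfc_min`. The full table is returned, flags included, so
#' downstream stages can look up fold changes of non-DEG genes too.
#'
#' The built-in test is deliberately nonparametric; results of an external
#' differential-expression analysis can be supplied instead via
#' [load_dea()].
#'
#' @param cohort A `meth_cohort` from [align_cohort()] or
#'   [simulate_cohort()].
#' @param fdr_max BH-adjusted significance cutoff for the DEG flag.
#' @param lfc_min Minimum absolute log2 fold change for the DEG flag.
#' @return A tibble with columns `gene_symbol`, `log2fc` (tumor minus
#'   normal mean, log2 scale), `p_value`, `fdr`, `direction` (`up` iff
#'   `log2fc > 0`), `is_deg`.
#' @export
run_dea <- function(cohort, fdr_max = 0.05, lfc_min = 1.0) {
  expr <- cohort$expr
  tum <- expr[, cohort$tumor_ids, drop = FALSE]
  nor <- expr[, cohort$normal_ids, drop = FALSE]
  genes <- rownames(expr)

  lfc <- rowMeans(tum, na.rm = TRUE) - rowMeans(nor, na.rm = TRUE)
  n_flat <- 0L
  p <- vapply(seq_along(genes), function(i) {
    x <- tum[i, ]; y <- nor[i, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (stats::var(c(x, y)) == 0) return(NA_real_)  # flagged below
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  flat <- is.na(p)
  if (any(flat)) {
    p[flat] <- 1
    md_inform(sprintf("%d zero-variance gene(s) assigned p = 1", sum(flat)))
  }
  fdr <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene_symbol = genes,
    log2fc = unname(lfc),
    p_value = unname(p),
    fdr = unname(fdr),
    direction = unname(ifelse(lfc > 0, "up", "down")),
    is_deg = fdr <= fdr_max & abs(lfc) >= lfc_min
  )
}

#' Load an externally computed differential-expression table
#'
#' Accepts a TSV with columns `gene_symbol` (or `gene`), `log2fc`,
#' `p_value` (or `p`) and `fdr`, e.g. exported from a count-model DEA.
#' A `direction` column is derived from the sign of `log2fc` when absent;
#' an `is_deg` column is derived from the thresholds when absent.
#'
#' @param path Path to the TSV file.
#' @param fdr_max,lfc_min Thresholds used to derive `is_deg` when the
#'   column is missing.
#' @return A tibble in the same shape as [run_dea()].
#' @export
load_dea <- function(path, fdr_max = 0.05, lfc_min = 1.0) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[names(df) == "gene"] <- "gene_symbol"
  names(df)[names(df) == "p"] <- "p_value"
  req <- c("gene_symbol", "log2fc", "p_value", "fdr")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("DEA table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE) ||
      any(df$p_value < 0 | df$p_value > 1, na.rm = TRUE)) {
    rlang::abort("p_value and fdr must lie in [0, 1]")
  }
  if (anyDuplicated(df$gene_symbol)) rlang::abort("duplicate gene_symbol in DEA table")
  if (!"direction" %in% names(df)) df$direction <- ifelse(df$log2fc > 0, "up", "down")
  if (!"is_deg" %in% names(df)) {
    df$is_deg <- df$fdr <= fdr_max & abs(df$log2fc) >= lfc_min
  }
  tibble::as_tibble(df[c("gene_symbol", "log2fc", "p_value", "fdr", "direction", "is_deg")])
}
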