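#' Test association between CpG methylation state and gene expression
#'
#' For every probe whose mixture fit contains at least one abnormal
#' (hypo- or hypermethylated) component, and every gene the manifest maps
#' it to (promoter rows only by default), the gene's tumor expression is
#' compared by Wilcoxon rank-sum test between samples assigned to the
#' abnormal component(s) and samples assigned to the normal-like
#' component(s). When the fit has no normal-like component the abnormal
#' group is compared against the expression of the normal-tissue samples
#' instead. P-values are Benjamini-Hochberg corrected across all tested
#' probe-gene pairs; pairs with `assoc_fdr <= assoc_fdr_max` are flagged
#' functional. Comparisons with fewer than `min_group` samples on either
#' side are skipped (counted in a message).
#'
#' @param fits Named list of state-called `beta_mixture_fit` objects, e.g.
#'   from [fit_cohort_mixtures()].
#' @param manifest Probe manifest tibble.
#' @param cohort A `meth_cohort` providing expression and the
#'   tumor/normal partition.
#' @param assoc_fdr_max FDR cutoff for the `functional` flag.
#' @param promoter_only Restrict to manifest rows with
#'   `region_class == "promoter"`.
#' @param min_group Minimum samples per comparison group.
#' @return A tibble of all tested pairs with columns `probe_id`,
#'   `gene_symbol`, `cpg_state` (`Hypo`/`Hyper`/`Dual`), `dm` (list column
#'   of abnormal-component differential-methylation values), `n_abnormal`,
#'   `n_reference`, `assoc_p`, `assoc_fdr`, `functional`. Functional pairs
#'   are the rows with `functional == TRUE`.
#' @export
pair_with_expression <- function(fits, manifest, cohort, assoc_fdr_max = 0.05,
                                 promoter_only = TRUE, min_group = 3) {
  man <- manifest
  if (promoter_only) man <- man[man$region_class == "promoter", , drop = FALSE]
  expr <- cohort$expr
  n_skipped <- 0L
  rows <- list()
  for (p in sort_c(names(fits))) {
    fit <- fits[[p]]
    if (is.null(fit$probe_state) || fit$probe_state == "None") next
    abn_comp <- which(fit$component_state != "normal-like")
    nl_comp <- which(fit$component_state == "normal-like")
    abn_samples <- names(fit$assignment)[fit$assignment %in% abn_comp]
    ref_samples <- names(fit$assignment)[fit$assignment %in% nl_comp]
    use_normals <- length(nl_comp) == 0
    genes <- sort_c(unique(man$gene_symbol[man$probe_id == p]))
    genes <- genes[genes %in% rownames(expr)]
    for (g in genes) {
      x <- expr[g, abn_samples]
      y <- if (use_normals) expr[g, cohort$normal_ids] else expr[g, ref_samples]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_group || length(y) < min_group) {
        n_skipped <- n_skipped + 1L
        next
      }
      pv <- if (stats::var(c(x, y)) == 0) 1
        else suppressWarnings(stats::wilcox.test(x, y)$p.value)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        probe_id = p, gene_symbol = g, cpg_state = fit$probe_state,
        dm = list(fit$dm[abn_comp]),
        n_abnormal = length(x), n_reference = length(y),
        assoc_p = pv)
    }
  }
  if (n_skipped > 0) {
    md_inform(sprintf("%d probe-gene comparison(s) skipped: fewer than %d samples in a group",
                      n_skipped, min_group))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      probe_id = character(), gene_symbol = character(), cpg_state = character(),
      dm = list(), n_abnormal = integer(), n_reference = integer(),
      assoc_p = numeric(), assoc_fdr = numeric(), functional = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out$assoc_fdr <- stats::p.adjust(out$assoc_p, method = "BH")
  out$functional <- out$assoc_fdr <= assoc_fdr_max
  out
}
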