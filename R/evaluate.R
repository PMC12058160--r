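#' Confusion counts of a predicted gene set against a reference census
#'
#' True positives are predicted genes found in the census, false positives
#' predicted genes absent from it, and false negatives census genes that
#' were not predicted. Precision is `100 * tp / (tp + fp)` and sensitivity
#' `100 * tp / (tp + fn)`, both reported as percentages (NA when the
#' denominator is zero). The census is restricted to the gene universe
#' before counting; the universe should be the set of genes the pipeline
#' could have predicted from (for example all genes entering the
#' differential-expression step).
#'
#' @param genes Character vector of predicted genes; must be a subset of
#'   `universe`.
#' @param census Character vector of reference driver genes.
#' @param universe Character vector of all candidate genes.
#' @param name Label stored in `gene_set_name`.
#' @return A one-row tibble with columns `gene_set_name`, `tp`, `fp`,
#'   `fn`, `precision`, `sensitivity`, `universe_size`.
#' @export
confusion_vs_census <- function(genes, census, universe, name = "gene_set") {
  genes <- unique(genes); census <- unique(census); universe <- unique(universe)
  if (length(universe) == 0) rlang::abort("empty gene universe")
  if (!all(genes %in% universe)) {
    rlang::abort("predicted genes must be a subset of the universe")
  }
  census <- intersect(census, universe)
  tp <- length(intersect(genes, census))
  fp <- length(setdiff(genes, census))
  fn <- length(setdiff(census, genes))
  tibble::tibble(
    gene_set_name = name,
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    universe_size = length(universe))
}

#' Fisher's exact test of association with the census
#'
#' Builds the 2x2 table (predicted / not predicted) x (in census / not in
#' census) over the gene universe and adds the two-sided Fisher exact
#' p-value and the sample odds ratio `(a d) / (b c)`; when any cell is
#' zero the Haldane-Anscombe correction (+0.5 on every cell) is applied to
#' the odds ratio. The p-value sums all hypergeometric tables whose
#' probability does not exceed that of the observed table, the standard
#' two-sided convention.
#'
#' @param report A one-row tibble from [confusion_vs_census()].
#' @return The report with `fisher_p` and `odds_ratio` columns appended.
#' @export
fisher_association <- function(report) {
  a <- report$tp
  b <- report$fp
  c_ <- report$fn
  d <- report$universe_size - a - b - c_
  if (min(a, b, c_, d) < 0) rlang::abort("negative contingency cell")
  report$fisher_p <- fisher_exact_p(a, b, c_, d)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  report$odds_ratio <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  report
}

# Two-sided Fisher exact p for table [[a, b], [c, d]] by hypergeometric
# enumeration over the table support at fixed margins. Tables are counted
# as at-least-as-extreme when their probability is <= that of the observed
# table, with a small relative tolerance guarding against floating-point
# ties.
fisher_exact_p <- function(a, b, c_, d) {
  m <- a + b          # predicted genes
  n2 <- c_ + d        # not predicted
  k <- a + c_         # census genes
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n2, k)
  d_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Three-way overlap counts of two gene sets
#'
#' @param a,b Character vectors.
#' @return A one-row tibble with `only_a`, `shared`, `only_b` — the counts
#'   behind a two-set Venn diagram.
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  tibble::tibble(
    only_a = length(setdiff(a, b)),
    shared = length(intersect(a, b)),
    only_b = length(setdiff(b, a)))
}

#' Evaluate drivers and mediators against a census in one call
#'
#' @param prediction A `driver_prediction`.
#' @param census Character vector of reference driver genes.
#' @param universe Character vector of candidate genes (defaults to all
#'   genes in the prediction's DEG annotation).
#' @return A two-row tibble (driver genes, mediators) with confusion
#'   counts, precision, sensitivity, Fisher p and odds ratio.
#' @export
evaluate_prediction <- function(prediction, census,
                                universe = prediction$deg_annotation$gene_symbol) {
  dplyr::bind_rows(
    fisher_association(confusion_vs_census(
      prediction$drivers$gene_symbol, census, universe, name = "drivers")),
    fisher_association(confusion_vs_census(
      prediction$mediator_summary$gene_symbol, census, universe, name = "mediators")))
}
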