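#' Summarize functional CpG states per oncogenic mediator
#'
#' Counts, for each mediator, its functional CpG-gene pairs by methylation
#' state and derives the gene-level state: `Hypo` when only hypomethylated
#' CpGs are present, `Hyper` when only hypermethylated, `Mixed` when both,
#' `Dual-only` when only dual-state CpGs, `None` when the gene has no
#' functional pairs. Dual CpGs are counted but never decide between
#' `Hypo` and `Hyper`.
#'
#' @param mediators Mediator tibble from [run_pra()] / [load_pra()].
#' @param pairs Pair tibble from [pair_with_expression()]; when it carries
#'   a `functional` column only functional rows are counted.
#' @return A tibble with columns `gene_symbol`, `putative_role`, `n_hypo`,
#'   `n_hyper`, `n_dual`, `gene_state`.
#' @export
summarize_cpgs <- function(mediators, pairs) {
  if ("functional" %in% names(pairs)) pairs <- pairs[pairs$functional, , drop = FALSE]
  counts <- pairs |>
    dplyr::count(.data$gene_symbol, .data$cpg_state) |>
    tidyr::pivot_wider(names_from = "cpg_state", values_from = "n", values_fill = 0L)
  for (col in c("Hypo", "Hyper", "Dual")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- tibble::tibble(
    gene_symbol = mediators$gene_symbol,
    putative_role = mediators$putative_role)
  idx <- match(out$gene_symbol, counts$gene_symbol)
  out$n_hypo <- ifelse(is.na(idx), 0L, counts$Hypo[idx])
  out$n_hyper <- ifelse(is.na(idx), 0L, counts$Hyper[idx])
  out$n_dual <- ifelse(is.na(idx), 0L, counts$Dual[idx])
  out$gene_state <- dplyr::case_when(
    out$n_hypo > 0 & out$n_hyper == 0 ~ "Hypo",
    out$n_hyper > 0 & out$n_hypo == 0 ~ "Hyper",
    out$n_hypo > 0 & out$n_hyper > 0 ~ "Mixed",
    out$n_dual > 0 ~ "Dual-only",
    TRUE ~ "None")
  out
}

#' Assign evidence categories from methylation state and putative role
#'
#' Implements the agreement/conflict rule table reconciling the
#' methylation layer with the expression layer. Promoter hypomethylation
#' activates genes and promoter hypermethylation silences them, so:
#' \itemize{
#'   \item `Hypo` + `putative_OCG` -> `Agreement_OCG`
#'   \item `Hyper` + `putative_TSG` -> `Agreement_TSG`
#'   \item `Hypo` + `putative_TSG` -> `Conflicting`
#'   \item `Hyper` + `putative_OCG` -> `Conflicting`
#'   \item `Mixed` -> `Mixed`; `Dual-only` or `None` -> `NoEvidence`
#' }
#' Only `Agreement_*` genes become driver genes.
#'
#' @param records Tibble from [summarize_cpgs()] (columns `putative_role`,
#'   `gene_state` required).
#' @return The input tibble with an `evidence` column appended.
#' @export
classify_evidence <- function(records) {
  bad <- setdiff(unique(records$putative_role), c("putative_OCG", "putative_TSG"))
  if (length(bad)) {
    rlang::abort(sprintf("unknown putative_role value(s): %s", paste(bad, collapse = ", ")))
  }
  records$evidence <- dplyr::case_when(
    records$gene_state == "Hypo" & records$putative_role == "putative_OCG" ~ "Agreement_OCG",
    records$gene_state == "Hyper" & records$putative_role == "putative_TSG" ~ "Agreement_TSG",
    records$gene_state == "Hypo" & records$putative_role == "putative_TSG" ~ "Conflicting",
    records$gene_state == "Hyper" & records$putative_role == "putative_OCG" ~ "Conflicting",
    records$gene_state == "Mixed" ~ "Mixed",
    records$gene_state %in% c("Dual-only", "None") ~ "NoEvidence",
    TRUE ~ NA_character_)
  if (anyNA(records$evidence)) {
    rlang::abort("unknown gene_state value(s) in evidence records")
  }
  records
}

#' Predict driver genes by integrating methylation and expression evidence
#'
#' Runs the full methylation layer on a cohort — beta-mixture fits per
#' CpG, hypo/hyper/dual state calls against normal tissue, and
#' methylation-expression association — then joins the resulting
#' functional CpG-gene pairs with the oncogenic mediators from the
#' expression layer and applies the evidence rule table
#' ([classify_evidence()]). Mediators with agreement evidence are the
#' predicted driver genes.
#'
#' @param cohort A `meth_cohort`.
#' @param mediators Mediator tibble from [run_pra()] or [load_pra()].
#' @param degs Full DEG table from [run_dea()] or [load_dea()].
#' @param manifest Probe manifest tibble.
#' @param dm_min Differential-methylation threshold (beta difference).
#' @param assoc_fdr_max FDR cutoff for functional pairs.
#' @param promoter_only Restrict pairing to promoter manifest rows.
#' @param k_max Maximum number of mixture components per probe.
#' @param out_dir Optional directory; when given, all outputs are written
#'   as TSV plus a `run_manifest.json` echoing the effective parameters.
#'   Files are only written after the whole computation succeeds.
#' @param seed Optional seed recorded in the run manifest (the methylation
#'   layer itself is deterministic).
#' @return An object of class `driver_prediction`: a list with
#'   \describe{
#'     \item{drivers}{tibble `gene_symbol`, `role` (`TSG`/`OCG`) — the
#'       predicted driver genes}
#'     \item{mediator_summary}{per-mediator CpG counts, gene state and
#'       evidence category}
#'     \item{deg_annotation}{per-DEG annotation: mediator status, role,
#'       CpG counts, evidence}
#'     \item{pairs}{all tested probe-gene pairs (raw methylation-layer
#'       output)}
#'     \item{fits_summary}{one-row-per-probe mixture summaries}
#'     \item{fits}{named list of `beta_mixture_fit` objects}
#'     \item{params}{effective parameters}
#'   }
#' @export
predict_driver_genes <- function(cohort, mediators, degs, manifest,
                                 dm_min = 0.10, assoc_fdr_max = 0.05,
                                 promoter_only = TRUE, k_max = 3,
                                 out_dir = NULL, seed = NULL) {
  man <- manifest
  if (promoter_only) man <- man[man$region_class == "promoter", , drop = FALSE]
  fits <- fit_cohort_mixtures(cohort, man, dm_min = dm_min, k_max = k_max)
  pairs <- pair_with_expression(fits, man, cohort,
                                assoc_fdr_max = assoc_fdr_max,
                                promoter_only = promoter_only)
  summary <- classify_evidence(summarize_cpgs(mediators, pairs))

  drivers <- summary[summary$evidence %in% c("Agreement_OCG", "Agreement_TSG"), , drop = FALSE]
  drivers <- tibble::tibble(
    gene_symbol = drivers$gene_symbol,
    role = ifelse(drivers$evidence == "Agreement_TSG", "TSG", "OCG"))

  # evidence categories partition the mediators
  stopifnot(nrow(summary) == nrow(mediators),
            all(drivers$gene_symbol %in% mediators$gene_symbol))

  deg_annotation <- tibble::tibble(
    gene_symbol = degs$gene_symbol,
    log2fc = degs$log2fc,
    fdr = degs$fdr,
    is_deg = degs$is_deg)
  idx <- match(deg_annotation$gene_symbol, summary$gene_symbol)
  deg_annotation$is_mediator <- !is.na(idx)
  deg_annotation$putative_role <- ifelse(is.na(idx), NA_character_, summary$putative_role[idx])
  deg_annotation$n_hypo <- ifelse(is.na(idx), 0L, summary$n_hypo[idx])
  deg_annotation$n_hyper <- ifelse(is.na(idx), 0L, summary$n_hyper[idx])
  deg_annotation$n_dual <- ifelse(is.na(idx), 0L, summary$n_dual[idx])
  deg_annotation$evidence <- ifelse(is.na(idx), NA_character_, summary$evidence[idx])
  deg_annotation$is_driver <- deg_annotation$gene_symbol %in% drivers$gene_symbol

  fits_summary <- dplyr::bind_rows(lapply(fits, glance))

  params <- list(dm_min = dm_min, assoc_fdr_max = assoc_fdr_max,
                 promoter_only = promoter_only, k_max = k_max, seed = seed)
  res <- structure(list(
    drivers = drivers,
    mediator_summary = summary,
    deg_annotation = deg_annotation,
    pairs = pairs,
    fits_summary = fits_summary,
    fits = fits,
    params = params
  ), class = "driver_prediction")

  if (!is.null(out_dir)) write_prediction(res, out_dir)
  res
}

# Write the four standard outputs plus a run manifest.
write_prediction <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$drivers, file.path(out_dir, "drivers.tsv"))
  readr::write_tsv(res$mediator_summary, file.path(out_dir, "mediator_summary.tsv"))
  readr::write_tsv(res$deg_annotation, file.path(out_dir, "deg_annotation.tsv"))
  pairs_flat <- res$pairs
  if (nrow(pairs_flat) > 0) {
    pairs_flat$dm <- vapply(pairs_flat$dm, function(d) paste(signif(d, 6), collapse = ","), "")
  } else {
    pairs_flat$dm <- character(0)
  }
  readr::write_tsv(pairs_flat, file.path(out_dir, "raw_pairs.tsv"))
  readr::write_tsv(res$fits_summary, file.path(out_dir, "raw_fits.tsv"))
  jsonlite::write_json(
    list(package = "methdriver",
         version = as.character(utils::packageVersion("methdriver")),
         params = res$params),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.driver_prediction <- function(x, ...) {
  tab <- table(factor(x$mediator_summary$evidence,
                      levels = c("Agreement_OCG", "Agreement_TSG", "Conflicting",
                                 "Mixed", "NoEvidence")))
  cat(sprintf("<driver_prediction> %d mediator(s) -> %d driver gene(s) (%d TSG, %d OCG)\n",
              nrow(x$mediator_summary), nrow(x$drivers),
              sum(x$drivers$role == "TSG"), sum(x$drivers$role == "OCG")))
  cat("  evidence:", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

#' One-row summary of a driver prediction
#'
#' @param x A `driver_prediction`.
#' @param ... Unused.
#' @return A one-row tibble with mediator/driver counts and evidence
#'   category totals.
#' @export
glance.driver_prediction <- function(x, ...) {
  ev <- x$mediator_summary$evidence
  tibble::tibble(
    n_mediators = nrow(x$mediator_summary),
    n_drivers = nrow(x$drivers),
    n_tsg = sum(x$drivers$role == "TSG"),
    n_ocg = sum(x$drivers$role == "OCG"),
    n_conflicting = sum(ev == "Conflicting"),
    n_mixed = sum(ev == "Mixed"),
    n_no_evidence = sum(ev == "NoEvidence"),
    n_functional_pairs = sum(x$pairs$functional))
}

#' Tidy a driver prediction into the per-mediator evidence table
#'
#' @param x A `driver_prediction`.
#' @param ... Unused.
#' @return The mediator summary tibble.
#' @export
tidy.driver_prediction <- function(x, ...) x$mediator_summary
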