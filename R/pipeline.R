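#' Run the whole driver-prediction pipeline on a cohort
#'
#' Chains the expression layer (differential expression, mutual-information
#' network, process effect scores, mediator calls) and the methylation
#' layer ([predict_driver_genes()]) with default parameters. For simulated
#' cohorts the bundled manifest and signatures are used automatically.
#'
#' @param cohort A `meth_cohort` (or `sim_cohort`).
#' @param manifest Probe manifest tibble; defaults to the cohort's own for
#'   simulated cohorts.
#' @param signatures Signature tibble; defaults to the cohort's own for
#'   simulated cohorts.
#' @param seed Seed driving the network permutation threshold.
#' @param fdr_max,lfc_min DEG thresholds.
#' @param n_perm,alpha Network permutation settings.
#' @param growing,blocking Process names for the mediator call.
#' @param t Effect-score threshold for mediators.
#' @param dm_min,assoc_fdr_max,k_max Methylation-layer settings.
#' @param out_dir Optional output directory, see [predict_driver_genes()].
#' @return A list with elements `degs`, `grn`, `ura`, `mediators` and
#'   `prediction` (a `driver_prediction`).
#' @export
run_pipeline <- function(cohort,
                         manifest = cohort$manifest,
                         signatures = cohort$signatures,
                         seed,
                         fdr_max = 0.05, lfc_min = 1.0,
                         n_perm = 100, alpha = 0.05,
                         growing = "proliferation", blocking = "apoptosis",
                         t = 1.0,
                         dm_min = 0.10, assoc_fdr_max = 0.05, k_max = 3,
                         out_dir = NULL) {
  if (missing(seed)) rlang::abort("run_pipeline() requires a seed")
  if (is.null(manifest)) rlang::abort("run_pipeline() needs a probe manifest")
  if (is.null(signatures)) rlang::abort("run_pipeline() needs process signatures")
  degs <- run_dea(cohort, fdr_max = fdr_max, lfc_min = lfc_min)
  grn <- build_grn(cohort, degs, n_perm = n_perm, alpha = alpha, seed = seed)
  ura <- run_ura(grn, degs, signatures)
  mediators <- run_pra(ura, growing = growing, blocking = blocking, t = t)
  prediction <- predict_driver_genes(cohort, mediators, degs, manifest,
                                     dm_min = dm_min,
                                     assoc_fdr_max = assoc_fdr_max,
                                     k_max = k_max, out_dir = out_dir,
                                     seed = seed)
  list(degs = degs, grn = grn, ura = ura, mediators = mediators,
       prediction = prediction)
}
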