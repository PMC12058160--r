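#' Configuration for a synthetic tumor/normal cohort
#'
#' Defines a paired tumor/normal cohort with planted methylation-driven
#' driver genes. Each planted oncogene (OCG) carries promoter CpGs that
#' are hypomethylated in a fraction of tumors, with expression raised by
#' `delta_expr` in exactly those samples; each planted tumor suppressor
#' (TSG) mirrors this with hypermethylated CpGs and lowered expression.
#' Every driver regulates dedicated signature genes
#' (`targets_per_process` per process) whose expression shifts
#' concordantly in the same samples, so the expression layer can recover
#' the planted roles through the network and process scores. Null genes
#' and all signature targets carry CpGs with no differential methylation.
#'
#' @param n_tumor,n_normal Cohort sizes.
#' @param n_hypo_ocg,n_hyper_tsg Numbers of planted drivers.
#' @param n_null_genes Unperturbed background genes.
#' @param n_probes_per_gene Promoter CpGs per gene.
#' @param targets_per_process Signature targets per driver per process.
#' @param abnormal_fraction Fraction of tumors carrying the abnormal
#'   methylation component (per driver, at least 3 samples).
#' @param delta_meth Beta-value shift of the abnormal component.
#' @param delta_expr Expression shift (log2) in abnormal samples.
#' @param noise_sd Expression noise standard deviation (log2).
#' @param base_expr Baseline log2 expression.
#' @param beta_precision Precision of the generating beta distributions.
#' @param mu_hypo Normal-tissue beta mean at OCG probes (hypomethylation
#'   lowers it by `delta_meth` in affected tumors).
#' @param mu_hyper Normal-tissue beta mean at TSG probes.
#' @param mu_null Beta mean at undisturbed probes.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tumor = 30, n_normal = 20,
                       n_hypo_ocg = 10, n_hyper_tsg = 10, n_null_genes = 200,
                       n_probes_per_gene = 1, targets_per_process = 4,
                       abnormal_fraction = 0.7,
                       delta_meth = 0.4, delta_expr = 2,
                       noise_sd = 0.5, base_expr = 8, beta_precision = 20,
                       mu_hypo = 0.6, mu_hyper = 0.3, mu_null = 0.5,
                       seed) {
  if (missing(seed)) rlang::abort("sim_config() requires a seed")
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal,
              n_hypo_ocg = n_hypo_ocg, n_hyper_tsg = n_hyper_tsg,
              n_null_genes = n_null_genes,
              n_probes_per_gene = n_probes_per_gene,
              targets_per_process = targets_per_process,
              abnormal_fraction = abnormal_fraction,
              delta_meth = delta_meth, delta_expr = delta_expr,
              noise_sd = noise_sd, base_expr = base_expr,
              beta_precision = beta_precision,
              mu_hypo = mu_hypo, mu_hyper = mu_hyper, mu_null = mu_null,
              seed = as.integer(seed))
  fracs <- c(abnormal_fraction, mu_hypo, mu_hyper, mu_null)
  if (any(fracs < 0 | fracs > 1)) rlang::abort("fractions and beta means must lie in [0, 1]")
  n_abn <- round(abnormal_fraction * n_tumor)
  if ((n_hypo_ocg + n_hyper_tsg) > 0 && n_abn < 3) {
    rlang::abort(sprintf(
      "infeasible config: abnormal_fraction x n_tumor = %d (< 3)", n_abn))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a tumor/normal cohort with planted methylation-driven drivers
#'
#' Generates all standard pipeline inputs — expression and methylation
#' matrices, sample sheet, probe manifest, process signatures — plus a
#' truth table recording every planted state. Output is fully determined
#' by the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return An object of classes `sim_cohort` and `meth_cohort`: the usual
#'   cohort fields (`expr`, `meth`, `samples`, `tumor_ids`, `normal_ids`)
#'   plus `manifest`, `signatures`, `truth` and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normal))
  samples <- c(tumor_ids, normal_ids)
  n_abn <- round(cfg$abnormal_fraction * cfg$n_tumor)

  ocgs <- if (cfg$n_hypo_ocg > 0) sprintf("OCG%02d", seq_len(cfg$n_hypo_ocg)) else character()
  tsgs <- if (cfg$n_hyper_tsg > 0) sprintf("TSG%02d", seq_len(cfg$n_hyper_tsg)) else character()
  nulls <- if (cfg$n_null_genes > 0) sprintf("NULL%03d", seq_len(cfg$n_null_genes)) else character()
  drivers <- c(ocgs, tsgs)

  tp <- cfg$targets_per_process
  target_rows <- list()
  for (d in drivers) {
    is_ocg <- d %in% ocgs
    if (tp > 0) {
      target_rows[[length(target_rows) + 1L]] <- tibble::tibble(
        gene = c(sprintf("%s_PRO%d", d, seq_len(tp)), sprintf("%s_APO%d", d, seq_len(tp))),
        driver = d,
        process = rep(c("proliferation", "apoptosis"), each = tp),
        # hypomethylated OCGs rise in affected tumors and push proliferation
        # up / apoptosis down; hypermethylated TSGs mirror this
        expr_sign = rep(if (is_ocg) c(1, -1) else c(-1, 1), each = tp))
    }
  }
  targets <- dplyr::bind_rows(target_rows)
  genes <- c(drivers, if (nrow(targets) > 0) targets$gene else character(), nulls)

  # expression: baseline noise everywhere, shifts added below
  expr <- matrix(stats::rnorm(length(genes) * length(samples),
                              cfg$base_expr, cfg$noise_sd),
                 nrow = length(genes), dimnames = list(genes, samples))

  # Methylation-driven (in)activation is modelled as two coherent epigenetic
  # tumor subtypes: all hypomethylated oncogenes share one affected patient
  # subgroup, all hypermethylated suppressors another. The two subgroups
  # overlap at the product expectation, so the two driver classes are
  # uncorrelated across tumors and the network cannot link them spuriously.
  set_ocg <- sort(sample(tumor_ids, n_abn))
  n_shared <- min(round(cfg$abnormal_fraction^2 * cfg$n_tumor), n_abn)
  n_outside <- min(n_abn - n_shared, cfg$n_tumor - n_abn)
  set_tsg <- sort(c(sample(set_ocg, n_abn - n_outside),
                    sample(setdiff(tumor_ids, set_ocg), n_outside)))
  abnormal_sets <- stats::setNames(
    lapply(drivers, function(d) if (d %in% ocgs) set_ocg else set_tsg), drivers)
  for (d in drivers) {
    abn <- abnormal_sets[[d]]
    sgn <- if (d %in% ocgs) 1 else -1
    expr[d, abn] <- expr[d, abn] + sgn * cfg$delta_expr
    if (nrow(targets) > 0) {
      tg <- targets[targets$driver == d, , drop = FALSE]
      for (i in seq_len(nrow(tg))) {
        expr[tg$gene[i], abn] <- expr[tg$gene[i], abn] + tg$expr_sign[i] * cfg$delta_expr
      }
    }
  }

  # methylation: one block of probes per gene
  probe_ids <- character()
  probe_gene <- character()
  for (g in genes) {
    ids <- sprintf("cg_%s_%02d", g, seq_len(cfg$n_probes_per_gene))
    probe_ids <- c(probe_ids, ids)
    probe_gene <- c(probe_gene, rep(g, length(ids)))
  }
  phi <- cfg$beta_precision
  rbeta_mu <- function(n, mu) stats::rbeta(n, mu * phi, (1 - mu) * phi)
  meth <- matrix(NA_real_, length(probe_ids), length(samples),
                 dimnames = list(probe_ids, samples))
  for (i in seq_along(probe_ids)) {
    g <- probe_gene[i]
    if (g %in% ocgs) {
      mu_n <- cfg$mu_hypo; mu_ab <- cfg$mu_hypo - cfg$delta_meth
    } else if (g %in% tsgs) {
      mu_n <- cfg$mu_hyper; mu_ab <- cfg$mu_hyper + cfg$delta_meth
    } else {
      mu_n <- cfg$mu_null; mu_ab <- cfg$mu_null
    }
    meth[i, normal_ids] <- rbeta_mu(length(normal_ids), mu_n)
    if (g %in% drivers) {
      abn <- abnormal_sets[[g]]
      rest <- setdiff(tumor_ids, abn)
      meth[i, abn] <- rbeta_mu(length(abn), mu_ab)
      meth[i, rest] <- rbeta_mu(length(rest), mu_n)
    } else {
      meth[i, tumor_ids] <- rbeta_mu(length(tumor_ids), mu_n)
    }
  }
  eps <- 1e-3
  meth[] <- pmin(pmax(meth, eps), 1 - eps)

  manifest <- tibble::tibble(
    probe_id = probe_ids,
    gene_symbol = probe_gene,
    chrom = "chr1",
    start = seq_along(probe_ids) * 1000,
    end = seq_along(probe_ids) * 1000 + 2,
    region_class = "promoter")

  # signatures: all planted targets plus a static reference block so the
  # signature set is well-formed even in null-only cohorts
  sig_static <- tibble::tibble(
    process = rep(c("proliferation", "apoptosis"), each = 5),
    gene = c(sprintf("PRO_REF%d", 1:5), sprintf("APO_REF%d", 1:5)),
    direction = "increase")
  sig_planted <- if (nrow(targets) > 0) {
    tibble::tibble(process = targets$process, gene = targets$gene,
                   direction = "increase")
  } else NULL
  signatures <- dplyr::bind_rows(sig_planted, sig_static) |>
    dplyr::distinct(.data$process, .data$gene, .keep_all = TRUE)

  truth <- tibble::tibble(
    gene = genes,
    kind = dplyr::case_when(
      genes %in% ocgs ~ "driver",
      genes %in% tsgs ~ "driver",
      genes %in% nulls ~ "null",
      TRUE ~ "target"),
    role = dplyr::case_when(
      genes %in% ocgs ~ "OCG",
      genes %in% tsgs ~ "TSG",
      TRUE ~ NA_character_),
    meth_state = dplyr::case_when(
      genes %in% ocgs ~ "Hypo",
      genes %in% tsgs ~ "Hyper",
      TRUE ~ "None"),
    abnormal_fraction = ifelse(genes %in% drivers, cfg$abnormal_fraction, 0))

  sheet <- tibble::tibble(
    sample_id = samples,
    group = rep(c("tumor", "normal"), c(length(tumor_ids), length(normal_ids))))

  cohort <- align_cohort(expr, meth, sheet,
                         min_tumor = min(5, cfg$n_tumor),
                         min_normal = min(5, cfg$n_normal))
  cohort$manifest <- manifest
  cohort$signatures <- signatures
  cohort$truth <- truth
  cohort$config <- cfg
  class(cohort) <- c("sim_cohort", class(cohort))
  cohort
}

#' Write all standard input files of a simulated cohort
#'
#' Writes `expression.tsv`, `methylation.tsv`, `samples.tsv`,
#' `manifest.tsv`, `signatures.tsv` and `truth.tsv` to a directory, in the
#' formats the readers in this package expect.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$expr, file.path(dir, "expression.tsv"), feature_col = "gene_symbol")
  write_matrix_tsv(sim$meth, file.path(dir, "methylation.tsv"), feature_col = "probe_id")
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$signatures, file.path(dir, "signatures.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
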