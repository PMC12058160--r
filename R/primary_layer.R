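#' Upstream regulator analysis: signed process effect scores
#'
#' Scores the effect of each network regulator on each biological process.
#' For regulator g and process P, every target gene of g that belongs to
#' the signature of P contributes +1 when the observed direction of its
#' differential expression matches the direction expected under process
#' activation (`up` with `increase`, `down` with `decrease`) and -1
#' otherwise. The effect score is
#' \deqn{z(g, P) = \sum_i s_i / \sqrt{m}}
#' where m is the number of scored targets; z = 0 when the regulon does not
#' intersect the signature. Targets absent from the DEG table cannot be
#' scored and are skipped (counted in a message).
#'
#' @param regulons Edge tibble from [build_grn()]; only `kept` edges are
#'   used.
#' @param degs Full DEG table ([run_dea()] output) providing fold-change
#'   signs.
#' @param signatures Signature tibble from [read_signatures()].
#' @return A tibble with columns `gene_symbol`, `process`, `n_scored`, `z`,
#'   one row per regulator-process combination.
#' @export
run_ura <- function(regulons, degs, signatures) {
  edges <- regulons[regulons$kept, , drop = FALSE]
  regulators <- sort_c(unique(regulons$regulator))
  processes <- sort_c(unique(signatures$process))
  lfc <- stats::setNames(degs$log2fc, degs$gene_symbol)
  dir_obs <- ifelse(lfc > 0, "increase", "decrease")

  n_skipped <- 0L
  rows <- list()
  for (g in regulators) {
    tg <- edges$target[edges$regulator == g]
    for (p in processes) {
      sig <- signatures[signatures$process == p, , drop = FALSE]
      inter <- intersect(tg, sig$gene)
      scored <- inter[inter %in% names(lfc)]
      n_skipped <- n_skipped + (length(inter) - length(scored))
      if (length(scored) == 0) {
        z <- 0
      } else {
        expected <- sig$direction[match(scored, sig$gene)]
        s <- ifelse(dir_obs[scored] == expected, 1, -1)
        z <- sum(s) / sqrt(length(scored))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_symbol = g, process = p, n_scored = length(scored), z = z)
    }
  }
  if (n_skipped > 0) {
    md_inform(sprintf("%d signature target(s) absent from the DEG table were skipped",
                      n_skipped))
  }
  dplyr::bind_rows(rows)
}

#' Pattern recognition analysis: call putative oncogenes and suppressors
#'
#' Classifies regulators into oncogenic mediators from their effect on a
#' cancer-growing and a cancer-blocking process: a gene promoting growth
#' (`z_growing >= t`) while suppressing the blocking process
#' (`z_blocking <= -t`) is a putative oncogene (OCG); the mirrored pattern
#' yields a putative tumor suppressor (TSG). Genes matching neither
#' pattern are not mediators and are dropped.
#'
#' @param ura Long score tibble from [run_ura()].
#' @param growing,blocking Process names playing the growing (e.g.
#'   proliferation) and blocking (e.g. apoptosis) roles.
#' @param t Symmetric effect-score threshold.
#' @return A tibble with columns `gene_symbol`, `putative_role`
#'   (`putative_OCG` / `putative_TSG`), `z_growing`, `z_blocking`.
#' @export
run_pra <- function(ura, growing = "proliferation", blocking = "apoptosis", t = 1.0) {
  if (nrow(ura) == 0) {
    return(tibble::tibble(gene_symbol = character(), putative_role = character(),
                          z_growing = numeric(), z_blocking = numeric()))
  }
  for (p in c(growing, blocking)) {
    if (!p %in% ura$process) rlang::abort(sprintf("process '%s' absent from URA scores", p))
  }
  wide <- tibble::tibble(
    gene_symbol = sort_c(unique(ura$gene_symbol)))
  wide$z_growing <- ura$z[match(paste(wide$gene_symbol, growing),
                                paste(ura$gene_symbol, ura$process))]
  wide$z_blocking <- ura$z[match(paste(wide$gene_symbol, blocking),
                                 paste(ura$gene_symbol, ura$process))]
  role <- dplyr::case_when(
    wide$z_growing >= t & wide$z_blocking <= -t ~ "putative_OCG",
    wide$z_growing <= -t & wide$z_blocking >= t ~ "putative_TSG",
    TRUE ~ NA_character_)
  out <- wide[!is.na(role), , drop = FALSE]
  out$putative_role <- role[!is.na(role)]
  tibble::as_tibble(out[c("gene_symbol", "putative_role", "z_growing", "z_blocking")])
}

#' Load an externally computed mediator table
#'
#' Reads a TSV with columns `gene_symbol` (or `gene`) and `putative_role`
#' (or `role`), so mediator calls from another implementation of the
#' primary layer can feed the methylation-integration step directly. Role
#' labels are matched case-insensitively and the short aliases `TSG` /
#' `OCG` are accepted.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_symbol`, `putative_role` and, when
#'   present in the file, `z_growing` / `z_blocking`.
#' @export
load_pra <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[names(df) == "gene"] <- "gene_symbol"
  names(df)[names(df) == "role"] <- "putative_role"
  if (nrow(df) == 0) {
    rlang::warn("empty mediator table")
    return(tibble::tibble(gene_symbol = character(), putative_role = character()))
  }
  if (!all(c("gene_symbol", "putative_role") %in% names(df))) {
    rlang::abort("mediator table must have columns gene_symbol (or gene) and putative_role (or role)")
  }
  norm <- tolower(sub("^putative_", "", df$putative_role, ignore.case = TRUE))
  role <- dplyr::case_when(norm == "tsg" ~ "putative_TSG",
                           norm == "ocg" ~ "putative_OCG",
                           TRUE ~ NA_character_)
  if (anyNA(role)) {
    bad <- unique(df$putative_role[is.na(role)])
    rlang::abort(sprintf("unknown putative_role value(s): %s", paste(bad, collapse = ", ")))
  }
  df$putative_role <- role
  if (anyDuplicated(df$gene_symbol)) rlang::abort("duplicate gene_symbol in mediator table")
  keep <- intersect(c("gene_symbol", "putative_role", "z_growing", "z_blocking"), names(df))
  tibble::as_tibble(df[keep])
}
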