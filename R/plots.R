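#' Heatmap of functional CpG counts per mediator
#'
#' Shows, for every oncogenic mediator with at least one functional CpG,
#' the number of hypo-, hyper- and dual-methylated CpG sites. Rows are
#' ordered by evidence category and then gene symbol, so re-rendering the
#' same input gives an identical figure.
#'
#' @param mediator_summary Tibble from [summarize_cpgs()] /
#'   [classify_evidence()] (or the `mediator_summary` element of a
#'   `driver_prediction`).
#' @return A ggplot object, or `NULL` (with a warning) when no mediator
#'   has any functional CpG.
#' @export
plot_cpg_state_counts <- function(mediator_summary) {
  df <- mediator_summary
  df <- df[df$n_hypo + df$n_hyper + df$n_dual > 0, , drop = FALSE]
  if (nrow(df) == 0) {
    rlang::warn("no mediator has functional CpGs; nothing to plot")
    return(NULL)
  }
  if (!"evidence" %in% names(df)) df$evidence <- ""
  df <- df[order(df$evidence, df$gene_symbol), , drop = FALSE]
  long <- tidyr::pivot_longer(
    df[c("gene_symbol", "evidence", "n_hypo", "n_hyper", "n_dual")],
    cols = c("n_hypo", "n_hyper", "n_dual"),
    names_to = "state", values_to = "n")
  long$state <- factor(long$state, levels = c("n_hypo", "n_hyper", "n_dual"),
                       labels = c("Hypo", "Hyper", "Dual"))
  long$gene_symbol <- factor(long$gene_symbol, levels = rev(unique(df$gene_symbol)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$gene_symbol,
                                     fill = .data$n)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "CpG methylation state", y = NULL, fill = "CpG sites",
                  title = "Functional CpG sites per oncogenic mediator") +
    ggplot2::theme_minimal()
}

#' Heatmap of process effect scores for predicted driver genes
#'
#' Displays the growing- and blocking-process effect scores of the driver
#' genes, annotated by role: oncogenes push the growing process up and the
#' blocking process down; tumor suppressors mirror this.
#'
#' @param ura Long score tibble from [run_ura()].
#' @param drivers Driver tibble (`gene_symbol`, `role`), e.g. the
#'   `drivers` element of a `driver_prediction`.
#' @param growing,blocking Process names to display.
#' @return A ggplot object, or `NULL` (with a warning) when the driver set
#'   is empty.
#' @export
plot_driver_process_effects <- function(ura, drivers,
                                        growing = "proliferation",
                                        blocking = "apoptosis") {
  if (nrow(drivers) == 0) {
    rlang::warn("empty driver set; nothing to plot")
    return(NULL)
  }
  missing <- setdiff(drivers$gene_symbol, ura$gene_symbol)
  if (length(missing)) {
    rlang::abort(sprintf("driver gene(s) absent from URA scores: %s",
                         paste(missing, collapse = ", ")))
  }
  df <- ura[ura$gene_symbol %in% drivers$gene_symbol &
              ura$process %in% c(growing, blocking), , drop = FALSE]
  df$role <- drivers$role[match(df$gene_symbol, drivers$gene_symbol)]
  df <- df[order(df$role, df$gene_symbol), , drop = FALSE]
  df$gene_symbol <- factor(df$gene_symbol, levels = rev(unique(df$gene_symbol)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$process, y = .data$gene_symbol,
                                   fill = .data$z)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$role), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "effect z",
                  title = "Process effects of predicted driver genes") +
    ggplot2::theme_minimal()
}

#' Methylation mixture and expression of one CpG-gene pair
#'
#' Two panels: the tumor beta-value histogram of the probe overlaid with
#' the fitted beta-mixture component densities, and the gene's expression
#' split by methylation group (abnormal component samples, normal-like
#' component samples, and normal tissue).
#'
#' @param cohort A `meth_cohort`.
#' @param fits Named list of state-called fits (see
#'   [fit_cohort_mixtures()]), or a single `beta_mixture_fit`.
#' @param probe_id Probe to display.
#' @param gene_symbol Gene to display.
#' @return A patchwork-combined ggplot object.
#' @export
plot_methylation_expression <- function(cohort, fits, probe_id, gene_symbol) {
  fit <- if (inherits(fits, "beta_mixture_fit")) fits else fits[[probe_id]]
  if (is.null(fit)) rlang::abort(sprintf("unknown probe '%s'", probe_id))
  if (!gene_symbol %in% rownames(cohort$expr)) {
    rlang::abort(sprintf("unknown gene '%s'", gene_symbol))
  }
  dens <- do.call(rbind, lapply(seq_len(fit$K), function(k) {
    xs <- seq(0.005, 0.995, length.out = 200)
    data.frame(component = factor(k), x = xs,
               y = fit$weights[k] * stats::dbeta(xs, fit$alpha[k], fit$beta[k]))
  }))
  p1 <- ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = data.frame(beta = fit$data),
      ggplot2::aes(x = .data$beta, y = ggplot2::after_stat(density)),
      bins = 25, fill = "grey85", color = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$component), linewidth = 0.8) +
    ggplot2::labs(x = "beta value (tumor)", y = "density",
                  title = sprintf("%s: %d-component beta mixture", probe_id, fit$K)) +
    ggplot2::theme_minimal()

  groups <- rep("normal tissue", length(cohort$normal_ids))
  vals <- cohort$expr[gene_symbol, cohort$normal_ids]
  if (!is.null(names(fit$assignment))) {
    st <- fit$component_state %||% rep("component", fit$K)
    lab <- paste0("tumor: ", st[fit$assignment])
    groups <- c(lab, groups)
    vals <- c(cohort$expr[gene_symbol, names(fit$assignment)], vals)
  }
  p2 <- ggplot2::ggplot(data.frame(group = groups, expr = vals),
                        ggplot2::aes(x = .data$group, y = .data$expr)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, fill = "grey90") +
    ggplot2::labs(x = NULL, y = sprintf("%s expression (log2)", gene_symbol)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))

  patchwork::wrap_plots(p1, p2, ncol = 2)
}

#' @rdname plot_cpg_state_counts
#' @param object A `driver_prediction`.
#' @param ... Unused.
#' @export
autoplot.driver_prediction <- function(object, ...) {
  plot_cpg_state_counts(object$mediator_summary)
}
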