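#' Mutual information between two discretized vectors
#'
#' Plug-in mutual information (natural log) after equal-frequency
#' discretization of both variables into `max(2, floor(sqrt(n)))` bins.
#' Constant vectors carry no information and return 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Nonnegative mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  xd <- discretize_ef(x, b)
  yd <- discretize_ef(y, b)
  mi_disc(xd$bins, yd$bins, xd$n_bins, yd$n_bins)
}

# Equal-frequency discretization; collapses bins when quantile breaks tie.
discretize_ef <- function(x, b) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = b + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) {
    return(list(bins = rep(1L, length(x)), n_bins = 1L))
  }
  bins <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  list(bins = as.integer(bins), n_bins = length(br) - 1L)
}

# MI from pre-binned integer vectors; nx, ny are bin counts.
mi_disc <- function(xb, yb, nx, ny) {
  if (nx < 2L || ny < 2L) return(0)
  n <- length(xb)
  joint <- tabulate((xb - 1L) * ny + yb, nbins = nx * ny) / n
  px <- tabulate(xb, nbins = nx) / n
  py <- tabulate(yb, nbins = ny) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  max(0, h(px) + h(py) - h(joint))
}

#' Build a mutual-information gene regulatory network over the DEGs
#'
#' For each differentially expressed gene (regulator) the mutual
#' information with every other gene is computed on tumor samples (the
#' disease state in which drivers act; set `samples = "all"` to use the
#' whole cohort). Both variables are discretized into equal-frequency bins,
#' `B = max(2, floor(sqrt(n)))`. Edges are kept when their MI exceeds a
#' per-regulator permutation threshold: the `1 - alpha` quantile of MI
#' values obtained from `n_perm` seeded permutations of the regulator's
#' values against cycling target genes.
#'
#' @param cohort A `meth_cohort`.
#' @param degs DEG table from [run_dea()] / [load_dea()]; rows with
#'   `is_deg` define the regulators.
#' @param n_perm Number of permutations per regulator.
#' @param alpha Permutation significance level for edge retention.
#' @param seed Seed for the single permutation stream (required).
#' @param samples `"tumor"` (default) or `"all"`.
#' @return A tibble with columns `regulator`, `target`, `mi`, `threshold`,
#'   `kept`. The retained regulon of a regulator is its `kept` rows.
#' @export
build_grn <- function(cohort, degs, n_perm = 100, alpha = 0.05, seed,
                      samples = c("tumor", "all")) {
  samples <- match.arg(samples)
  if (missing(seed)) rlang::abort("build_grn() requires an explicit seed")
  ids <- if (samples == "tumor") cohort$tumor_ids else colnames(cohort$expr)
  if (length(ids) < 8) {
    rlang::abort(sprintf("need >= 8 samples to estimate the network, got %d", length(ids)))
  }
  expr <- cohort$expr[, ids, drop = FALSE]
  n <- ncol(expr)
  b <- max(2L, floor(sqrt(n)))

  genes <- rownames(expr)
  disc <- lapply(seq_len(nrow(expr)), function(i) discretize_ef(expr[i, ], b))
  bins <- lapply(disc, `[[`, "bins")
  nb <- vapply(disc, `[[`, integer(1), "n_bins")
  names(bins) <- names(nb) <- genes

  regulators <- sort_c(intersect(degs$gene_symbol[degs$is_deg], genes))
  if (length(regulators) == 0) {
    return(tibble::tibble(regulator = character(), target = character(),
                          mi = numeric(), threshold = numeric(), kept = logical()))
  }

  with_rng(seed, {
    out <- lapply(regulators, function(r) {
      targets <- setdiff(genes, r)
      xb <- bins[[r]]; nx <- nb[[r]]
      mi <- vapply(targets, function(tg) mi_disc(xb, bins[[tg]], nx, nb[[tg]]),
                   numeric(1))
      # Null: permute the regulator, pair with cycling targets. Equal-
      # frequency binning gives every gene the same marginals, so the null
      # MI distribution is shared across targets.
      null_mi <- vapply(seq_len(n_perm), function(j) {
        tg <- targets[((j - 1L) %% length(targets)) + 1L]
        xp <- xb[sample.int(n)]
        mi_disc(xp, bins[[tg]], nx, nb[[tg]])
      }, numeric(1))
      thr <- stats::quantile(null_mi, probs = 1 - alpha, names = FALSE)
      tibble::tibble(regulator = r, target = targets, mi = unname(mi),
                     threshold = thr, kept = mi > thr)
    })
    dplyr::bind_rows(out)
  })
}
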