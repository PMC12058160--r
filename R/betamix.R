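#' Fit a beta mixture to tumor beta values at one CpG
#'
#' Decomposes the tumor methylation profile of a probe into 1..`k_max`
#' beta-distributed components by expectation-maximisation. Components are
#' parameterised by mean and precision, \eqn{\alpha_k = \mu_k \phi_k},
#' \eqn{\beta_k = (1 - \mu_k)\phi_k}. The E-step computes responsibilities
#' from beta densities; the M-step re-estimates \eqn{\mu_k, \phi_k} by
#' method of moments on responsibility-weighted moments. Initialisation
#' partitions the sorted values into K equal blocks, which makes the fit
#' deterministic. Iteration stops when the log-likelihood gain falls below
#' `tol` or after `max_iter` iterations; a moment update that would lower
#' the log-likelihood is rejected and the previous parameters kept, so the
#' recorded log-likelihood trace is non-decreasing. A component whose
#' weight collapses below `prune_min` marks the fit degenerate and the
#' model drops out of selection, leaving the K-1 fit. The number of
#' components is chosen by minimum BIC = -2 log L + (3K - 1) log n.
#'
#' @param tumor_betas Numeric vector of beta values in (0, 1); at least 10
#'   non-missing values.
#' @param k_max Largest number of components considered (3 allows a
#'   normal-like plus a hypo- and a hypermethylated component).
#' @param probe_id Optional identifier stored in the fit.
#' @param tol,max_iter EM convergence controls.
#' @param prune_min Minimum component weight before a fit is declared
#'   degenerate.
#' @return An object of class `beta_mixture_fit` with elements `K`,
#'   `weights`, `means`, `phis`, `alpha`, `beta`, `loglik`, `loglik_trace`,
#'   `bic`, `bic_all`, `assignment` (per-sample argmax-responsibility
#'   component), `responsibilities`, `n`, `data`.
#' @export
fit_beta_mixture <- function(tumor_betas, k_max = 3, probe_id = NA_character_,
                             tol = 1e-6, max_iter = 500, prune_min = 0.01) {
  x <- tumor_betas[!is.na(tumor_betas)]
  if (length(x) < 10) {
    rlang::abort(sprintf("need >= 10 non-missing tumor beta values, got %d", length(x)))
  }
  eps <- 1e-3
  x <- pmin(pmax(x, eps), 1 - eps)
  n <- length(x)

  fits <- vector("list", k_max)
  bic_all <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    f <- beta_mix_em(x, k, tol = tol, max_iter = max_iter, prune_min = prune_min)
    fits[[k]] <- f
    if (!is.null(f)) bic_all[k] <- -2 * f$loglik + (3 * k - 1) * log(n)
  }
  if (all(is.na(bic_all))) rlang::abort("beta mixture fit failed for all K")
  best <- which.min(bic_all)
  f <- fits[[best]]

  structure(list(
    probe_id = probe_id,
    K = best,
    weights = f$pi,
    means = f$mu,
    phis = f$phi,
    alpha = f$mu * f$phi,
    beta = (1 - f$mu) * f$phi,
    loglik = f$loglik,
    loglik_trace = f$trace,
    bic = bic_all[best],
    bic_all = bic_all,
    assignment = f$assignment,
    responsibilities = f$resp,
    n = n,
    data = x
  ), class = "beta_mixture_fit")
}

# EM for a fixed K; returns NULL when a component degenerates.
beta_mix_em <- function(x, k, tol, max_iter, prune_min) {
  n <- length(x)
  # quantile-partition init: sorted values split into k equal blocks
  ord <- sort(x)
  blocks <- split(ord, ceiling(seq_along(ord) / (n / k)))
  mu <- vapply(blocks, mean, numeric(1))
  v <- vapply(blocks, function(b) {
    vv <- stats::var(b); if (is.na(vv)) 1e-6 else max(vv, 1e-6)
  }, numeric(1))
  phi <- pmax(pmin(mu * (1 - mu) / v - 1, 1e4), 1e-2)
  pi_k <- lengths(blocks) / n
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)

  ld <- log_dens(x, pi_k, mu, phi)
  lse <- row_lse(ld)
  ll <- sum(lse)
  trace <- ll
  for (it in seq_len(max_iter)) {
    resp <- exp(ld - lse)
    nk <- .colSums(resp, n, k)
    if (any(nk / n < prune_min)) return(NULL)  # degenerate: drop this K
    pi_new <- nk / n
    mu_new <- .colSums(resp * x, n, k) / nk
    v_new <- .colSums(resp * x * x, n, k) / nk - mu_new^2
    phi_new <- mu_new * (1 - mu_new) / pmax(v_new, 1e-8) - 1
    phi_new <- pmax(pmin(phi_new, 1e4), 1e-2)
    mu_new <- pmin(pmax(mu_new, 1e-4), 1 - 1e-4)
    ld_new <- log_dens(x, pi_new, mu_new, phi_new)
    lse_new <- row_lse(ld_new)
    ll_new <- sum(lse_new)
    if (ll_new < ll - 1e-10) break  # moment step would descend; keep previous
    pi_k <- pi_new; mu <- mu_new; phi <- phi_new
    ld <- ld_new; lse <- lse_new
    gain <- ll_new - ll
    ll <- ll_new
    trace <- c(trace, ll)
    if (gain < tol) break
  }
  resp <- exp(ld - lse)
  if (any(.colSums(resp, n, k) / n < prune_min)) return(NULL)
  ord_mu <- order(mu)
  resp <- resp[, ord_mu, drop = FALSE]
  list(pi = unname(pi_k[ord_mu]), mu = unname(mu[ord_mu]), phi = unname(phi[ord_mu]),
       loglik = ll, trace = trace,
       resp = resp,
       assignment = max.col(resp, ties.method = "first"))
}

log_dens <- function(x, pi_k, mu, phi) {
  k <- length(pi_k)
  ld <- matrix(0, length(x), k)
  for (j in seq_len(k)) {
    ld[, j] <- log(pi_k[j]) + stats::dbeta(x, mu[j] * phi[j], (1 - mu[j]) * phi[j], log = TRUE)
  }
  ld
}

row_lse <- function(ld) {
  m <- ld[, 1]
  k <- ncol(ld)
  if (k > 1) for (j in 2:k) m <- pmax(m, ld[, j])
  m + log(.rowSums(exp(ld - m), nrow(ld), k))
}

#' Call hypo/hyper/dual methylation states against normal tissue
#'
#' Computes the mean beta of the normal samples and, per mixture
#' component, the differential methylation value
#' `dm_k = mu_k - normal_mean`. A component is `hypo` when
#' `dm_k <= -dm_min`, `hyper` when `dm_k >= dm_min`, otherwise
#' `normal-like`. The probe-level state summarises the abnormal
#' components: `Hypo` (only hypomethylated abnormal components), `Hyper`
#' (only hyper), `Dual` (both, i.e. some patients lose and others gain
#' methylation at this CpG), or `None`.
#'
#' @param fit A `beta_mixture_fit`.
#' @param normal_betas Beta values of the normal samples at the same probe.
#' @param dm_min Minimum absolute differential methylation for an abnormal
#'   call (beta-value difference).
#' @param min_normal Minimum number of non-missing normal values.
#' @return The fit, augmented with `normal_mean`, `dm`,
#'   `component_state` and `probe_state`.
#' @export
call_states <- function(fit, normal_betas, dm_min = 0.10, min_normal = 5) {
  nb <- normal_betas[!is.na(normal_betas)]
  if (length(nb) < min_normal) {
    rlang::abort(sprintf("need >= %d normal beta values, got %d", min_normal, length(nb)))
  }
  fit$normal_mean <- mean(nb)
  fit$dm <- fit$means - fit$normal_mean
  fit$dm_min <- dm_min
  fit$component_state <- dplyr::case_when(
    fit$dm <= -dm_min ~ "hypo",
    fit$dm >= dm_min ~ "hyper",
    TRUE ~ "normal-like")
  has_hypo <- any(fit$component_state == "hypo")
  has_hyper <- any(fit$component_state == "hyper")
  fit$probe_state <- if (has_hypo && has_hyper) "Dual"
    else if (has_hypo) "Hypo"
    else if (has_hyper) "Hyper"
    else "None"
  fit
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf("<beta_mixture_fit> probe %s: K = %d, n = %d, BIC = %.2f\n",
              x$probe_id, x$K, x$n, x$bic))
  cat(sprintf("  weights: %s\n  means:   %s\n",
              paste(sprintf("%.3f", x$weights), collapse = " "),
              paste(sprintf("%.3f", x$means), collapse = " ")))
  if (!is.null(x$probe_state)) {
    cat(sprintf("  normal mean %.3f, probe state %s\n", x$normal_mean, x$probe_state))
  }
  invisible(x)
}

#' Tidy a beta-mixture fit into one row per component
#'
#' @param x A `beta_mixture_fit`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `component`, `weight`,
#'   `mean`, `phi`, `alpha`, `beta` and, after [call_states()], `dm` and
#'   `state`.
#' @export
tidy.beta_mixture_fit <- function(x, ...) {
  out <- tibble::tibble(
    probe_id = x$probe_id,
    component = seq_len(x$K),
    weight = x$weights,
    mean = x$means,
    phi = x$phis,
    alpha = x$alpha,
    beta = x$beta)
  if (!is.null(x$dm)) {
    out$dm <- x$dm
    out$state <- x$component_state
  }
  out
}

#' One-row model summary of a beta-mixture fit
#'
#' @param x A `beta_mixture_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `probe_id`, `K`, `loglik`, `bic`, `n`
#'   and, after [call_states()], `normal_mean` and `probe_state`.
#' @export
glance.beta_mixture_fit <- function(x, ...) {
  tibble::tibble(
    probe_id = x$probe_id,
    K = x$K,
    loglik = x$loglik,
    bic = x$bic,
    n = x$n,
    normal_mean = x$normal_mean %||% NA_real_,
    probe_state = x$probe_state %||% NA_character_)
}

#' Fit and state-call beta mixtures for every manifest probe in a cohort
#'
#' Convenience wrapper running [fit_beta_mixture()] on the tumor samples
#' and [call_states()] against the normal samples of each probe present in
#' both the methylation matrix and the probe manifest.
#'
#' @param cohort A `meth_cohort`.
#' @param manifest Probe manifest tibble; only its probes are fitted.
#' @param dm_min Differential-methylation threshold for [call_states()].
#' @param k_max Passed to [fit_beta_mixture()].
#' @return A named list of `beta_mixture_fit` objects, one per probe.
#' @export
fit_cohort_mixtures <- function(cohort, manifest, dm_min = 0.10, k_max = 3) {
  probes <- sort_c(intersect(unique(manifest$probe_id), rownames(cohort$meth)))
  tum <- cohort$meth[probes, cohort$tumor_ids, drop = FALSE]
  nor <- cohort$meth[probes, cohort$normal_ids, drop = FALSE]
  fits <- lapply(probes, function(p) {
    f <- fit_beta_mixture(tum[p, ], k_max = k_max, probe_id = p)
    names(f$assignment) <- cohort$tumor_ids[!is.na(tum[p, ])]
    call_states(f, nor[p, ], dm_min = dm_min)
  })
  stats::setNames(fits, probes)
}
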