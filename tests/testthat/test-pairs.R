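# Hand-built cohort with a single probe whose tumor betas split into a
# hypomethylated and a normal-like group, and genes whose expression either
# tracks that split or ignores it.
pair_cohort <- function(shift_a = 2, shift_b = 0, seed = 21) {
  set.seed(seed)
  n_ab <- 30; n_nl <- 30; n_nor <- 20
  tum <- sprintf("T%02d", seq_len(n_ab + n_nl))
  nor <- sprintf("N%02d", seq_len(n_nor))
  abn <- tum[seq_len(n_ab)]
  beta <- c(rbeta(n_ab, 2, 18), rbeta(n_nl, 12, 8), rbeta(n_nor, 12, 8))
  meth <- matrix(pmin(pmax(beta, 1e-3), 1 - 1e-3), 1,
                 dimnames = list("cg1", c(tum, nor)))
  ga <- c(rnorm(n_ab, 8 + shift_a, 0.5), rnorm(n_nl + n_nor, 8, 0.5))
  gb <- c(rnorm(n_ab, 8 + shift_b, 0.5), rnorm(n_nl + n_nor, 8, 0.5))
  expr <- rbind(GA = ga, GB = gb)
  colnames(expr) <- c(tum, nor)
  sheet <- tibble::tibble(sample_id = c(tum, nor),
                          group = rep(c("tumor", "normal"), c(length(tum), n_nor)))
  list(cohort = align_cohort(expr, meth, sheet), abnormal = abn)
}

pair_manifest <- tibble::tibble(
  probe_id = "cg1", gene_symbol = c("GA", "GB"), chrom = "chr1",
  start = 1, end = 3, region_class = "promoter")

test_that("an expression-shifted abnormal group yields a functional pair", {
  pc <- pair_cohort(shift_a = 2, shift_b = 0)
  fits <- fit_cohort_mixtures(pc$cohort, pair_manifest)
  expect_identical(fits$cg1$probe_state, "Hypo")
  pairs <- pair_with_expression(fits, pair_manifest, pc$cohort)
  # probe maps to two genes; only the shifted one is functional
  expect_identical(sort(pairs$gene_symbol), c("GA", "GB"))
  expect_true(pairs$functional[pairs$gene_symbol == "GA"])
  expect_lte(pairs$assoc_fdr[pairs$gene_symbol == "GA"], 0.05)
  expect_false(pairs$functional[pairs$gene_symbol == "GB"])
})

test_that("a flat gene over the same split is not functional", {
  pc <- pair_cohort(shift_a = 0, shift_b = 0)
  fits <- fit_cohort_mixtures(pc$cohort, pair_manifest)
  pairs <- pair_with_expression(fits, pair_manifest, pc$cohort)
  expect_true(all(!pairs$functional))
})

test_that("promoter_only filters non-promoter manifest rows", {
  pc <- pair_cohort()
  man <- pair_manifest
  man$region_class <- c("promoter", "other")
  fits <- fit_cohort_mixtures(pc$cohort, man)
  pairs <- pair_with_expression(fits, man, pc$cohort, promoter_only = TRUE)
  expect_identical(pairs$gene_symbol, "GA")
  pairs_all <- pair_with_expression(fits, man, pc$cohort, promoter_only = FALSE)
  expect_identical(sort(pairs_all$gene_symbol), c("GA", "GB"))
})

test_that("probes without normal-like components fall back to normal tissue", {
  set.seed(33)
  tum <- sprintf("T%02d", 1:30); nor <- sprintf("N%02d", 1:20)
  # all tumors hypomethylated; normals high
  meth <- matrix(c(rbeta(30, 2, 18), rbeta(20, 16, 4)), 1,
                 dimnames = list("cg1", c(tum, nor)))
  expr <- matrix(c(rnorm(30, 10, 0.5), rnorm(20, 8, 0.5)), 1,
                 dimnames = list("GA", c(tum, nor)))
  sheet <- tibble::tibble(sample_id = c(tum, nor),
                          group = rep(c("tumor", "normal"), c(30, 20)))
  co <- align_cohort(expr, meth, sheet)
  man <- pair_manifest[1, ]
  fits <- fit_cohort_mixtures(co, man)
  expect_identical(fits$cg1$K, 1L)
  expect_identical(fits$cg1$probe_state, "Hypo")
  pairs <- pair_with_expression(fits, man, co)
  expect_identical(pairs$n_reference, 20L)  # compared against normal tissue
  expect_true(pairs$functional)
})

test_that("undersized comparison groups are skipped with a message", {
  pc <- pair_cohort()
  fits <- fit_cohort_mixtures(pc$cohort, pair_manifest)
  # shrink the abnormal group below min_group by raising the minimum
  expect_message(
    pairs <- pair_with_expression(fits, pair_manifest, pc$cohort, min_group = 50),
    "skipped")
  expect_identical(nrow(pairs), 0L)
})
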