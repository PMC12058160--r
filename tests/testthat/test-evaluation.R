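# Independent two-sided Fisher oracle via stats::fisher.test (conditional
# exact test); the package computes the p-value by direct hypergeometric
# enumeration, so the two routes are independent.
fisher_oracle <- function(a, b, c_, d) {
  stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value
}

test_that("confusion counts and the percentage formulas are exact", {
  u <- c(LETTERS, letters)
  r <- confusion_vs_census(c("A", "B"), c("A", "B"), u)
  expect_identical(c(r$tp, r$fp, r$fn), c(2L, 0L, 0L))
  expect_equal(r$precision, 100)
  expect_equal(r$sensitivity, 100)

  r2 <- confusion_vs_census(c("A", "B", "C", "D"), c("A", "X", "Y"), u)
  expect_identical(c(r2$tp, r2$fp, r2$fn), c(1L, 3L, 2L))
  expect_equal(r2$precision, 25)
  expect_equal(r2$sensitivity, 100 / 3)

  r3 <- confusion_vs_census("A", c("B", "C"), u)
  expect_identical(c(r3$tp, r3$fn), c(0L, 2L))
  expect_equal(r3$sensitivity, 0)
  expect_equal(r3$precision, 0)

  r4 <- confusion_vs_census(character(0), "A", u)
  expect_true(is.na(r4$precision))

  expect_error(confusion_vs_census("A", "A", character(0)), "empty")
  expect_error(confusion_vs_census("zz", "A", u), "subset")
})

test_that("precision and sensitivity formulas hold on exhaustive small tables", {
  u <- sprintf("g%03d", 1:40)
  for (tp in 0:6) for (fp in 0:6) for (fn in 0:6) {
    genes <- u[seq_len(tp + fp)]
    census <- c(u[seq_len(tp)], u[tp + fp + seq_len(fn)])
    r <- confusion_vs_census(genes, census, u)
    expect_identical(c(r$tp, r$fp, r$fn), c(tp, fp, fn))
    if (tp + fp > 0) expect_equal(r$precision, 100 * tp / (tp + fp))
    if (tp + fn > 0) expect_equal(r$sensitivity, 100 * tp / (tp + fn))
  }
})

test_that("the enumerated Fisher p matches the closed-form extreme case", {
  # table [[5,0],[0,5]]: only the two perfectly sorted tables are as extreme
  r <- tibble::tibble(gene_set_name = "x", tp = 5L, fp = 0L, fn = 0L,
                      precision = 100, sensitivity = 100, universe_size = 10L)
  out <- fisher_association(r)
  expect_equal(out$fisher_p, 2 / choose(10, 5), tolerance = 1e-12)
})

test_that("the enumerated Fisher p agrees with the conditional exact test", {
  # dense sweep of small tables plus random larger ones with N <= 60
  for (a in 0:4) for (b in 0:4) for (c_ in 0:4) for (d in 0:4) {
    if (a + b + c_ + d == 0) next
    expect_equal(methdriver:::fisher_exact_p(a, b, c_, d),
                 fisher_oracle(a, b, c_, d), tolerance = 1e-10)
  }
  set.seed(8)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(10:60, 1), runif(4, 0.05, 1)))
    expect_equal(methdriver:::fisher_exact_p(cells[1], cells[2], cells[3], cells[4]),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("odds ratios are symmetric at balance and monotone in cell d", {
  mk <- function(tp, fp, fn, n) tibble::tibble(
    gene_set_name = "x", tp = tp, fp = fp, fn = fn,
    precision = NA_real_, sensitivity = NA_real_, universe_size = n)
  bal <- fisher_association(mk(10L, 10L, 10L, 40L))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$fisher_p, 1)

  or1 <- fisher_association(mk(5L, 5L, 5L, 20L))$odds_ratio   # d = 5
  or2 <- fisher_association(mk(5L, 5L, 5L, 25L))$odds_ratio   # d = 10
  expect_gt(or2, or1)

  # Haldane correction engages on zero cells
  zero <- fisher_association(mk(5L, 0L, 0L, 10L))
  expect_equal(zero$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))

  expect_error(fisher_association(mk(5L, 5L, 5L, 10L)), "negative")
})

test_that("set overlaps count the three disjoint regions", {
  expect_equal(set_overlap(c(1, 2, 3), c(2, 3, 4)),
               tibble::tibble(only_a = 1L, shared = 2L, only_b = 1L))
  expect_equal(set_overlap(c("a", "b"), c("x")),
               tibble::tibble(only_a = 2L, shared = 0L, only_b = 1L))
  expect_equal(set_overlap(1:3, 1:3),
               tibble::tibble(only_a = 0L, shared = 3L, only_b = 0L))
})
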