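mk_pairs <- function(gene, states) {
  tibble::tibble(
    probe_id = sprintf("cg%02d", seq_along(states)),
    gene_symbol = gene, cpg_state = states,
    dm = replicate(length(states), 0.3, simplify = FALSE),
    n_abnormal = 10L, n_reference = 10L,
    assoc_p = 0.001, assoc_fdr = 0.01, functional = TRUE)
}

mk_mediators <- function(genes, roles) {
  tibble::tibble(gene_symbol = genes, putative_role = roles,
                 z_growing = 2, z_blocking = -2)
}

test_that("CpG states are counted per mediator with dual never deciding", {
  med <- mk_mediators(c("A", "B", "C", "D"), rep("putative_OCG", 4))
  pairs <- dplyr::bind_rows(
    mk_pairs("A", c("Hypo", "Hypo", "Dual")),
    mk_pairs("B", c("Hypo", "Hyper")),
    mk_pairs("C", c("Dual")))
  s <- summarize_cpgs(med, pairs)
  a <- s[s$gene_symbol == "A", ]
  expect_identical(c(a$n_hypo, a$n_hyper, a$n_dual), c(2L, 0L, 1L))
  expect_identical(a$gene_state, "Hypo")
  expect_identical(s$gene_state[s$gene_symbol == "B"], "Mixed")
  expect_identical(s$gene_state[s$gene_symbol == "C"], "Dual-only")
  expect_identical(s$gene_state[s$gene_symbol == "D"], "None")
})

test_that("non-functional pairs are excluded from the counts", {
  med <- mk_mediators("A", "putative_OCG")
  pairs <- mk_pairs("A", c("Hypo", "Hypo"))
  pairs$functional[2] <- FALSE
  s <- summarize_cpgs(med, pairs)
  expect_identical(s$n_hypo, 1L)
})

test_that("the evidence rule table is implemented exactly", {
  grid <- tibble::tibble(
    gene_symbol = sprintf("G%d", 1:8),
    putative_role = rep(c("putative_OCG", "putative_TSG"), 4),
    n_hypo = 0L, n_hyper = 0L, n_dual = 0L,
    gene_state = rep(c("Hypo", "Hyper", "Mixed", "None"), each = 2))
  out <- classify_evidence(grid)
  expect_identical(out$evidence, c(
    "Agreement_OCG", "Conflicting",   # Hypo x {OCG, TSG}
    "Conflicting", "Agreement_TSG",   # Hyper x {OCG, TSG}
    "Mixed", "Mixed",
    "NoEvidence", "NoEvidence"))
  dual <- tibble::tibble(gene_symbol = "X", putative_role = "putative_TSG",
                         n_hypo = 0L, n_hyper = 0L, n_dual = 3L,
                         gene_state = "Dual-only")
  expect_identical(classify_evidence(dual)$evidence, "NoEvidence")
  expect_error(classify_evidence(dplyr::mutate(grid, putative_role = "oncogene")),
               "unknown putative_role")
})

test_that("a loaded mediator plus one hypo CpG yields exactly that driver", {
  f <- write_tsv_text(c("gene\trole", "MYC\tOCG"))
  med <- load_pra(f)
  pairs <- mk_pairs("MYC", "Hypo")
  s <- classify_evidence(summarize_cpgs(med, pairs))
  expect_identical(s$evidence, "Agreement_OCG")
})

test_that("evidence categories always partition the mediators", {
  run <- default_run()
  ms <- run$res$prediction$mediator_summary
  tab <- table(ms$evidence)
  expect_identical(sum(tab), nrow(run$res$mediators))
  drv <- run$res$prediction$drivers
  expect_true(all(drv$gene_symbol %in% ms$gene_symbol))
  expect_identical(length(intersect(drv$gene_symbol[drv$role == "TSG"],
                                    drv$gene_symbol[drv$role == "OCG"])), 0L)
})

test_that("removing a functional pair can only demote evidence, never flip roles", {
  med <- mk_mediators("A", "putative_OCG")
  pairs <- mk_pairs("A", c("Hypo", "Hyper"))
  full <- classify_evidence(summarize_cpgs(med, pairs))
  expect_identical(full$evidence, "Mixed")
  drop_hyper <- classify_evidence(summarize_cpgs(med, pairs[1, ]))
  expect_identical(drop_hyper$evidence, "Agreement_OCG")
  none <- classify_evidence(summarize_cpgs(med, pairs[0, ]))
  expect_identical(none$evidence, "NoEvidence")
})

test_that("the orchestrator writes the four outputs plus a run manifest", {
  run <- default_run()
  out <- file.path(tempdir(), "md_outputs")
  on.exit(unlink(out, recursive = TRUE))
  write_res <- predict_driver_genes(
    run$sim, run$res$mediators[0, ], run$res$degs[1:5, ],
    run$sim$manifest[1:3, ], out_dir = out)
  expect_true(all(file.exists(file.path(out, c(
    "drivers.tsv", "mediator_summary.tsv", "deg_annotation.tsv",
    "raw_pairs.tsv", "raw_fits.tsv", "run_manifest.json")))))
  manifest <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_identical(manifest$package, "methdriver")
  expect_equal(manifest$params$dm_min, 0.10)
})

test_that("zero functional pairs gives an empty driver set and NoEvidence", {
  med <- mk_mediators(c("A", "B"), c("putative_OCG", "putative_TSG"))
  empty_pairs <- mk_pairs("A", "Hypo")[0, ]
  s <- classify_evidence(summarize_cpgs(med, empty_pairs))
  expect_true(all(s$evidence == "NoEvidence"))
})
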