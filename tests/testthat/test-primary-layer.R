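make_regulons <- function(reg, targets) {
  tibble::tibble(regulator = reg, target = targets, mi = 1,
                 threshold = 0, kept = TRUE)
}

deg_row <- function(gene, lfc) {
  tibble::tibble(gene_symbol = gene, log2fc = lfc, p_value = 0.001,
                 fdr = 0.01, direction = ifelse(lfc > 0, "up", "down"),
                 is_deg = TRUE)
}

sigs2 <- tibble::tibble(
  process = rep(c("proliferation", "apoptosis"), each = 4),
  gene = c(paste0("P", 1:4), paste0("A", 1:4)),
  direction = "increase")

test_that("process effect scores follow the signed concordance formula", {
  regs <- make_regulons("G", paste0("P", 1:4))
  degs <- dplyr::bind_rows(deg_row("G", 2), lapply(paste0("P", 1:4), deg_row, lfc = 1.5))

  # 4 concordant targets: z = 4 / sqrt(4) = 2
  ura <- run_ura(regs, degs, sigs2)
  expect_equal(ura$z[ura$process == "proliferation"], 2)
  # empty intersection with the other process: z = 0
  expect_equal(ura$z[ura$process == "apoptosis"], 0)

  # 3 concordant + 1 discordant: z = (3 - 1) / sqrt(4) = 1
  degs_mixed <- dplyr::bind_rows(
    deg_row("G", 2), lapply(paste0("P", 1:3), deg_row, lfc = 1.5), deg_row("P4", -1.5))
  ura2 <- run_ura(regs, degs_mixed, sigs2)
  expect_equal(ura2$z[ura2$process == "proliferation"], 1)

  # a decrease-direction signature gene that goes down is concordant
  sigs_dec <- dplyr::mutate(sigs2, direction = "decrease")
  degs_down <- dplyr::bind_rows(deg_row("G", 2), lapply(paste0("P", 1:4), deg_row, lfc = -1))
  ura3 <- run_ura(regs, degs_down, sigs_dec)
  expect_equal(ura3$z[ura3$process == "proliferation"], 2)
})

test_that("targets absent from the DEG table are skipped with a message", {
  regs <- make_regulons("G", paste0("P", 1:4))
  degs <- dplyr::bind_rows(deg_row("G", 2), lapply(paste0("P", 1:3), deg_row, lfc = 1.5))
  expect_message(ura <- run_ura(regs, degs, sigs2), "skipped")
  expect_equal(ura$z[ura$process == "proliferation"], 3 / sqrt(3))
})

test_that("mediator calls implement the sign pattern on both processes", {
  ura <- tibble::tibble(
    gene_symbol = rep(c("A", "B", "C", "D", "E"), each = 2),
    process = rep(c("proliferation", "apoptosis"), 5),
    n_scored = 4,
    z = c(3, -3,    # A: growing up, blocking down -> OCG
          -3, 3,    # B: mirrored -> TSG
          0, 0,     # C: no signal -> excluded
          2, 2,     # D: same sign -> excluded
          0.5, -0.5 # E: below threshold -> excluded
    ))
  med <- run_pra(ura)
  expect_identical(med$gene_symbol, c("A", "B"))
  expect_identical(med$putative_role, c("putative_OCG", "putative_TSG"))
  expect_false(any(duplicated(med$gene_symbol)))

  # threshold is symmetric and tunable
  med2 <- run_pra(ura, t = 0.4)
  expect_true("E" %in% med2$gene_symbol)
  expect_error(run_pra(ura, growing = "nosuch"), "absent")
})

test_that("external mediator tables load with role aliases", {
  f <- write_tsv_text(c("gene\trole", "BRCA1\tTSG", "MYC\tocg", "KRAS\tPutative_OCG"))
  med <- load_pra(f)
  expect_identical(med$putative_role, c("putative_TSG", "putative_OCG", "putative_OCG"))

  bad <- write_tsv_text(c("gene\trole", "X\toncogene?"))
  expect_error(load_pra(bad), "unknown putative_role")
  empty <- write_tsv_text(c("gene\trole"))
  expect_warning(med0 <- load_pra(empty), "empty")
  expect_identical(nrow(med0), 0L)
})

test_that("planted mediators are recovered with correct roles on a synthetic cohort", {
  run <- default_run()
  truth <- run$sim$truth[run$sim$truth$kind == "driver", ]
  med <- run$res$mediators
  hit <- merge(med, truth, by.x = "gene_symbol", by.y = "gene")
  expect_gte(nrow(hit), 0.8 * nrow(truth))
  expect_identical(sub("putative_", "", hit$putative_role), hit$role)
})
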