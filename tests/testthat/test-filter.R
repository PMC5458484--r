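# Phase-I cascade: each filter's semantics, ledger bookkeeping, and
# order-insensitivity of the independent exclusion predicates.

test_that("filter_by_class keeps exactly the requested codes", {
  tx <- dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 300))),
    tx_tbl("t2", list(c(400, 700))),
    tx_tbl("t3", list(c(800, 1100)))
  )
  codes <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), class_code = c("u", "=", "x")
  )
  res <- filter_by_class(tx, codes)
  expect_setequal(unique(res$retained$transcript_id), c("t1", "t3"))
  expect_equal(res$ledger$n_excluded, 1L)
  expect_equal(res$ledger$n_input, res$ledger$n_retained + res$ledger$n_excluded)

  res <- filter_by_class(tx, codes, keep = c("=", "j", "o", "x", "i", "u"))
  expect_equal(dplyr::n_distinct(res$retained$transcript_id), 3)

  res <- filter_by_class(empty_tx(), codes)
  expect_equal(res$ledger$n_input, 0L)
  expect_equal(res$ledger$n_retained, 0L)

  expect_error(filter_by_class(tx, codes[1:2, ]), "no class code")
})

test_that("add-back unions annotated lncRNAs without double counting", {
  retained <- tx_tbl("t1", list(c(0, 300)))
  reference <- dplyr::bind_rows(
    tx_tbl("L1", list(c(1000, 1500))),
    tx_tbl("L2", list(c(2000, 2500))),
    tx_tbl("P1", list(c(3000, 3500)))
  ) |> dplyr::mutate(biotype = c("lincRNA", "antisense", "protein_coding"))
  res <- add_back_annotated_lncrnas(retained, reference)
  expect_setequal(unique(res$augmented$transcript_id), c("t1", "L1", "L2"))
  expect_equal(res$ledger$n_added, 2L)

  # no lncRNA biotypes: identity
  res <- add_back_annotated_lncrnas(
    retained, reference |> dplyr::filter(biotype == "protein_coding")
  )
  expect_equal(res$ledger$n_added, 0L)

  # an already-present id is not counted again
  res <- add_back_annotated_lncrnas(
    dplyr::bind_rows(retained, reference[1, ]), reference
  )
  expect_equal(res$ledger$n_added, 1L)
})

test_that("extended-TSS exclusion is strand-aware with half-open boundaries", {
  pc <- tx_tbl("p1", list(c(10000, 10500), c(11000, 11500)), gid = "pg1") |>
    dplyr::mutate(biotype = "protein_coding")
  mk_locus <- function(start, end, strand = "+") {
    merge_to_gene_loci(tx_tbl("q", list(c(start, end)), strand = strand,
                              gid = "gq"))
  }
  # region is [8500, 11501): an exon at [9000,9500) on '+' is excluded
  res <- exclude_pc_tss_overlap(mk_locus(9000, 9500), pc, flank = 1500)
  expect_equal(res$excluded, "gq")
  # same geometry on the opposite strand survives
  res <- exclude_pc_tss_overlap(mk_locus(9000, 9500, "-"), pc, flank = 1500)
  expect_equal(res$excluded, character())
  # exon ending exactly where the region starts does not overlap
  res <- exclude_pc_tss_overlap(mk_locus(8000, 8500), pc, flank = 1500)
  expect_equal(res$excluded, character())
  res <- exclude_pc_tss_overlap(mk_locus(8000, 8501), pc, flank = 1500)
  expect_equal(res$excluded, "gq")
})

test_that("small-RNA exclusion credits every matching set once per gene", {
  loci <- merge_to_gene_loci(dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 400)), gid = "g1"),
    tx_tbl("t2", list(c(1000, 1400)), gid = "g2")
  ))
  sets <- list(
    tRNA = tibble::tibble(chrom = "chr1", start = 100L, end = 200L, strand = "+"),
    miRNA = tibble::tibble(chrom = "chr1", start = 150L, end = 250L, strand = ".")
  )
  res <- exclude_small_rna_overlap(loci, sets)
  expect_equal(res$excluded, "g1")
  expect_equal(res$per_set$n_excluded, c(1L, 1L)) # both sets credited
  expect_equal(res$ledger$n_excluded, 1L)         # excluded once

  # intron-hosted small RNA does not exclude the host (exonic overlap only)
  host <- merge_to_gene_loci(tx_tbl("t3", list(c(0, 100), c(900, 1000)),
                                    gid = "g3"))
  res <- exclude_small_rna_overlap(
    host, list(tRNA = tibble::tibble(chrom = "chr1", start = 400L, end = 500L,
                                     strand = "+"))
  )
  expect_equal(res$excluded, character())

  # no sets: identity step
  res <- exclude_small_rna_overlap(loci, list())
  expect_equal(res$ledger$n_excluded, 0L)
})

test_that("minimum-length filter uses the spliced exon-union length", {
  loci <- merge_to_gene_loci(dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 199)), gid = "g199"),
    tx_tbl("t2", list(c(1000, 1100), c(2000, 2100)), gid = "g200")
  ))
  res <- filter_min_length(loci, 200)
  expect_equal(res$excluded, "g199")
  expect_true("g200" %in% res$retained$gene_id) # 100 + 100 = 200 retained
  res <- filter_min_length(loci, 0)
  expect_equal(res$excluded, character())
})

test_that("annotation-source labels require same-strand exonic overlap", {
  loci <- merge_to_gene_loci(tx_tbl("t1", list(c(0, 400)), gid = "g1"))
  sources <- list(
    MiTranscriptome = tx_tbl("m1", list(c(100, 200))),
    RefSeq = tx_tbl("r1", list(c(100, 200)), strand = "-")
  )
  lab <- annotate_known_overlap(loci, sources)
  expect_true(lab$MiTranscriptome)
  expect_false(lab$RefSeq) # opposite strand only
  expect_equal(names(annotate_known_overlap(loci, list())), "gene_id")
})

test_that("run_phase1 conserves the ledger and recovers planted exclusions", {
  fx <- generate_fixtures(fixture_spec(
    seed = 5, groups = c("A", "B"), samples_per_group = 2, n_pc = 20,
    n_lnc_per_group = 1, n_erna_per_group = 1, n_silent = 1, n_addback = 2,
    n_eq = 2, n_j = 1, n_o = 1, n_short = 2, n_tss = 2, n_smallrna = 1,
    n_coding = 1, with_hic = FALSE, with_segments = FALSE, with_de = FALSE
  ))
  p1 <- run_phase1(fx$data$assembly, fx$data$reference, fx$phase1_config)
  led <- tibble::as_tibble(p1$ledger)
  truth <- fx$truth$genes
  expect_equal(
    led$n_excluded[led$step == "class_code_filter"],
    sum(truth$fate == "excluded_class")
  )
  expect_equal(
    led$n_excluded[led$step == "pc_tss_exclusion"],
    sum(truth$fate == "excluded_tss")
  )
  expect_equal(
    led$n_excluded[led$step == "small_rna_exclusion"],
    sum(truth$fate == "excluded_smallrna")
  )
  expect_equal(
    led$n_excluded[led$step == "min_length_filter"],
    sum(truth$fate == "excluded_length")
  )
  # conservation where exclusion counts exist, chaining within each unit
  ex_steps <- led |> dplyr::filter(!is.na(n_excluded))
  expect_true(all(ex_steps$n_input == ex_steps$n_retained + ex_steps$n_excluded))
  for (u in unique(led$unit)) {
    sub <- led |> dplyr::filter(unit == u)
    if (nrow(sub) > 1) {
      expect_equal(sub$n_input[-1], sub$n_retained[-nrow(sub)])
    }
  }
})

test_that("the three exclusion filters commute on the final set", {
  fx <- generate_fixtures(fixture_spec(
    seed = 9, groups = c("A", "B"), samples_per_group = 2, n_pc = 16,
    n_lnc_per_group = 1, n_erna_per_group = 1, n_silent = 1, n_addback = 2,
    n_eq = 1, n_j = 1, n_o = 1, n_short = 2, n_tss = 2, n_smallrna = 2,
    n_coding = 0, with_hic = FALSE, with_segments = FALSE, with_de = FALSE
  ))
  idx <- build_reference_index(fx$data$reference)
  codes <- classify_transfrags(fx$data$assembly, idx)
  kept <- filter_by_class(fx$data$assembly, codes)$retained
  tx <- add_back_annotated_lncrnas(kept, fx$data$reference)$augmented
  loci <- merge_to_gene_loci(tx)
  pc <- fx$data$reference |> dplyr::filter(biotype == "protein_coding")
  filters <- list(
    tss = function(l) exclude_pc_tss_overlap(l, pc, 1500)$retained,
    rna = function(l) exclude_small_rna_overlap(l, fx$data$small_rna_sets)$retained,
    len = function(l) filter_min_length(l, 200)$retained
  )
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  results <- lapply(perms, function(p) {
    out <- loci
    for (i in p) out <- filters[[i]](out)
    sort(unique(out$gene_id))
  })
  for (r in results[-1]) expect_identical(r, results[[1]])
})
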