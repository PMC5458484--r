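mk_summary <- function(gene, group, mean_fpkm) {
  tibble::tibble(gene_id = gene, group = group, mean_fpkm = mean_fpkm,
                 n_above = 2L, n_samples = 3L, fraction_above = 2 / 3)
}

mk_marks <- function(gene, group, marks) {
  tibble::tibble(gene_id = gene, group = group, mark = marks,
                 max_enrichment = 5)
}

test_that("call rules separate lncRNA, eRNA and none", {
  rules <- group_call_rules()
  s <- mk_summary("g1", "A", 0.6)
  expect_equal(call_groups(s, mk_marks("g1", "A", "H3K4me3"), rules)$call,
               "lncRNA")
  expect_equal(
    call_groups(s, mk_marks("g1", "A", c("H3K4me1", "H3K27ac")), rules)$call,
    "eRNA"
  )
  # all three marks: the K4me3 rule wins and the eRNA NOT-clause fails
  expect_equal(
    call_groups(s, mk_marks("g1", "A", c("H3K4me1", "H3K27ac", "H3K4me3")),
                rules)$call,
    "lncRNA"
  )
  # below the expression cutoff: no call regardless of marks
  expect_equal(
    call_groups(mk_summary("g1", "A", 0.4),
                mk_marks("g1", "A", c("H3K4me1", "H3K27ac", "H3K4me3")),
                rules)$call,
    "none"
  )
  # exactly at the cutoff: strict >, no call
  expect_equal(
    call_groups(mk_summary("g1", "A", 0.5),
                mk_marks("g1", "A", "H3K4me3"), rules)$call,
    "none"
  )
})

test_that("rules that can hold simultaneously are rejected", {
  expect_error(
    group_call_rules(lncrna_required = "H3K4me3",
                     erna_required = "H3K27ac", erna_forbidden = character()),
    "simultaneously"
  )
  # custom disjoint rules are accepted
  r <- group_call_rules(lncrna_required = "H3K4me3",
                        lncrna_forbidden = "H3K27me3",
                        erna_required = "H3K27me3",
                        erna_forbidden = character())
  expect_s3_class(r, "lnc_call_rules")
})

test_that("lncRNA and eRNA calls are disjoint per (gene, group)", {
  withr::with_seed(88, {
    marks_all <- c("H3K4me3", "H3K4me1", "H3K27ac")
    combos <- expand.grid(rep(list(c(TRUE, FALSE)), 3))
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      g <- paste0("g", i)
      present <- marks_all[unlist(combos[i, ])]
      list(
        summary = mk_summary(g, "A", sample(c(0.2, 0.7, 3), 1)),
        marks = if (length(present)) mk_marks(g, "A", present)
      )
    })
    calls <- call_groups(
      purrr::list_rbind(purrr::map(rows, "summary")),
      purrr::list_rbind(purrr::compact(purrr::map(rows, "marks")))
    )
    expect_true(all(calls$call %in% c("lncRNA", "eRNA", "none")))
    expect_equal(anyDuplicated(calls[c("gene_id", "group")]), 0)
  })
})

test_that("pie matrix is symmetric with self-overlap equal to the diagonal", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3"),
    group = c("A", "A", "B", "B"),
    call = "lncRNA",
    H3K4me3 = TRUE, H3K4me1 = FALSE, H3K27ac = FALSE
  )
  pm <- pie_matrix(calls)
  cell <- function(a, b, cat) {
    x <- pm |> dplyr::filter(group_a == a, group_b == b, category == cat)
    if (nrow(x) == 0) 0L else x$n
  }
  expect_equal(cell("A", "A", "(all)"), 2L)
  expect_equal(cell("B", "B", "(all)"), 2L)
  expect_equal(cell("A", "B", "(all)"), 1L) # g2 in both
  expect_equal(cell("A", "B", "H3K4me3"), cell("B", "A", "H3K4me3"))
  expect_equal(cell("A", "A", "H3K4me3"), 2L) # self-overlap = diagonal

  # disjoint groups
  calls2 <- calls |> dplyr::mutate(gene_id = c("g1", "g2", "g5", "g6"))
  pm2 <- pie_matrix(calls2)
  expect_equal(
    pm2 |> dplyr::filter(group_a == "A", group_b == "B",
                         category == "(all)") |> dplyr::pull(n),
    0L
  )
})

test_that("supervised order concatenates groups by descending mean FPKM", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    group = c("A", "A", "B"),
    call = c("lncRNA", "lncRNA", "eRNA")
  )
  summaries <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    group = c("A", "A", "B"),
    mean_fpkm = c(1, 5, 2)
  )
  ord <- supervised_order(calls, summaries, group_order = c("A", "B"))
  expect_equal(ord$gene_id, c("g2", "g1", "g2"))
  expect_equal(ord$group, c("A", "A", "B"))
  expect_equal(nrow(ord), sum(calls$call != "none"))
  expect_equal(nrow(supervised_order(calls[0, ], summaries)), 0)
})

test_that("DE columns attach per comparison with stable order", {
  records <- tibble::tibble(gene_id = c("g1", "g2"))
  de <- list(
    A_vs_B = tibble::tibble(gene_id = "g1", log2fc = 2, pvalue = 0.01, fdr = 0.05),
    A_vs_C = tibble::tibble(gene_id = "g2", log2fc = -1, pvalue = 0.2, fdr = 0.4)
  )
  out <- attach_de_results(records, de)
  expect_equal(
    names(out),
    c("gene_id", "A_vs_B_log2fc", "A_vs_B_pvalue", "A_vs_B_fdr",
      "A_vs_C_log2fc", "A_vs_C_pvalue", "A_vs_C_fdr")
  )
  expect_equal(out$A_vs_B_log2fc, c(2, NA))
  expect_error(attach_de_results(records, list(x = de[[1]], x = de[[2]])),
               "duplicate")
})

test_that("write_feature_report emits deterministic TSV and HTML twins", {
  records <- tibble::tibble(
    gene_id = c("g1", "g2"),
    locus = c("chr1:0-100(+)", "chr1:200-300(-)"),
    A_mean_fpkm = c(1.23456, 0),
    A_pct_above = c(66.666, 0),
    A_call = c("lncRNA", "none")
  )
  d <- withr::local_tempdir()
  f <- file.path(d, "report.tsv")
  paths <- write_feature_report(records, f)
  expect_true(all(file.exists(paths)))
  lines <- readLines(f)
  expect_match(lines[2], "1.2346", fixed = TRUE) # 4 decimals
  expect_match(lines[2], "66.67", fixed = TRUE)  # percentages at 2 decimals
  first <- tools::md5sum(unname(paths))
  write_feature_report(records, f)
  expect_identical(tools::md5sum(unname(paths)), first)

  # zero lncRNAs: header-only file
  write_feature_report(records[0, ], f)
  expect_equal(length(readLines(f)), 1)
})
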