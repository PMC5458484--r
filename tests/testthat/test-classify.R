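# Class-code assignment: planted examples for every code, precedence, and
# agreement with the brute-force base-level oracle.

ref_two_exon <- function() {
  # reference transcript: exons [0,100) and [200,300) on '+', intron [100,200)
  tx_tbl("r1", list(c(0, 100), c(200, 300)), gid = "rg1")
}

test_that("build_reference_index derives introns from exon gaps", {
  idx <- build_reference_index(ref_two_exon())
  expect_equal(idx$introns$start, 100L)
  expect_equal(idx$introns$end, 200L)
  idx <- build_reference_index(tx_tbl("r1", list(c(0, 100))))
  expect_equal(nrow(idx$introns), 0)
  # two transcripts sharing an intron: both indexed, both retrievable
  ref <- dplyr::bind_rows(
    tx_tbl("r1", list(c(0, 100), c(200, 300))),
    tx_tbl("r2", list(c(50, 100), c(200, 400)))
  )
  idx <- build_reference_index(ref)
  expect_equal(sort(idx$introns$transcript_id), c("r1", "r2"))
})

test_that("intron_chain_equal ignores terminal exon boundaries", {
  a <- tx_tbl("a", list(c(0, 100), c(200, 300)))
  expect_true(intron_chain_equal(a, tx_tbl("b", list(c(0, 100), c(200, 300)))))
  expect_true(intron_chain_equal(a, tx_tbl("b", list(c(50, 100), c(200, 280)))))
  expect_false(intron_chain_equal(
    a, tx_tbl("b", list(c(0, 100), c(150, 180), c(200, 300)))
  ))
  expect_false(intron_chain_equal(a, tx_tbl("b", list(c(0, 100), c(200, 300)),
                                            strand = "-")))
})

test_that("each class code is recovered on constructed geometries", {
  ref <- ref_two_exon()
  idx <- build_reference_index(ref)
  # '=': identical chains
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(10, 100), c(200, 250))), idx)[1], "=")
  # 'j': shares the intron but adds an exon
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(10, 100), c(200, 250), c(260, 280))), idx)[1], "j")
  # 'o': same-strand exonic overlap without a shared intron
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(250, 320))), idx)[1], "o")
  # 'x': exonic overlap on the opposite strand
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(250, 320)), strand = "-"), idx)[1], "x")
  # 'i': single-exon query inside the reference intron, either strand
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(120, 180))), idx)[1], "i")
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(120, 180)), strand = "-"), idx)[1], "i")
  # multi-exon query entirely inside one reference intron is still 'i'
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(110, 130), c(150, 190))), idx)[1], "i")
  # 'u': no reference features on the chromosome
  expect_equal(classify_transfrag(
    tx_tbl("q", list(c(0, 50)), chrom = "chrX"), idx)[1], "u")
  # 'x' via intronic overlap on the opposite strand (no exon contact)
  q <- tx_tbl("q", list(c(105, 110), c(150, 160)), strand = "-")
  expect_equal(classify_transfrag(q, idx)[1], "x")
  # single-exon query vs single-exon same-strand reference with overlap: '='
  idx_se <- build_reference_index(tx_tbl("r", list(c(0, 100))))
  expect_equal(classify_transfrag(tx_tbl("q", list(c(50, 150))), idx_se)[1], "=")
})

test_that("unstranded queries are rejected", {
  idx <- build_reference_index(ref_two_exon())
  expect_error(
    classify_transfrags(tx_tbl("q", list(c(0, 50)), strand = "."), idx),
    "unstranded"
  )
})

test_that("classification is total, deterministic, and matches the oracle", {
  withr::with_seed(101, {
    for (k in 1:30) {
      n_ref <- sample(0:5, 1)
      ref <- if (n_ref == 0) empty_tx() else {
        purrr::map(seq_len(n_ref), function(i) {
          rand_tx(paste0("r", i), max_coord = 200)
        }) |> purrr::list_rbind()
      }
      idx <- build_reference_index(ref)
      queries <- purrr::map(1:5, function(i) {
        rand_tx(paste0("q", i), max_coord = 200)
      })
      batch <- purrr::list_rbind(queries)
      got <- classify_transfrags(batch, idx) |> dplyr::arrange(transcript_id)
      oracle <- vapply(queries, oracle_classify, character(1), ref = ref)
      expect_equal(got$class_code, oracle)
      again <- classify_transfrags(batch, idx) |> dplyr::arrange(transcript_id)
      expect_identical(got, again) # deterministic
    }
  })
})

test_that("adding reference features never demotes a query's code", {
  rank <- c("=" = 1, j = 2, o = 3, x = 4, i = 5, u = 6)
  withr::with_seed(202, {
    ok <- logical(25)
    for (k in seq_along(ok)) {
      ref_full <- purrr::map(1:5, function(i) {
        rand_tx(paste0("r", i), max_coord = 150)
      }) |> purrr::list_rbind()
      keep <- sample(unique(ref_full$transcript_id), 2)
      ref_sub <- ref_full |> dplyr::filter(transcript_id %in% keep)
      batch <- purrr::list_rbind(purrr::map(1:4, function(i) {
        rand_tx(paste0("q", i), max_coord = 150)
      }))
      code_sub <- classify_transfrags(batch, build_reference_index(ref_sub)) |>
        dplyr::arrange(transcript_id)
      code_full <- classify_transfrags(batch, build_reference_index(ref_full)) |>
        dplyr::arrange(transcript_id)
      ok[k] <- all(rank[code_full$class_code] <= rank[code_sub$class_code])
    }
    expect_true(all(ok))
  })
})

test_that("the reported reference match maximises exonic overlap", {
  ref <- dplyr::bind_rows(
    tx_tbl("rA", list(c(0, 10))),
    tx_tbl("rB", list(c(0, 50)))
  )
  idx <- build_reference_index(ref)
  res <- classify_transfrags(tx_tbl("q", list(c(0, 60))), idx)
  expect_equal(res$ref_id, "rB")
})
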