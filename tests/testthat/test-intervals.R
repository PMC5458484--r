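test_that("overlap_length follows half-open, strand-aware semantics", {
  iv <- function(start, end, strand = "+", chrom = "chr1") {
    tibble::tibble(chrom = chrom, start = start, end = end, strand = strand)
  }
  expect_equal(overlap_length(iv(0, 10), iv(5, 20), "same"), 5L)
  expect_equal(overlap_length(iv(0, 10, "+"), iv(5, 20, "-"), "same"), 0L)
  expect_equal(overlap_length(iv(0, 10, "+"), iv(5, 20, "-"), "opposite"), 5L)
  expect_equal(overlap_length(iv(0, 10), iv(10, 20), "ignore"), 0L) # adjacency
  expect_equal(overlap_length(iv(0, 10), iv(5, 20, chrom = "chr2")), 0L)
  # unstranded records are compatible with both strands
  expect_equal(overlap_length(iv(0, 10, "."), iv(5, 20, "-"), "same"), 5L)
  expect_equal(overlap_length(iv(0, 10, "."), iv(5, 20, "-"), "opposite"), 5L)
  expect_error(overlap_length(iv(10, 10), iv(0, 5)), "start < end")
})

test_that("overlap_length is symmetric and matches the per-base oracle", {
  withr::with_seed(42, {
    n <- 500
    rand_iv <- function() {
      tibble::tibble(
        chrom = sample(c("c1", "c2"), n, replace = TRUE),
        start = sample(0:50, n, replace = TRUE),
        strand = sample(c("+", "-", "."), n, replace = TRUE)
      ) |> dplyr::mutate(end = start + sample(1:30, n, replace = TRUE))
    }
    a <- rand_iv()
    b <- rand_iv()
    for (mode in c("ignore", "same", "opposite")) {
      got <- overlap_length(a, b, mode)
      oracle <- vapply(seq_len(n), function(i) {
        as.integer(oracle_overlap(a[i, ], b[i, ], mode))
      }, integer(1))
      expect_identical(got, oracle)
      expect_identical(got, overlap_length(b, a, mode))
    }
  })
})

test_that("merge_to_gene_loci unions exons per gene", {
  tx <- dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 100)), gid = "g1"),
    tx_tbl("t2", list(c(50, 150)), gid = "g1")
  )
  loci <- merge_to_gene_loci(tx)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 0L)
  expect_equal(loci$end, 150L)
  expect_equal(locus_lengths(loci)$length, 150L)

  # identity on a single transcript
  tx <- tx_tbl("t1", list(c(0, 100), c(200, 300)), gid = "g1")
  loci <- merge_to_gene_loci(tx)
  expect_equal(loci$start, c(0L, 200L))
  expect_equal(loci$end, c(100L, 300L))
  expect_equal(locus_lengths(loci)$length, 200L)

  # disjoint transcripts of one gene stay two blocks
  tx <- dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 100)), gid = "g1"),
    tx_tbl("t2", list(c(200, 300)), gid = "g1")
  )
  expect_equal(locus_lengths(merge_to_gene_loci(tx))$length, 200L)
})

test_that("merge_to_gene_loci rejects genes spanning chromosomes or strands", {
  tx <- dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 100)), gid = "g1", chrom = "chr1"),
    tx_tbl("t2", list(c(0, 100)), gid = "g1", chrom = "chr2")
  )
  expect_error(merge_to_gene_loci(tx), "multiple chromosomes")
  tx <- dplyr::bind_rows(
    tx_tbl("t1", list(c(0, 100)), gid = "g1", strand = "+"),
    tx_tbl("t2", list(c(0, 100)), gid = "g1", strand = "-")
  )
  expect_error(merge_to_gene_loci(tx), "strand")
})

test_that("merged unions are disjoint, sorted, and cover the input base set", {
  withr::with_seed(7, {
    ok <- logical(100)
    for (k in seq_along(ok)) {
      n_tx <- sample(1:4, 1)
      tx <- purrr::map(seq_len(n_tx), function(i) {
        rand_tx(paste0("t", i), gid = "g", chroms = "c1", max_coord = 120)
      }) |> purrr::list_rbind()
      tx$strand <- "+"
      loci <- merge_to_gene_loci(tx)
      expected <- oracle_union_blocks(tx$start, tx$end)
      ok[k] <- identical(loci$start, expected$start) &&
        identical(loci$end, expected$end) &&
        all(diff(loci$start) > 0) &&
        all(loci$start[-1] > loci$end[-nrow(loci)])
    }
    expect_true(all(ok))
  })
})

test_that("tss_region places and clamps the extended TSS window", {
  tx <- tx_tbl("t1", list(c(10000, 11000)))
  r <- tss_region(tx, 1500)
  expect_equal(r$start, 8500L)
  expect_equal(r$end, 11501L)
  expect_equal(r$end - r$start, 2L * 1500L + 1L)

  # minus strand: TSS is the rightmost base (half-open end - 1)
  tx <- tx_tbl("t1", list(c(3000, 4000), c(4500, 5000)), strand = "-")
  r <- tss_region(tx, 1500)
  expect_equal(r$tss, 4999L)
  expect_equal(r$start, 3499L)
  expect_equal(r$end, 6500L)

  # clamping at the chromosome start
  tx <- tx_tbl("t1", list(c(100, 500)))
  r <- tss_region(tx, 1500)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 1601L)

  expect_error(tss_region(tx_tbl("t1", list(c(0, 10)), strand = ".")),
               "unstranded")
})

test_that("tss_region length equals 2*flank+1 except when clamped", {
  withr::with_seed(11, {
    ok <- logical(500)
    for (k in seq_along(ok)) {
      strand <- sample(c("+", "-"), 1)
      start <- sample(0:5000, 1)
      tx <- tx_tbl("t1", list(c(start, start + sample(1:500, 1))), strand = strand)
      flank <- sample(0:2000, 1)
      r <- tss_region(tx, flank)
      tss <- if (strand == "+") tx$start else tx$end - 1L
      ok[k] <- r$tss == tss && if (tss - flank >= 0) {
        (r$end - r$start) == 2L * flank + 1L
      } else {
        r$start == 0L && r$end == tss + flank + 1L
      }
    }
    expect_true(all(ok))
  })
})
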