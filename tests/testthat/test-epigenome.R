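mk_loci <- function(start, end, strand = "+", gid = "g1", chrom = "chr1") {
  merge_to_gene_loci(tx_tbl("t", list(c(start, end)), strand = strand,
                            gid = gid, chrom = chrom))
}

test_that("assign_marks overlaps peaks with the extended TSS region", {
  loci <- mk_loci(10000, 11000) # TSS 10000, region [8500, 11501)
  pk <- function(start, end, score, mark = "H3K4me3", group = "A") {
    tibble::tibble(group = group, mark = mark, chrom = "chr1",
                   start = start, end = end, score = score)
  }
  res <- assign_marks(loci, pk(11000, 12000, 6))
  expect_equal(res$max_enrichment, 6)
  # fold cutoff removes the peak
  expect_equal(nrow(assign_marks(loci, pk(11000, 12000, 6), min_fold = 7)), 0)
  # half-open adjacency: a peak starting at the region end does not overlap
  expect_equal(nrow(assign_marks(loci, pk(11501, 12000, 6))), 0)
  # maximum enrichment across several overlapping peaks
  res <- assign_marks(loci, dplyr::bind_rows(pk(9000, 9100, 3), pk(9200, 9300, 8)))
  expect_equal(res$max_enrichment, 8)
  # peaks are unstranded: a minus-strand locus is still matched
  res <- assign_marks(mk_loci(10000, 11000, strand = "-"), pk(10500, 11200, 4))
  expect_equal(res$max_enrichment, 4)
  expect_error(assign_marks(loci, pk(0, 10, -1)), "non-negative")
})

test_that("raising min_fold never adds assignments", {
  withr::with_seed(66, {
    loci <- merge_to_gene_loci(purrr::map(1:10, function(i) {
      s <- i * 20000
      tx_tbl(paste0("t", i), list(c(s, s + 500)), gid = paste0("g", i))
    }) |> purrr::list_rbind())
    peaks <- tibble::tibble(
      group = "A", mark = "H3K4me3", chrom = "chr1",
      start = as.integer(runif(60, 0, 220000))
    ) |>
      dplyr::mutate(end = start + 1000L, score = runif(60, 0, 10))
    prev <- NULL
    for (mf in c(0, 2, 5, 8, 11)) {
      res <- assign_marks(loci, peaks, min_fold = mf)
      key <- paste(res$gene_id, res$group, res$mark)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  })
})

test_that("annotate_segments emits one record per overlapping segment", {
  loci <- mk_loci(100, 500)
  segs <- list(CNV = tibble::tibble(
    chrom = "chr1", start = c(0L, 400L, 600L), end = c(1000L, 450L, 700L),
    score = c(2, -1, 5)
  ))
  res <- annotate_segments(loci, segs)
  expect_equal(nrow(res), 2) # third segment is disjoint
  expect_setequal(res$score, c(2, -1))
  expect_equal(nrow(annotate_segments(loci, list())), 0)
})

test_that("annotate_hic composes anchor, cis and TAD constraints", {
  lnc <- mk_loci(1000, 2000, gid = "L")
  mrna <- mk_loci(50000, 51000, gid = "M")
  tads <- tibble::tibble(chrom = "chr1", start = 0L, end = 60000L)
  pair <- tibble::tibble(
    chrom1 = "chr1", start1 = 900L, end1 = 2100L,
    chrom2 = "chr1", start2 = 49900L, end2 = 51100L, score = 7, cis = TRUE
  )
  res <- annotate_hic(lnc, mrna, pair, tads)
  expect_equal(res$gene_id, "L")
  expect_equal(res$partner, "M")
  expect_equal(res$score, 7)

  # partners in different TADs are not reported
  tads2 <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                          end = c(10000L, 60000L))
  expect_equal(nrow(annotate_hic(lnc, mrna, pair, tads2)), 0)

  # trans pairs are never reported
  pair_trans <- pair |> dplyr::mutate(chrom2 = "chr2")
  expect_equal(nrow(annotate_hic(lnc, mrna, pair_trans, tads)), 0)

  # without TADs the constraint is skipped and flagged
  res <- annotate_hic(lnc, mrna, pair, NULL)
  expect_equal(res$partner, "M")
  expect_false(attr(res, "tad_constrained"))

  # anchors may hit the partners in either order
  pair_rev <- tibble::tibble(
    chrom1 = "chr1", start1 = 49900L, end1 = 51100L,
    chrom2 = "chr1", start2 = 900L, end2 = 2100L, score = 3, cis = TRUE
  )
  expect_equal(annotate_hic(lnc, mrna, pair_rev, tads)$partner, "M")
})

test_that("annotate_hic agrees with a brute-force triple loop", {
  withr::with_seed(77, {
    for (k in 1:20) {
      lnc <- merge_to_gene_loci(purrr::map(1:4, function(i) {
        s <- sample(0:80000, 1)
        tx_tbl(paste0("lt", i), list(c(s, s + 2000)), gid = paste0("L", i))
      }) |> purrr::list_rbind())
      mrna <- merge_to_gene_loci(purrr::map(1:4, function(i) {
        s <- sample(0:80000, 1)
        tx_tbl(paste0("mt", i), list(c(s, s + 3000)), gid = paste0("M", i))
      }) |> purrr::list_rbind())
      tads <- tibble::tibble(chrom = "chr1", start = c(0L, 30000L, 60000L),
                             end = c(30000L, 60000L, 100000L))
      pairs <- tibble::tibble(
        chrom1 = "chr1", start1 = sample(0:80000, 5)
      ) |>
        dplyr::mutate(
          end1 = start1 + 4000L, chrom2 = "chr1",
          start2 = sample(0:80000, 5), end2 = start2 + 4000L,
          score = round(runif(5, 1, 30), 1)
        )
      got <- annotate_hic(lnc, mrna, pairs, tads)
      lspan <- locus_spans(lnc)
      mspan <- locus_spans(mrna)
      expected <- list()
      for (i in seq_len(nrow(lspan))) {
        for (j in seq_len(nrow(mspan))) {
          l_tads <- which(tads$start < lspan$end[i] & tads$end > lspan$start[i])
          m_tads <- which(tads$start < mspan$end[j] & tads$end > mspan$start[j])
          if (length(intersect(l_tads, m_tads)) == 0) next
          for (p in seq_len(nrow(pairs))) {
            hit1 <- pairs$start1[p] < lspan$end[i] & pairs$end1[p] > lspan$start[i]
            hit2 <- pairs$start2[p] < mspan$end[j] & pairs$end2[p] > mspan$start[j]
            hit1r <- pairs$start1[p] < mspan$end[j] & pairs$end1[p] > mspan$start[j]
            hit2r <- pairs$start2[p] < lspan$end[i] & pairs$end2[p] > lspan$start[i]
            if ((hit1 && hit2) || (hit1r && hit2r)) {
              expected[[length(expected) + 1]] <-
                paste(lspan$gene_id[i], mspan$gene_id[j])
            }
          }
        }
      }
      exp_vec <- unique(unlist(expected)) %||% character()
      expect_identical(sort(unique(paste(got$gene_id, got$partner))),
                       sort(exp_vec))
    }
  })
})
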