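# Strand-aware interval algebra on tidy interval tibbles.
#
# All coordinates in this package are 0-based half-open ([start, end)).
# GTF input/output is converted at the boundary (GTF is 1-based closed);
# BED-family formats are already 0-based half-open and pass through.

.check_intervals <- function(x, what = "interval") {
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom)) || any(is.na(x$chrom))) {
    abort(sprintf("%s: chrom must be non-empty", what))
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$end <= x$start)
  if (length(bad)) {
    abort(sprintf(
      "%s: invalid coordinates (need 0 <= start < end) at row %d [%s:%s-%s]",
      what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

# tibble (chrom,start,end[,strand]) -> GRanges; '.' and NA strand become '*'
.as_granges <- function(x) {
  s <- if ("strand" %in% names(x)) {
    ifelse(is.na(x$strand) | !(x$strand %in% c("+", "-")), "*", x$strand)
  } else {
    rep("*", nrow(x))
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = s
  )
}

# Overlap join between two interval tibbles.  Returns tibble(q, s, overlap_bp)
# of row indices into `query` and `subject`.  Unstranded ('.') records match
# both strands under "same" and "opposite" modes.  Small problems take a
# vectorized all-pairs path; larger ones go through GenomicRanges.
overlap_hits <- function(query, subject,
                         strand_mode = c("ignore", "same", "opposite"),
                         type = "any") {
  strand_mode <- match.arg(strand_mode)
  nq <- nrow(query)
  ns <- nrow(subject)
  if (nq == 0 || ns == 0) {
    return(tibble(q = integer(), s = integer(), overlap_bp = integer()))
  }
  if (as.double(nq) * ns <= 5e4 && type %in% c("any", "within")) {
    q <- rep(seq_len(nq), times = ns)
    s <- rep(seq_len(ns), each = nq)
    keep <- query$chrom[q] == subject$chrom[s]
    if (strand_mode != "ignore") {
      sq <- if ("strand" %in% names(query)) query$strand[q] else rep(".", length(q))
      ss <- if ("strand" %in% names(subject)) subject$strand[s] else rep(".", length(s))
      stranded <- sq %in% c("+", "-") & ss %in% c("+", "-")
      keep <- keep & (!stranded |
                        (if (strand_mode == "same") sq == ss else sq != ss))
    }
    if (type == "within") {
      keep <- keep & query$start[q] >= subject$start[s] &
        query$end[q] <= subject$end[s]
    }
    ov <- pmax(0L, pmin(query$end[q], subject$end[s]) -
                 pmax(query$start[q], subject$start[s]))
    keep <- keep & (ov > 0L | (type == "within" & ov >= 0L))
    return(tibble(q = q[keep], s = s[keep],
                  overlap_bp = as.integer(ov[keep])))
  }
  gq <- .as_granges(query)
  gs <- .as_granges(subject)
  if (strand_mode == "opposite") gs <- BiocGenerics::invertStrand(gs)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    gq, gs,
    type = type, ignore.strand = (strand_mode == "ignore")
  ))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmax(
    0L,
    pmin(query$end[q], subject$end[s]) - pmax(query$start[q], subject$start[s])
  )
  tibble(q = q, s = s, overlap_bp = as.integer(ov))
}

#' Length of the overlap between two genomic intervals
#'
#' Computes the number of shared bases between paired intervals under a
#' strand-compatibility mode.  Intervals are 0-based half-open, so touching
#' intervals ([0,10) and [10,20)) do not overlap.  Unstranded (`"."`) records
#' are compatible with both strands under `"same"` and `"opposite"` modes.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` and optionally
#'   `strand`. Rows are paired; the shorter of the two is recycled if it has
#'   one row.
#' @param strand_mode `"ignore"` (default), `"same"` or `"opposite"`.
#' @return Integer vector of overlap lengths in bases (0 when chromosomes
#'   differ or the strand mode is unsatisfied).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10, strand = "+")
#' b <- tibble::tibble(chrom = "chr1", start = 5, end = 20, strand = "+")
#' overlap_length(a, b, "same")
#' @export
overlap_length <- function(a, b, strand_mode = c("ignore", "same", "opposite")) {
  strand_mode <- match.arg(strand_mode)
  a <- as_tibble(a)
  b <- as_tibble(b)
  .check_intervals(a, "overlap_length(a)")
  .check_intervals(b, "overlap_length(b)")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  if (nrow(a) != nrow(b)) abort("overlap_length: a and b must have matching rows")
  if (n == 0) return(integer())
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0L
  sa <- if ("strand" %in% names(a)) a$strand else rep(".", n)
  sb <- if ("strand" %in% names(b)) b$strand else rep(".", n)
  unstranded <- sa == "." | sb == "." | is.na(sa) | is.na(sb)
  if (strand_mode == "same") {
    ov[!unstranded & sa != sb] <- 0L
  } else if (strand_mode == "opposite") {
    ov[!unstranded & sa == sb] <- 0L
  }
  as.integer(ov)
}

#' Merge transcripts into gene loci (exon unions)
#'
#' Collapses a transcript set to one locus per `gene_id`, taking the interval
#' union of all member exons.  The union blocks are disjoint and sorted; the
#' spliced length of a locus is the sum of its block lengths.  Transcripts
#' sharing a `gene_id` but disagreeing on chromosome or strand are rejected:
#' a well-formed merger output never contains them.
#'
#' @param transcripts Exon-level transcript tibble (one row per exon) with
#'   columns `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @return A locus tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (one row per union block) plus a `member_transcripts` attribute
#'   mapping gene ids to member transcript ids.
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = c("t1", "t2"), gene_id = "g1",
#'   chrom = "chr1", strand = "+", start = c(0, 50), end = c(100, 150)
#' )
#' merge_to_gene_loci(tx)
#' @export
merge_to_gene_loci <- function(transcripts) {
  tx <- as_tibble(transcripts)
  if (nrow(tx) == 0) {
    out <- tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer()
    )
    attr(out, "member_transcripts") <- tibble(
      gene_id = character(), transcript_id = character()
    )
    return(out)
  }
  .check_intervals(tx, "merge_to_gene_loci")
  consistency <- tx |>
    group_by(gene_id) |>
    summarise(
      n_chrom = n_distinct(chrom), n_strand = n_distinct(strand),
      .groups = "drop"
    )
  bad <- consistency |> filter(n_chrom > 1 | n_strand > 1)
  if (nrow(bad)) {
    abort(sprintf(
      "merge_to_gene_loci: gene '%s' has transcripts on multiple chromosomes or strands",
      bad$gene_id[1]
    ))
  }
  gr <- .as_granges(tx)
  red <- IRanges::reduce(S4Vectors::split(gr, tx$gene_id))
  flat <- BiocGenerics::unlist(red)
  info <- tx |> distinct(gene_id, chrom, strand)
  out <- tibble(
    gene_id = names(flat),
    start = BiocGenerics::start(flat) - 1L,
    end = BiocGenerics::end(flat)
  ) |>
    left_join(info, by = "gene_id") |>
    select(gene_id, chrom, strand, start, end) |>
    arrange(gene_id, start)
  attr(out, "member_transcripts") <-
    tx |> distinct(gene_id, transcript_id) |> arrange(gene_id, transcript_id)
  out
}

#' Spliced length of each gene locus
#'
#' @param loci Locus tibble from [merge_to_gene_loci()].
#' @return Tibble with `gene_id` and `length` (sum of exon-union block
#'   lengths, in nt).
#' @export
locus_lengths <- function(loci) {
  loci |>
    group_by(gene_id) |>
    summarise(length = sum(end - start), .groups = "drop")
}

#' Genomic span of each gene locus
#'
#' @param loci Locus tibble from [merge_to_gene_loci()].
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start` (leftmost base), `end` (rightmost end), `n_blocks`.
#' @export
locus_spans <- function(loci) {
  loci <- as_tibble(loci)
  if (nrow(loci) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), n_blocks = integer()
    ))
  }
  loci |>
    group_by(gene_id) |>
    summarise(
      chrom = first(chrom), strand = first(strand),
      start = min(start), end = max(end), n_blocks = n(),
      .groups = "drop"
    )
}

#' Extended transcription start site region
#'
#' The TSS is the strand-dependent first transcribed base (leftmost base on
#' `+`, rightmost on `-`).  The region extends `flank` bases upstream and
#' downstream and includes the TSS base itself, covering `2 * flank + 1`
#' bases unless clamped at the chromosome start.
#'
#' @param x Exon-level tibble (transcripts or gene loci).  Features are
#'   grouped by `transcript_id` if present, else by `gene_id`.
#' @param flank Extension in bases on each side (default 1500).
#' @return Tibble with the grouping id column, `chrom`, `strand`, `tss` (the
#'   TSS base), `start`, `end` of the extended region.
#' @examples
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   strand = "+", start = 10000, end = 11000
#' )
#' tss_region(tx, flank = 1500)
#' @export
tss_region <- function(x, flank = 1500) {
  if (flank < 0) abort("tss_region: flank must be >= 0")
  x <- as_tibble(x)
  id_col <- if ("transcript_id" %in% names(x)) "transcript_id" else "gene_id"
  if (!id_col %in% names(x)) abort("tss_region: need a transcript_id or gene_id column")
  if (nrow(x) == 0) {
    return(tibble(
      !!id_col := character(), chrom = character(), strand = character(),
      tss = integer(), start = integer(), end = integer()
    ))
  }
  bad <- x |> filter(!strand %in% c("+", "-"))
  if (nrow(bad)) {
    abort(sprintf(
      "tss_region: '%s' is unstranded; a TSS requires strand + or -",
      bad[[id_col]][1]
    ))
  }
  x |>
    group_by(.data[[id_col]]) |>
    summarise(
      chrom = first(chrom), strand = first(strand),
      tss = if_else(first(strand) == "+", min(start), max(end) - 1L),
      .groups = "drop"
    ) |>
    mutate(
      start = pmax(0L, as.integer(tss - flank)),
      end = as.integer(tss + flank + 1L)
    )
}
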