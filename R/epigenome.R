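# Integration of histone-mark peaks at extended TSS regions, generic BED4
# segment annotation, and TAD-constrained Hi-C lncRNA-mRNA interaction
# annotation.

#' Assign histone-mark peaks to extended TSS regions
#'
#' For each locus, the TSS is extended by `flank` bases on both sides; a
#' mark is assigned in a group iff some peak of that (group, mark) with
#' score at least `min_fold` overlaps the extended region by >= 1 base
#' (peaks are unstranded and match regardless of locus strand).  The
#' maximum enrichment among qualifying overlapping peaks is reported.
#'
#' @param loci Locus tibble (stranded).
#' @param peaks Tibble of peaks with columns `group`, `mark`, `chrom`,
#'   `start`, `end`, `score`.
#' @param flank TSS extension in bases (default 1500).
#' @param min_fold Fold-enrichment cutoff; peaks below it are ignored
#'   (default 0).
#' @return Tibble with columns `gene_id`, `group`, `mark`,
#'   `max_enrichment`, one row per assigned (gene, group, mark).
#' @export
assign_marks <- function(loci, peaks, flank = 1500, min_fold = 0) {
  loci <- as_tibble(loci)
  peaks <- as_tibble(peaks)
  empty <- tibble(
    gene_id = character(), group = character(), mark = character(),
    max_enrichment = double()
  )
  if (nrow(loci) == 0 || nrow(peaks) == 0) return(empty)
  if (!all(c("group", "mark", "chrom", "start", "end", "score") %in% names(peaks))) {
    abort("assign_marks: peaks need columns group, mark, chrom, start, end, score")
  }
  if (any(peaks$score < 0)) {
    abort("assign_marks: peak enrichment scores must be non-negative")
  }
  peaks <- peaks |> filter(score >= min_fold)
  if (nrow(peaks) == 0) return(empty)
  regions <- tss_region(loci, flank = flank)
  hits <- overlap_hits(regions, peaks, "ignore")
  if (nrow(hits) == 0) return(empty)
  tibble(
    gene_id = regions$gene_id[hits$q],
    group = peaks$group[hits$s],
    mark = peaks$mark[hits$s],
    score = peaks$score[hits$s]
  ) |>
    group_by(gene_id, group, mark) |>
    summarise(max_enrichment = max(score), .groups = "drop")
}

#' Annotate loci with overlapping segmented data
#'
#' Generic BED4 segment integration (copy-number segments, SNP density
#' tracks, ...): one record is emitted per >= 1-base overlap between a
#' locus genomic span and a segment, carrying the segment's score.
#'
#' @param loci Locus tibble.
#' @param segments Named list of BED4 tibbles (`chrom`, `start`, `end`,
#'   `score`).
#' @return Tibble with columns `gene_id`, `source`, `chrom`, `start`,
#'   `end`, `score` (segment coordinates).
#' @export
annotate_segments <- function(loci, segments = list()) {
  loci <- as_tibble(loci)
  empty <- tibble(
    gene_id = character(), source = character(), chrom = character(),
    start = integer(), end = integer(), score = double()
  )
  if (nrow(loci) == 0 || length(segments) == 0) return(empty)
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    abort("annotate_segments: segments must be named")
  }
  spans <- locus_spans(loci)
  imap(segments, function(seg, nm) {
    seg <- as_tibble(seg)
    hits <- overlap_hits(spans, seg, "ignore")
    tibble(
      gene_id = spans$gene_id[hits$q],
      source = nm,
      chrom = seg$chrom[hits$s],
      start = seg$start[hits$s],
      end = seg$end[hits$s],
      score = seg$score[hits$s]
    )
  }) |>
    list_rbind() |>
    arrange(gene_id, source, chrom, start)
}

#' Annotate lncRNA-mRNA interactions in cis within TADs
#'
#' A (lncRNA, mRNA) pair is reported iff some interaction pair has one
#' anchor overlapping the lncRNA's genomic span and the other overlapping
#' the mRNA's span, the two anchors are on the same chromosome (cis), and
#' both genes overlap (>= 1 base) a common TAD interval.  Anchors match
#' locus spans, not exons, since interaction bins are coarse.  When `tads`
#' is `NULL` the TAD constraint is skipped and the result carries attribute
#' `tad_constrained = FALSE`.
#'
#' @param lnc_loci Putative lncRNA locus tibble.
#' @param mrna_loci Protein-coding (mRNA) locus tibble.
#' @param pairs Interaction tibble from [read_hic_pairs()].
#' @param tads Optional TAD tibble (`chrom`, `start`, `end`).
#' @return Tibble with columns `gene_id` (lncRNA), `partner` (mRNA),
#'   `score` (maximum supporting interaction score), `n_pairs`.
#' @export
annotate_hic <- function(lnc_loci, mrna_loci, pairs, tads = NULL) {
  empty <- tibble(
    gene_id = character(), partner = character(), score = double(),
    n_pairs = integer()
  )
  lnc <- locus_spans(as_tibble(lnc_loci))
  mrna <- locus_spans(as_tibble(mrna_loci))
  pairs <- as_tibble(pairs)
  tad_constrained <- !is.null(tads)
  out <- empty
  if (nrow(lnc) && nrow(mrna) && nrow(pairs)) {
    pairs <- pairs |> filter(chrom1 == chrom2) |> mutate(pair_id = row_number())
    a1 <- pairs |> transmute(pair_id, chrom = chrom1, start = start1, end = end1)
    a2 <- pairs |> transmute(pair_id, chrom = chrom2, start = start2, end = end2)
    match_anchor <- function(anchor, spans, id_name) {
      hits <- overlap_hits(anchor, spans, "ignore")
      tibble(
        pair_id = anchor$pair_id[hits$q],
        !!id_name := spans$gene_id[hits$s]
      )
    }
    # either anchor may hit either partner
    links <- bind_rows(
      inner_join(match_anchor(a1, lnc, "gene_id"),
                 match_anchor(a2, mrna, "partner"),
                 by = "pair_id", relationship = "many-to-many"),
      inner_join(match_anchor(a2, lnc, "gene_id"),
                 match_anchor(a1, mrna, "partner"),
                 by = "pair_id", relationship = "many-to-many")
    ) |> distinct()
    if (nrow(links) && tad_constrained) {
      tads <- as_tibble(tads)
      tad_of <- function(spans) {
        hits <- overlap_hits(spans, tads, "ignore")
        tibble(gene = spans$gene_id[hits$q], tad = hits$s)
      }
      lnc_tads <- tad_of(lnc)
      mrna_tads <- tad_of(mrna)
      shared <- inner_join(
        lnc_tads |> rename(gene_id = gene),
        mrna_tads |> rename(partner = gene),
        by = "tad", relationship = "many-to-many"
      ) |> distinct(gene_id, partner)
      links <- links |> semi_join(shared, by = c("gene_id", "partner"))
    }
    if (nrow(links)) {
      out <- links |>
        left_join(pairs |> select(pair_id, score), by = "pair_id") |>
        group_by(gene_id, partner) |>
        summarise(score = max(score), n_pairs = n_distinct(pair_id),
                  .groups = "drop") |>
        arrange(gene_id, partner)
    }
  }
  attr(out, "tad_constrained") <- tad_constrained
  out
}
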