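# Transcript-set helpers.  A transcript set is a tidy exon table: one row
# per exon with columns transcript_id, gene_id, chrom, strand, start, end
# (0-based half-open), optionally biotype.

#' Validate an exon-level transcript tibble
#'
#' Checks the structural invariants of a transcript set: valid coordinates,
#' one chromosome and strand per transcript, exons sorted with at least a
#' one-base gap between consecutive exons.
#'
#' @param tx Exon-level transcript tibble.
#' @return `tx` invisibly; aborts with an informative message on violation.
#' @export
validate_transcripts <- function(tx) {
  tx <- as_tibble(tx)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, names(tx))
  if (length(missing)) {
    abort(sprintf("transcripts: missing columns %s", paste(missing, collapse = ", ")))
  }
  if (nrow(tx) == 0) return(invisible(tx))
  .check_intervals(tx, "transcripts")
  chk <- tx |>
    group_by(transcript_id) |>
    summarise(
      n_chrom = n_distinct(chrom), n_strand = n_distinct(strand),
      .groups = "drop"
    )
  bad <- chk |> filter(n_chrom > 1)
  if (nrow(bad)) {
    abort(sprintf(
      "transcript '%s' has exons on multiple chromosomes", bad$transcript_id[1]
    ))
  }
  bad <- chk |> filter(n_strand > 1)
  if (nrow(bad)) {
    abort(sprintf(
      "transcript '%s' has exons on multiple strands", bad$transcript_id[1]
    ))
  }
  gaps <- tx |>
    arrange(transcript_id, start) |>
    group_by(transcript_id) |>
    summarise(
      ok = n() == 1 || all(start[-1] > end[-n()]),
      .groups = "drop"
    )
  bad <- gaps |> filter(!ok)
  if (nrow(bad)) {
    abort(sprintf(
      "transcript '%s' has overlapping or touching exons (need a gap of >= 1 base)",
      bad$transcript_id[1]
    ))
  }
  invisible(tx)
}

#' Introns of each transcript
#'
#' Introns are the gaps between consecutive exons of a transcript;
#' single-exon transcripts contribute none.
#'
#' @param tx Exon-level transcript tibble.
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_rank` (0-based half-open intron coordinates).
#' @export
transcript_introns <- function(tx) {
  tx <- as_tibble(tx)
  if (nrow(tx) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      intron_rank = integer()
    ))
  }
  tx |>
    arrange(transcript_id, start) |>
    group_by(transcript_id) |>
    mutate(
      intron_start = end,
      intron_end = lead(start),
      intron_rank = row_number()
    ) |>
    ungroup() |>
    filter(!is.na(intron_end)) |>
    transmute(
      transcript_id, gene_id, chrom, strand,
      start = intron_start, end = intron_end, intron_rank
    )
}

#' Genomic span and exon count of each transcript
#'
#' @param tx Exon-level transcript tibble.
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `n_exons`, `spliced_length`.
#' @export
transcript_spans <- function(tx) {
  tx <- as_tibble(tx)
  if (nrow(tx) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      n_exons = integer(), spliced_length = integer()
    ))
  }
  tx |>
    group_by(transcript_id) |>
    summarise(
      gene_id = first(gene_id), chrom = first(chrom), strand = first(strand),
      start = min(start), end = max(end), n_exons = n(),
      spliced_length = sum(end - start),
      .groups = "drop"
    )
}

# Canonical string key of a transcript's intron chain: chrom/strand plus the
# ordered intron coordinates.  NA for single-exon transcripts.
.chain_keys <- function(tx) {
  introns <- transcript_introns(tx)
  spans <- transcript_spans(tx)
  if (nrow(spans) == 0) {
    return(tibble(transcript_id = character(), key = character()))
  }
  keys <- introns |>
    arrange(transcript_id, start) |>
    group_by(transcript_id) |>
    summarise(
      key = paste0(
        first(chrom), first(strand), ":",
        paste(start, end, sep = "-", collapse = ",")
      ),
      .groups = "drop"
    )
  spans |>
    select(transcript_id, n_exons) |>
    left_join(keys, by = "transcript_id") |>
    mutate(key = if_else(n_exons > 1, key, NA_character_)) |>
    select(transcript_id, key)
}

#' Are two transcripts' intron chains identical?
#'
#' True iff the two transcripts lie on the same chromosome and strand and
#' have identical ordered intron lists; terminal exon boundaries may differ.
#' Two single-exon transcripts on the same chromosome and strand compare
#' equal (both chains are empty); callers that need overlap-based matching
#' of single-exon transcripts (as the class-code assignment does) must test
#' that separately.
#'
#' @param a,b Exon-level tibbles each describing a single transcript.
#' @return Logical scalar.
#' @export
intron_chain_equal <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  if (n_distinct(a$transcript_id) != 1 || n_distinct(b$transcript_id) != 1) {
    abort("intron_chain_equal: each argument must contain exactly one transcript")
  }
  if (!all(c(a$strand, b$strand) %in% c("+", "-"))) {
    abort("intron_chain_equal: both transcripts must be stranded")
  }
  if (a$chrom[1] != b$chrom[1] || a$strand[1] != b$strand[1]) return(FALSE)
  ia <- transcript_introns(a) |> arrange(start)
  ib <- transcript_introns(b) |> arrange(start)
  nrow(ia) == nrow(ib) &&
    all(ia$start == ib$start) && all(ia$end == ib$end)
}
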