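# Longest open reading frame on spliced transcript sequences, and the
# coding-probability gate.  The coding probabilities themselves are an
# external input (e.g. CPAT output); only the putative ORF size is computed
# natively.

#' Spliced sequence of gene loci
#'
#' Concatenates the exon-union blocks of each locus in genomic order and
#' reverse-complements the result for minus-strand loci, yielding the
#' oriented spliced transcript sequence.
#'
#' @param loci Locus tibble from [merge_to_gene_loci()].
#' @param genome A named `Biostrings::DNAStringSet` or named character
#'   vector of chromosome sequences.
#' @return Named character vector mapping `gene_id` to its spliced sequence.
#' @export
spliced_sequence <- function(loci, genome) {
  loci <- as_tibble(loci)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) abort("spliced_sequence: genome sequences must be named")
  if (nrow(loci) == 0) return(setNames(character(), character()))
  missing <- setdiff(unique(loci$chrom), names(genome))
  if (length(missing)) {
    abort(sprintf("spliced_sequence: chromosome '%s' not in genome", missing[1]))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  beyond <- loci |> filter(end > lens[chrom])
  if (nrow(beyond)) {
    abort(sprintf(
      "spliced_sequence: block %s:%d-%d of gene '%s' extends beyond the chromosome end",
      beyond$chrom[1], beyond$start[1], beyond$end[1], beyond$gene_id[1]
    ))
  }
  blocks <- loci |> arrange(gene_id, start)
  seqs <- as.character(Biostrings::subseq(
    genome[blocks$chrom], start = blocks$start + 1L, end = blocks$end
  ))
  joined <- tibble(
    gene_id = blocks$gene_id, strand = blocks$strand, seq = unname(seqs)
  ) |>
    group_by(gene_id) |>
    summarise(
      strand = first(strand), seq = paste(seq, collapse = ""),
      .groups = "drop"
    )
  minus <- joined$strand == "-"
  if (any(minus)) {
    joined$seq[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(joined$seq[minus]))
    )
  }
  setNames(joined$seq, joined$gene_id)
}

#' Length of the longest open reading frame
#'
#' Scans the three forward frames of each (already oriented) sequence for
#' ATG...stop spans (stop codons TAA, TAG, TGA) and returns the longest in
#' nucleotides, stop codon included; 0 if the sequence contains no complete
#' ORF.  ORFs lacking an in-sequence stop codon are ignored.
#'
#' @param seq Character vector of nucleotide sequences (ACGTN alphabet).
#' @return Integer vector of ORF lengths (always divisible by 3 when > 0).
#' @examples
#' longest_orf("ATGAAATAA") # 9
#' @export
longest_orf <- function(seq) {
  vapply(toupper(seq), .longest_orf_one, integer(1), USE.NAMES = FALSE)
}

.longest_orf_one <- function(s) {
  n <- nchar(s)
  if (n < 6L) return(0L)
  codon_at <- function(pos) substring(s, pos, pos + 2L)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- codon_at(starts)
    atg <- which(codons == "ATG")
    stop_ <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0 || length(stop_) == 0) next
    # first stop at or after each ATG (strictly after the start codon)
    nxt <- stop_[findInterval(atg, stop_) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len <- (nxt[ok] - atg[ok] + 1L) * 3L
    best <- max(best, max(len))
  }
  best
}

#' Gate putative lncRNA loci on coding probability
#'
#' Loci whose externally supplied coding probability reaches the cutoff are
#' excluded as likely protein-coding (`>= cutoff` excluded; the 0.364
#' default is the published optimum human cutoff of the CPAT model).  Genes
#' without a supplied probability are retained with a flag and a warning:
#' the gate is skipped for them.
#'
#' @param loci Locus tibble.
#' @param probabilities Tibble with `gene_id` and `coding_prob` in `[0, 1]`.
#' @param cutoff Exclusion boundary (default 0.364).
#' @return List with `retained` loci, `ledger` row (gene unit), `excluded`
#'   gene ids and `flags` (per-gene probability and `missing_prob` flag).
#' @export
apply_coding_gate <- function(loci, probabilities = NULL, cutoff = 0.364) {
  loci <- as_tibble(loci)
  genes <- distinct(loci, gene_id)
  n_in <- nrow(genes)
  if (is.null(probabilities) || nrow(as_tibble(probabilities)) == 0) {
    flags <- genes |> mutate(coding_prob = NA_real_, missing_prob = TRUE)
    if (n_in > 0) warn("apply_coding_gate: no coding probabilities supplied; gate skipped")
    return(list(
      retained = loci,
      ledger = .ledger_row("coding_potential_gate", "gene", n_in, n_in, 0L),
      excluded = character(),
      flags = flags
    ))
  }
  probabilities <- as_tibble(probabilities)
  if (any(probabilities$coding_prob < 0 | probabilities$coding_prob > 1, na.rm = TRUE)) {
    abort("apply_coding_gate: coding probabilities must lie in [0, 1]")
  }
  flags <- genes |>
    left_join(probabilities |> distinct(gene_id, .keep_all = TRUE),
              by = "gene_id") |>
    mutate(missing_prob = is.na(coding_prob))
  if (any(flags$missing_prob)) {
    warn(sprintf(
      "apply_coding_gate: %d gene(s) lack a coding probability; gate skipped for them",
      sum(flags$missing_prob)
    ))
  }
  excluded <- flags$gene_id[!flags$missing_prob & flags$coding_prob >= cutoff]
  retained <- loci |> filter(!gene_id %in% excluded)
  list(
    retained = retained,
    ledger = .ledger_row("coding_potential_gate", "gene", n_in,
                         n_in - length(excluded), length(excluded)),
    excluded = excluded,
    flags = flags
  )
}
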