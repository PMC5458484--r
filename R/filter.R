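# Phase-I filtration cascade: class-code filter, annotated-lncRNA add-back,
# gene-level merge, protein-coding extended-TSS exclusion, small-RNA
# exclusion, minimum spliced length, known-annotation overlap labels.
# Every step contributes one row to the filtration ledger.

.ledger_row <- function(step, unit, n_input, n_retained,
                        n_excluded = NA_integer_, n_added = NA_integer_) {
  tibble(
    step = step, unit = unit,
    n_input = as.integer(n_input), n_retained = as.integer(n_retained),
    n_excluded = as.integer(n_excluded), n_added = as.integer(n_added)
  )
}

.new_ledger <- function(rows) {
  structure(rows, class = c("lnc_ledger", class(tibble())))
}

#' Keep transfrags whose class code is in the retained set
#'
#' By default the cascade keeps intronic (`i`), intergenic (`u`) and
#' antisense (`x`) transfrags, discarding everything structurally matching
#' the reference on the same strand.
#'
#' @param transcripts Exon-level transcript tibble.
#' @param codes Tibble mapping `transcript_id` to `class_code` (from
#'   [classify_transfrags()]).
#' @param keep Character vector of class codes to retain.
#' @return List with `retained` (transcript tibble) and `ledger` (one-row
#'   ledger tibble, transcript unit).
#' @export
filter_by_class <- function(transcripts, codes, keep = c("i", "u", "x")) {
  tx <- as_tibble(transcripts)
  tids <- unique(tx$transcript_id)
  missing <- setdiff(tids, codes$transcript_id)
  if (length(missing)) {
    abort(sprintf("filter_by_class: transcript '%s' has no class code", missing[1]))
  }
  keep_ids <- codes$transcript_id[codes$class_code %in% keep]
  retained <- tx |> filter(transcript_id %in% keep_ids)
  n_in <- length(tids)
  n_ret <- n_distinct(retained$transcript_id)
  list(
    retained = retained,
    ledger = .ledger_row("class_code_filter", "transcript", n_in, n_ret,
                         n_excluded = n_in - n_ret)
  )
}

#' Add annotated lncRNAs back to the filtered transfrags
#'
#' Reference transcripts carrying a lncRNA biotype are unioned into the
#' retained set (the annotated + novel lncRNA assembly), so that known
#' lncRNAs are screened alongside novel candidates.  Transcript ids already
#' present are not double-counted.
#'
#' @param retained Exon-level transcript tibble surviving the class filter.
#' @param reference Reference transcript tibble with a `biotype` column.
#' @param lncrna_biotypes Biotypes regarded as annotated lncRNAs.
#' @return List with `augmented` (transcript tibble) and `ledger` (one-row
#'   ledger tibble recording `n_added`).
#' @export
add_back_annotated_lncrnas <- function(retained, reference,
                                       lncrna_biotypes = default_lncrna_biotypes()) {
  retained <- as_tibble(retained)
  reference <- as_tibble(reference)
  if (!"biotype" %in% names(reference)) {
    abort("add_back_annotated_lncrnas: reference needs a 'biotype' column")
  }
  lnc <- reference |> filter(biotype %in% lncrna_biotypes)
  new <- lnc |> filter(!transcript_id %in% retained$transcript_id)
  augmented <- bind_rows(retained, new)
  n_in <- n_distinct(retained$transcript_id)
  list(
    augmented = augmented,
    ledger = .ledger_row("add_back_annotated_lncrnas", "transcript",
                         n_in, n_in + n_distinct(new$transcript_id),
                         n_added = n_distinct(new$transcript_id))
  )
}

#' Default annotated-lncRNA biotypes
#'
#' The long non-coding biotypes of GENCODE-style annotations.
#' @return Character vector of biotype labels.
#' @export
default_lncrna_biotypes <- function() {
  c(
    "lincRNA", "lncRNA", "antisense", "sense_intronic", "sense_overlapping",
    "processed_transcript", "3prime_overlapping_ncRNA", "3prime_overlapping_ncrna"
  )
}

#' Exclude loci overlapping protein-coding extended TSS regions
#'
#' Each protein-coding reference transcript contributes an extended TSS
#' region (TSS +/- `flank`, capturing potential alternative start sites);
#' any locus with a same-strand exonic overlap (>= 1 base) with any such
#' region is excluded, since alternative TSSs of coding genes can masquerade
#' as novel transcripts.
#'
#' @param loci Locus tibble from [merge_to_gene_loci()].
#' @param reference_pc Reference transcripts restricted to the
#'   protein-coding biotype.
#' @param flank TSS extension in bases (default 1500).
#' @return List with `retained` loci, `ledger` row (gene unit) and
#'   `excluded` gene ids.
#' @export
exclude_pc_tss_overlap <- function(loci, reference_pc, flank = 1500) {
  loci <- as_tibble(loci)
  n_in <- n_distinct(loci$gene_id)
  if (nrow(as_tibble(reference_pc)) == 0 || nrow(loci) == 0) {
    return(list(
      retained = loci,
      ledger = .ledger_row("pc_tss_exclusion", "gene", n_in, n_in, 0L),
      excluded = character()
    ))
  }
  regions <- tss_region(reference_pc, flank = flank)
  hits <- overlap_hits(loci, regions, "same")
  excluded <- unique(loci$gene_id[hits$q])
  retained <- loci |> filter(!gene_id %in% excluded)
  list(
    retained = retained,
    ledger = .ledger_row("pc_tss_exclusion", "gene", n_in,
                         n_in - length(excluded), length(excluded)),
    excluded = excluded
  )
}

#' Exclude loci overlapping annotated small RNAs
#'
#' Loci with a same-strand exonic overlap (>= 1 base; unstranded records
#' match both strands) with any record of any named small-RNA set
#' (microRNA, snRNA, srpRNA, tRNA, scRNA, antigen-receptor loci, ...) are
#' excluded.  Overlap is exonic, so a small RNA hosted inside a long intron
#' does not exclude its host locus.
#'
#' @param loci Locus tibble.
#' @param small_rna_sets Named list of interval tibbles (`chrom`, `start`,
#'   `end`, optional `strand`).
#' @return List with `retained` loci, `ledger` row, `excluded` gene ids and
#'   `per_set` exclusion counts (a gene overlapping records in several sets
#'   is excluded once, each set credited).
#' @export
exclude_small_rna_overlap <- function(loci, small_rna_sets = list()) {
  loci <- as_tibble(loci)
  n_in <- n_distinct(loci$gene_id)
  per_set <- tibble(set = character(), n_excluded = integer())
  excluded <- character()
  if (length(small_rna_sets)) {
    if (is.null(names(small_rna_sets)) || any(!nzchar(names(small_rna_sets)))) {
      abort("exclude_small_rna_overlap: small_rna_sets must be named")
    }
    per_set <- imap(small_rna_sets, function(set, nm) {
      hits <- overlap_hits(loci, as_tibble(set), "same")
      tibble(set = nm, genes = list(unique(loci$gene_id[hits$q])))
    }) |>
      list_rbind() |>
      mutate(n_excluded = map_int(genes, length))
    excluded <- unique(unlist(per_set$genes))
    per_set <- per_set |> select(set, n_excluded)
  }
  retained <- loci |> filter(!gene_id %in% excluded)
  list(
    retained = retained,
    ledger = .ledger_row("small_rna_exclusion", "gene", n_in,
                         n_in - length(excluded), length(excluded)),
    excluded = excluded,
    per_set = per_set
  )
}

#' Exclude loci shorter than the lncRNA length definition
#'
#' Retains loci whose spliced length (sum of exon-union block lengths) is at
#' least `min_nt`; the 200 nt default is the defining lower bound of a
#' lncRNA, so a 199 nt locus is excluded and a 200 nt locus retained.
#'
#' @param loci Locus tibble.
#' @param min_nt Minimum spliced length in nt (default 200).
#' @return List with `retained` loci, `ledger` row and `excluded` gene ids.
#' @export
filter_min_length <- function(loci, min_nt = 200) {
  loci <- as_tibble(loci)
  n_in <- n_distinct(loci$gene_id)
  lens <- locus_lengths(loci)
  short <- lens$gene_id[lens$length < min_nt]
  retained <- loci |> filter(!gene_id %in% short)
  list(
    retained = retained,
    ledger = .ledger_row("min_length_filter", "gene", n_in,
                         n_in - length(short), length(short)),
    excluded = short
  )
}

#' Label loci by overlap with known annotation sources
#'
#' For each named source (RefSeq, ENSEMBL, MiTranscriptome, or any
#' user-supplied transcript set) a locus is flagged `TRUE` iff it has a
#' same-strand exonic overlap (>= 1 base) with any source transcript's
#' exons; loci unmatched in a source are novel with respect to it.
#'
#' @param loci Locus tibble.
#' @param sources Named list of exon-level transcript tibbles.
#' @return Tibble with `gene_id` and one logical column per source.
#' @export
annotate_known_overlap <- function(loci, sources = list()) {
  loci <- as_tibble(loci)
  out <- loci |> distinct(gene_id)
  if (length(sources) == 0) return(out)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    abort("annotate_known_overlap: sources must be named")
  }
  for (nm in names(sources)) {
    hits <- overlap_hits(loci, as_tibble(sources[[nm]]), "same")
    out[[nm]] <- out$gene_id %in% unique(loci$gene_id[hits$q])
  }
  out
}

#' Run the Phase-I filtration cascade
#'
#' Applies, in order: transfrag classification, class-code filter,
#' annotated-lncRNA add-back, gene-level merge, protein-coding extended-TSS
#' exclusion, small-RNA exclusion, minimum-length filter, and
#' known-annotation labelling.  The returned ledger records input, retained
#' and excluded (or added) counts for every step; counts are in transcripts
#' up to the merge and in genes after it.
#'
#' @param assembly Exon-level transcript tibble of the assembled
#'   transcriptome.
#' @param reference Reference transcript tibble with a `biotype` column.
#' @param config List of options: `keep_codes` (default `c("i","u","x")`),
#'   `tss_flank` (1500), `min_length` (200), `lncrna_biotypes`,
#'   `pc_biotypes` (`"protein_coding"`), `small_rna_sets` (named list of
#'   interval tibbles), `annotation_sources` (named list of transcript
#'   tibbles).
#' @return Object of class `lnc_phase1`: list with `loci` (putative lncRNA
#'   loci), `ledger`, `labels`, `codes`, `transcripts` (surviving
#'   transcripts) and `excluded` (per-step excluded gene ids).
#' @export
run_phase1 <- function(assembly, reference, config = list()) {
  cfg <- modifyList(
    list(
      keep_codes = c("i", "u", "x"),
      tss_flank = 1500,
      min_length = 200,
      lncrna_biotypes = default_lncrna_biotypes(),
      pc_biotypes = "protein_coding",
      small_rna_sets = list(),
      annotation_sources = list()
    ),
    config
  )
  assembly <- as_tibble(assembly)
  reference <- as_tibble(reference)
  validate_transcripts(reference)

  index <- build_reference_index(reference)
  codes <- classify_transfrags(assembly, index)
  steps <- list(.ledger_row(
    "classify", "transcript",
    n_distinct(assembly$transcript_id), n_distinct(assembly$transcript_id), 0L
  ))

  s <- filter_by_class(assembly, codes, keep = cfg$keep_codes)
  steps <- c(steps, list(s$ledger))

  s <- add_back_annotated_lncrnas(s$retained, reference, cfg$lncrna_biotypes)
  steps <- c(steps, list(s$ledger))
  tx <- s$augmented

  loci <- merge_to_gene_loci(tx)
  steps <- c(steps, list(.ledger_row(
    "merge_gene_level", "gene",
    n_distinct(tx$transcript_id), n_distinct(loci$gene_id)
  )))

  excluded <- list()
  pc <- reference |> filter(biotype %in% cfg$pc_biotypes)
  s <- exclude_pc_tss_overlap(loci, pc, flank = cfg$tss_flank)
  steps <- c(steps, list(s$ledger)); excluded$pc_tss <- s$excluded

  s <- exclude_small_rna_overlap(s$retained, cfg$small_rna_sets)
  steps <- c(steps, list(s$ledger)); excluded$small_rna <- s$excluded
  per_set <- s$per_set

  s <- filter_min_length(s$retained, min_nt = cfg$min_length)
  steps <- c(steps, list(s$ledger)); excluded$min_length <- s$excluded
  loci <- s$retained

  labels <- annotate_known_overlap(loci, cfg$annotation_sources)

  structure(
    list(
      loci = loci,
      ledger = .new_ledger(list_rbind(steps)),
      labels = labels,
      codes = codes,
      transcripts = tx |> filter(gene_id %in% loci$gene_id),
      excluded = excluded,
      small_rna_per_set = per_set,
      config = cfg
    ),
    class = "lnc_phase1"
  )
}

#' @export
print.lnc_phase1 <- function(x, ...) {
  cat(sprintf(
    "<lnc_phase1> %d putative lncRNA loci after filtration\n",
    n_distinct(x$loci$gene_id)
  ))
  print(as_tibble(x$ledger))
  invisible(x)
}
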