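# Class-code assignment of assembled transfrags against a reference
# annotation.  Only the codes the downstream filter consumes are
# distinguished (=, j, o, x, i, u); remaining Cuffcompare codes collapse
# into the nearest of these by the precedence below, which never changes
# what the filtration cascade keeps.
#
# Precedence (first satisfied wins):
#   '='  identical intron chain with a same-strand reference transcript
#        (single-exon query: exonic overlap with a single-exon same-strand
#        reference transcript)
#   'j'  shares >= 1 intron (exact donor and acceptor) with a same-strand
#        reference transcript, chains not equal
#   'o'  >= 1 base exonic overlap with a same-strand reference exon
#   'x'  >= 1 base exonic overlap with an opposite-strand reference exon,
#        or a query intron overlaps a reference intron on the opposite strand
#   'i'  full genomic span contained in a single reference intron (either
#        strand)
#   'u'  none of the above (unknown / intergenic)

CLASS_CODES <- c("=", "j", "o", "x", "i", "u")

#' Build a queryable index over a reference annotation
#'
#' Precomputes the exon, intron, span and intron-chain tables of a reference
#' transcript set, against which assembled transfrags are classified.
#'
#' @param reference Exon-level transcript tibble of the reference annotation.
#' @return An object of class `lnc_ref_index`.
#' @export
build_reference_index <- function(reference) {
  ref <- as_tibble(reference)
  validate_transcripts(ref)
  spans <- transcript_spans(ref)
  structure(
    list(
      exons = ref,
      introns = transcript_introns(ref),
      spans = spans,
      chains = .chain_keys(ref),
      single_exon = spans |> filter(n_exons == 1)
    ),
    class = "lnc_ref_index"
  )
}

#' @export
print.lnc_ref_index <- function(x, ...) {
  cat(sprintf(
    "<lnc_ref_index> %d reference transcripts (%d exons, %d introns)\n",
    nrow(x$spans), nrow(x$exons), nrow(x$introns)
  ))
  invisible(x)
}

# all candidate (transcript_id, ref_id) pairs for each code, plus exonic
# overlap in bases for tie-breaking the reported reference match
.code_candidates <- function(query, index) {
  q_spans <- transcript_spans(query)
  q_introns <- transcript_introns(query)
  q_chains <- .chain_keys(query)

  ref_ex <- index$exons
  ref_in <- index$introns

  # '=': multi-exon chain identity
  eq_multi <- q_chains |>
    filter(!is.na(key)) |>
    inner_join(index$chains |> filter(!is.na(key)),
               by = "key", suffix = c("", "_ref"), relationship = "many-to-many") |>
    transmute(transcript_id, ref_id = transcript_id_ref)
  # '=': single-exon query overlapping single-exon same-strand reference
  q_se <- q_spans |> filter(n_exons == 1)
  hits <- overlap_hits(q_se, index$single_exon, "same")
  eq_single <- tibble(
    transcript_id = q_se$transcript_id[hits$q],
    ref_id = index$single_exon$transcript_id[hits$s]
  )
  eq <- bind_rows(eq_multi, eq_single) |> distinct()

  # shared intron, same strand, exact coordinates
  j <- q_introns |>
    inner_join(ref_in, by = c("chrom", "strand", "start", "end"),
               suffix = c("", "_ref"), relationship = "many-to-many") |>
    transmute(transcript_id, ref_id = transcript_id_ref) |>
    distinct()

  # exonic overlap, same strand
  hits <- overlap_hits(query, ref_ex, "same")
  o <- tibble(
    transcript_id = query$transcript_id[hits$q],
    ref_id = ref_ex$transcript_id[hits$s],
    overlap_bp = hits$overlap_bp
  ) |>
    group_by(transcript_id, ref_id) |>
    summarise(overlap_bp = sum(overlap_bp), .groups = "drop")

  # exonic overlap, opposite strand
  hits <- overlap_hits(query, ref_ex, "opposite")
  x_exon <- tibble(
    transcript_id = query$transcript_id[hits$q],
    ref_id = ref_ex$transcript_id[hits$s],
    overlap_bp = hits$overlap_bp
  ) |>
    group_by(transcript_id, ref_id) |>
    summarise(overlap_bp = sum(overlap_bp), .groups = "drop")
  # intronic overlap, opposite strand
  hits <- overlap_hits(q_introns, ref_in, "opposite")
  x_intron <- tibble(
    transcript_id = q_introns$transcript_id[hits$q],
    ref_id = ref_in$transcript_id[hits$s],
    overlap_bp = 0L
  ) |> distinct()
  x <- bind_rows(x_exon, x_intron)
  if (nrow(x)) {
    x <- x |>
      group_by(transcript_id, ref_id) |>
      summarise(overlap_bp = max(overlap_bp), .groups = "drop")
  }

  # span contained in one reference intron, either strand
  hits <- overlap_hits(q_spans, ref_in, "ignore", type = "within")
  i <- tibble(
    transcript_id = q_spans$transcript_id[hits$q],
    ref_id = ref_in$transcript_id[hits$s]
  ) |> distinct()

  list(`=` = eq, j = j, o = o, x = x, i = i)
}

#' Classify assembled transfrags against a reference index
#'
#' Assigns each query transcript exactly one class code (`=`, `j`, `o`,
#' `x`, `i`, `u`) describing its structural relation to the reference, by
#' the precedence documented in [classify_transfrag()].  The reported
#' `ref_id` is the reference transcript satisfying the assigned relation
#' with the largest exonic overlap, ties broken lexicographically (`NA` for
#' `u`).
#'
#' @param query Exon-level transcript tibble of assembled transfrags; every
#'   transcript must be stranded (`+` or `-`).
#' @param index Reference index from [build_reference_index()].
#' @return Tibble with columns `transcript_id`, `gene_id`, `class_code`,
#'   `ref_id`, one row per query transcript.
#' @export
classify_transfrags <- function(query, index) {
  if (!is(index, "lnc_ref_index")) {
    abort("classify_transfrags: index must come from build_reference_index()")
  }
  query <- as_tibble(query)
  validate_transcripts(query)
  ids <- query |> distinct(transcript_id, gene_id)
  if (nrow(query) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      class_code = character(), ref_id = character()
    ))
  }
  unstranded <- query |> filter(!strand %in% c("+", "-"))
  if (nrow(unstranded)) {
    abort(sprintf(
      "classify_transfrags: transcript '%s' is unstranded; class codes require strand",
      unstranded$transcript_id[1]
    ))
  }
  cand <- .code_candidates(query, index)
  # total exonic overlap per (query, ref) pair regardless of strand, for
  # tie-breaking codes whose rule is not itself exonic (j, i, intron-only x)
  hits <- overlap_hits(query, index$exons, "ignore")
  ov_any <- tibble(
    transcript_id = query$transcript_id[hits$q],
    ref_id = index$exons$transcript_id[hits$s],
    ov = hits$overlap_bp
  ) |>
    group_by(transcript_id, ref_id) |>
    summarise(ov = sum(ov), .groups = "drop")

  assigned <- ids |> mutate(class_code = NA_character_, ref_id = NA_character_)
  for (code in c("=", "j", "o", "x", "i")) {
    pairs <- cand[[code]]
    if (nrow(pairs) == 0) next
    best <- pairs |>
      left_join(ov_any, by = c("transcript_id", "ref_id")) |>
      mutate(ov = coalesce(ov, 0L)) |>
      arrange(transcript_id, desc(ov), ref_id) |>
      group_by(transcript_id) |>
      slice(1) |>
      ungroup()
    open <- is.na(assigned$class_code) & assigned$transcript_id %in% best$transcript_id
    if (any(open)) {
      m <- match(assigned$transcript_id[open], best$transcript_id)
      assigned$class_code[open] <- code
      assigned$ref_id[open] <- best$ref_id[m]
    }
  }
  assigned$class_code[is.na(assigned$class_code)] <- "u"
  assigned
}

#' Classify a single transfrag
#'
#' Convenience wrapper around [classify_transfrags()] for one transcript.
#'
#' @param query Exon-level tibble describing a single transcript.
#' @param index Reference index from [build_reference_index()].
#' @return The class code as a length-1 character vector, with the matched
#'   reference transcript id in attribute `ref_id`.
#' @export
classify_transfrag <- function(query, index) {
  query <- as_tibble(query)
  if (n_distinct(query$transcript_id) != 1) {
    abort("classify_transfrag: query must contain exactly one transcript")
  }
  res <- classify_transfrags(query, index)
  structure(res$class_code, ref_id = res$ref_id)
}
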