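# Readers and writers for the exchange formats the pipeline consumes:
# GTF (9 columns, 1-based closed -> converted), BED4 peaks/segments,
# BED3 TADs, BED6 small-RNA sets, BEDPE-like interaction pairs,
# gene x sample count tables, sample/peak sheets, coding-probability and
# differential-expression tables.

.split_fields <- function(lines, n, path, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n)
  if (length(bad)) {
    abort(sprintf(
      "%s: malformed %s line %d (expected %d tab-separated columns, found %d)",
      path, what, bad[1], n, nf[bad[1]]
    ))
  }
  fields
}

.num_col <- function(values, lines_idx, path, what, col) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !is.na(values))
  if (length(bad)) {
    abort(sprintf(
      "%s: non-numeric %s in %s line %d: '%s'",
      path, col, what, lines_idx[bad[1]], values[bad[1]]
    ))
  }
  out
}

.content_lines <- function(path, comment = "#") {
  lines <- read_lines(path)
  keep <- nzchar(str_trim(lines)) & !startsWith(lines, comment)
  list(lines = lines[keep], idx = which(keep))
}

#' Read transcripts from a GTF file
#'
#' Parses `exon` features of a 9-column GTF into an exon-level transcript
#' tibble.  GTF coordinates (1-based closed) are converted to the package's
#' internal 0-based half-open convention.  `gene_id` and `transcript_id`
#' attributes are required on every exon; a biotype is captured from the
#' first of `gene_biotype`, `gene_type`, `transcript_biotype`,
#' `transcript_type` if present.
#'
#' @param path Path to a GTF file.
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `biotype`, one row per exon, exons sorted within each
#'   transcript.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_gtf: no such file: %s", path))
  cl <- .content_lines(path)
  empty <- tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    biotype = character()
  )
  if (length(cl$lines) == 0) return(empty)
  fields <- .split_fields(cl$lines, 9L, path, "GTF")
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(empty)
  m <- m[is_exon, , drop = FALSE]
  idx <- cl$idx[is_exon]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    abort(sprintf("%s: non-integer coordinates in GTF line %d", path, idx[bad[1]]))
  }
  bad <- which(end1 < start1)
  if (length(bad)) {
    abort(sprintf(
      "%s: exon with end < start in GTF line %d (%d < %d)",
      path, idx[bad[1]], end1[bad[1]], start1[bad[1]]
    ))
  }
  attrs <- m[, 9]
  gid <- str_match(attrs, 'gene_id\\s+"([^"]*)"')[, 2]
  tid <- str_match(attrs, 'transcript_id\\s+"([^"]*)"')[, 2]
  bad <- which(is.na(gid) | is.na(tid))
  if (length(bad)) {
    abort(sprintf(
      "%s: GTF line %d lacks gene_id/transcript_id attributes", path, idx[bad[1]]
    ))
  }
  bt <- str_match(
    attrs, '(?:gene_biotype|gene_type|transcript_biotype|transcript_type)\\s+"([^"]*)"'
  )[, 2]
  out <- tibble(
    transcript_id = tid, gene_id = gid, chrom = m[, 1], strand = m[, 7],
    start = start1 - 1L, end = end1, biotype = bt
  ) |>
    arrange(transcript_id, start)
  validate_transcripts(out)
  out
}

#' Write transcripts to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` line per exon row, converting
#' internal 0-based half-open coordinates back to GTF 1-based closed.
#' `read_gtf(write_gtf(x))` reproduces the exon chains of `x`.
#'
#' @param transcripts Exon-level transcript tibble (see [read_gtf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  tx <- as_tibble(transcripts)
  if (nrow(tx) == 0) {
    write_lines(character(), path)
    return(invisible(path))
  }
  validate_transcripts(tx)
  bt <- if ("biotype" %in% names(tx)) tx$biotype else rep(NA_character_, nrow(tx))
  attrs <- paste0(
    'gene_id "', tx$gene_id, '"; transcript_id "', tx$transcript_id, '";',
    ifelse(is.na(bt), "", paste0(' gene_biotype "', bt, '";'))
  )
  lines <- paste(
    tx$chrom, "lncscreenr", "exon", tx$start + 1L, tx$end, ".", tx$strand, ".",
    attrs,
    sep = "\t"
  )
  write_lines(lines, path)
  invisible(path)
}

#' Read a BED4 peak or segment file
#'
#' BED4 here is `chrom  start  end  score`, 0-based half-open, where the
#' fourth column is a ChIP enrichment score (or any segment value, e.g. a
#' copy-number ratio).
#'
#' @param path Path to a 4-column tab-separated file.
#' @param name Optional set name recorded in a `name` column (e.g. the
#'   histone mark).
#' @return Tibble with columns `chrom`, `start`, `end`, `score` (and `name`
#'   if given).
#' @export
read_bed4 <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("read_bed4: no such file: %s", path))
  cl <- .content_lines(path)
  out <- tibble(
    chrom = character(), start = integer(), end = integer(), score = double()
  )
  if (length(cl$lines)) {
    fields <- .split_fields(cl$lines, 4L, path, "BED4")
    m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
    start <- as.integer(.num_col(m[, 2], cl$idx, path, "BED4", "start"))
    end <- as.integer(.num_col(m[, 3], cl$idx, path, "BED4", "end"))
    score <- .num_col(m[, 4], cl$idx, path, "BED4", "score")
    bad <- which(end <= start | start < 0)
    if (length(bad)) {
      abort(sprintf(
        "%s: invalid interval in BED4 line %d (need 0 <= start < end)",
        path, cl$idx[bad[1]]
      ))
    }
    out <- tibble(chrom = m[, 1], start = start, end = end, score = score)
  }
  if (!is.null(name)) out$name <- name
  out
}

#' Read a BED3/BED6 interval file
#'
#' Flexible reader for 3- to 6-column BED (e.g. TAD intervals as BED3,
#' small-RNA annotation sets as BED6 with a strand column).  Missing columns
#' default to `name = "."`, `score = 0`, `strand = "."`.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_bed: no such file: %s", path))
  cl <- .content_lines(path)
  if (length(cl$lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character()
    ))
  }
  fields <- .split_fields(cl$lines, 3L, path, "BED")
  get <- function(i, default) {
    map_chr(fields, function(f) if (length(f) >= i) f[i] else default)
  }
  start <- as.integer(.num_col(get(2, NA), cl$idx, path, "BED", "start"))
  end <- as.integer(.num_col(get(3, NA), cl$idx, path, "BED", "end"))
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    abort(sprintf(
      "%s: invalid interval in BED line %d (need 0 <= start < end)",
      path, cl$idx[bad[1]]
    ))
  }
  tibble(
    chrom = get(1, NA), start = start, end = end,
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))) |> replace_na(0),
    strand = get(6, ".")
  )
}

#' Read Hi-C interaction pairs
#'
#' Reads a BEDPE-like 7-column tab-separated table:
#' `chrom1 start1 end1 chrom2 start2 end2 score`.
#'
#' @param path Path to the pairs file.
#' @return Tibble with those seven columns; `cis` column added
#'   (`chrom1 == chrom2`).
#' @export
read_hic_pairs <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_hic_pairs: no such file: %s", path))
  cl <- .content_lines(path)
  if (length(cl$lines) == 0) {
    return(tibble(
      chrom1 = character(), start1 = integer(), end1 = integer(),
      chrom2 = character(), start2 = integer(), end2 = integer(),
      score = double(), cis = logical()
    ))
  }
  fields <- .split_fields(cl$lines, 7L, path, "pairs")
  m <- matrix(unlist(lapply(fields, `[`, 1:7)), ncol = 7, byrow = TRUE)
  tibble(
    chrom1 = m[, 1],
    start1 = as.integer(.num_col(m[, 2], cl$idx, path, "pairs", "start1")),
    end1 = as.integer(.num_col(m[, 3], cl$idx, path, "pairs", "end1")),
    chrom2 = m[, 4],
    start2 = as.integer(.num_col(m[, 5], cl$idx, path, "pairs", "start2")),
    end2 = as.integer(.num_col(m[, 6], cl$idx, path, "pairs", "end2")),
    score = .num_col(m[, 7], cl$idx, path, "pairs", "score")
  ) |>
    mutate(cis = chrom1 == chrom2)
}

#' Read a gene x sample raw-count table
#'
#' First column is `gene_id`; the header row names the samples.  Counts must
#' be non-negative integers and gene/sample ids unique.
#'
#' @param path Path to the tab-separated count table.
#' @return Wide tibble: `gene_id` plus one integer column per sample.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_counts: no such file: %s", path))
  x <- read_tsv(path, col_types = cols(.default = "d", gene_id = col_character()),
                progress = FALSE)
  if (names(x)[1] != "gene_id") names(x)[1] <- "gene_id"
  samples <- setdiff(names(x), "gene_id")
  if (length(samples) == 0) abort(sprintf("%s: count table has no sample columns", path))
  if (anyDuplicated(x$gene_id)) abort(sprintf("%s: duplicate gene ids", path))
  vals <- as.matrix(x[samples])
  if (any(is.na(vals))) abort(sprintf("%s: missing counts", path))
  if (any(vals < 0)) abort(sprintf("%s: negative counts", path))
  if (any(vals != round(vals))) abort(sprintf("%s: non-integer counts", path))
  x[samples] <- lapply(x[samples], as.integer)
  as_tibble(x)
}

#' Read the sample sheet and peak sheet
#'
#' The sample sheet maps samples to groups: a tab-separated table with a
#' `sample` column, a `group` column and optionally further grouping
#' columns.  The peak sheet maps each (group, histone mark) to a BED4 peak
#' file: columns `group`, `mark`, `file`.
#'
#' @param samples_path Path to the sample sheet TSV.
#' @param peaks_path Optional path to the peak sheet TSV.
#' @param base_dir Directory against which relative peak file paths are
#'   resolved (defaults to the sheet's directory).
#' @return List with elements `samples` (tibble) and `peaks` (tibble with
#'   resolved `file` paths, or NULL).
#' @export
read_group_sheet <- function(samples_path, peaks_path = NULL, base_dir = NULL) {
  samples <- read_tsv(samples_path, col_types = cols(.default = "c"),
                      progress = FALSE)
  if (!all(c("sample", "group") %in% names(samples))) {
    abort("read_group_sheet: sample sheet needs 'sample' and 'group' columns")
  }
  if (anyDuplicated(samples$sample)) {
    abort("read_group_sheet: duplicate sample names")
  }
  if (any(is.na(samples$group) | !nzchar(samples$group))) {
    abort("read_group_sheet: every sample must be assigned to a group")
  }
  peaks <- NULL
  if (!is.null(peaks_path)) {
    peaks <- read_tsv(peaks_path, col_types = cols(.default = "c"),
                      progress = FALSE)
    if (!all(c("group", "mark", "file") %in% names(peaks))) {
      abort("read_group_sheet: peak sheet needs 'group', 'mark', 'file' columns")
    }
    dir <- base_dir %||% dirname(peaks_path)
    abs <- file.path(dir, peaks$file)
    peaks$file <- ifelse(file.exists(peaks$file), peaks$file, abs)
    missing <- !file.exists(peaks$file)
    if (any(missing)) {
      abort(sprintf(
        "read_group_sheet: peak file not found: %s", peaks$file[which(missing)[1]]
      ))
    }
  }
  list(samples = samples, peaks = peaks)
}

#' Read a coding-probability table
#'
#' Two-plus-column tab-separated table with header; the first column is a
#' gene or transcript id, and a `coding_prob` column holds the externally
#' computed coding probability in `[0, 1]` (e.g. a CPAT score).
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `id` and `coding_prob`.
#' @export
read_coding_probs <- function(path) {
  x <- read_tsv(path, col_types = cols(.default = "c"), progress = FALSE)
  if (!"coding_prob" %in% names(x)) {
    abort("read_coding_probs: need a 'coding_prob' column")
  }
  names(x)[1] <- "id"
  out <- tibble(id = x$id, coding_prob = as.numeric(x$coding_prob))
  if (any(is.na(out$coding_prob))) abort("read_coding_probs: non-numeric probabilities")
  if (any(out$coding_prob < 0 | out$coding_prob > 1)) {
    abort("read_coding_probs: probabilities must lie in [0, 1]")
  }
  out
}

#' Read a differential-expression result table
#'
#' Consumes an externally computed pairwise differential-expression table:
#' tab-separated with header columns `gene_id`, `log2fc`, `pvalue`, `fdr`.
#'
#' @param path Path to the TSV.
#' @return Tibble with those four columns.
#' @export
read_de_table <- function(path) {
  x <- read_tsv(path, col_types = cols(.default = "c"), progress = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "fdr")
  if (!all(need %in% names(x))) {
    abort(sprintf(
      "read_de_table: need columns %s", paste(need, collapse = ", ")
    ))
  }
  tibble(
    gene_id = x$gene_id,
    log2fc = as.numeric(x$log2fc),
    pvalue = as.numeric(x$pvalue),
    fdr = as.numeric(x$fdr)
  )
}
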