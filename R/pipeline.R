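# Single-command pipeline: Phase I filtration, coding gate, quantification,
# histone-mark integration, group calls, pie matrix, segment/Hi-C
# annotation and the comprehensive feature report.

.resolve_path <- function(p, base) {
  if (is.null(p)) return(NULL)
  ifelse(file.exists(p) | startsWith(p, "/"), p, file.path(base, p))
}

.resolve_named <- function(x, base) {
  if (is.null(x) || length(x) == 0) return(list())
  lapply(x, .resolve_path, base = base)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s': %s", name, conditionMessage(e)))
  })
}

#' Default pipeline parameters
#'
#' @return Named list of the tunable screening parameters and their
#'   defaults: `keep_codes` (i, u, x), `tss_flank` (1500 nt),
#'   `min_length` (200 nt), `fpkm_cutoff` (0.5), `coding_cutoff` (0.364),
#'   `min_fold` (0), `group_column` ("group"), `lncrna_biotypes`,
#'   `pc_biotypes`.
#' @export
default_params <- function() {
  list(
    keep_codes = c("i", "u", "x"),
    tss_flank = 1500,
    min_length = 200,
    fpkm_cutoff = 0.5,
    coding_cutoff = 0.364,
    min_fold = 0,
    group_column = "group",
    lncrna_biotypes = default_lncrna_biotypes(),
    pc_biotypes = "protein_coding"
  )
}

.read_config <- function(config) {
  base <- "."
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  required <- c("assembly_gtf", "reference_gtf", "counts", "samples")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(sprintf("config: missing required key '%s'", missing[1]))
  }
  for (key in c("assembly_gtf", "reference_gtf", "counts", "samples", "peaks",
                "coding_probs", "genome_fasta", "hic_pairs", "tads")) {
    config[[key]] <- .resolve_path(config[[key]], base)
  }
  for (key in c("small_rna", "annotation_sources", "segments", "de_tables")) {
    config[[key]] <- .resolve_named(config[[key]], base)
  }
  if (!is.null(config$outdir) && !startsWith(config$outdir, "/")) {
    config$outdir <- file.path(base, config$outdir)
  }
  config$params <- modifyList(default_params(), config$params %||% list())
  config$base <- base
  config
}

.segment_string <- function(seg_rows) {
  if (nrow(seg_rows) == 0) return("")
  seg_rows <- seg_rows |> arrange(chrom, start, end)
  paste(sprintf("%s:%d-%d=%s", seg_rows$chrom, seg_rows$start, seg_rows$end,
                format(seg_rows$score, trim = TRUE)), collapse = ";")
}

#' Run the complete lncRNA screening pipeline
#'
#' Executes every stage against the inputs named in the configuration:
#' Phase-I filtration (classification, class filter, add-back, gene merge,
#' extended-TSS/small-RNA/length exclusions), the coding-probability gate,
#' gene-level FPKM and cutoff-aware group summaries, histone-mark
#' assignment at extended TSS regions, group-enriched lncRNA / eRNA calls,
#' pie-matrix statistics, supervised ordering, segment and TAD-constrained
#' Hi-C annotation, and the comprehensive feature report.  All tabular
#' outputs are written to `outdir` with deterministic formatting.
#'
#' @param config A list or YAML file path.  Required keys: `assembly_gtf`,
#'   `reference_gtf`, `counts` (gene x sample TSV), `samples` (sample
#'   sheet).  Optional: `peaks` (peak sheet), `small_rna`,
#'   `annotation_sources`, `coding_probs`, `genome_fasta`, `segments`,
#'   `hic_pairs`, `tads`, `de_tables`, `outdir`, and `params` overriding
#'   [default_params()].
#' @param write Write output files (ignored unless `outdir` is configured).
#' @return Object of class `lncscreen_run` carrying every intermediate and
#'   final table.
#' @export
run_pipeline <- function(config, write = TRUE) {
  cfg <- .stage("config", .read_config(config))
  p <- cfg$params
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # ---- inputs -------------------------------------------------------------
  assembly <- .stage("input", read_gtf(cfg$assembly_gtf))
  reference <- .stage("input", read_gtf(cfg$reference_gtf))
  counts <- .stage("input", read_counts(cfg$counts))
  sheet <- .stage("input", read_group_sheet(cfg$samples, cfg$peaks, cfg$base))
  sample_cols <- setdiff(names(counts), "gene_id")
  missing <- setdiff(sample_cols, sheet$samples$sample)
  if (length(missing)) {
    abort(sprintf("stage 'input': sample '%s' absent from the sample sheet",
                  missing[1]))
  }
  small_rna_sets <- .stage("input", lapply(cfg$small_rna, function(f) {
    read_bed(f) |> select(chrom, start, end, strand)
  }))
  annotation_sources <- .stage("input", lapply(cfg$annotation_sources, read_gtf))
  note("input: %d assembly transcripts (%d genes), %d reference transcripts",
       n_distinct(assembly$transcript_id), n_distinct(assembly$gene_id),
       n_distinct(reference$transcript_id))

  # ---- phase I ------------------------------------------------------------
  phase1 <- .stage("phase1", run_phase1(assembly, reference, list(
    keep_codes = p$keep_codes, tss_flank = p$tss_flank,
    min_length = p$min_length, lncrna_biotypes = p$lncrna_biotypes,
    pc_biotypes = p$pc_biotypes, small_rna_sets = small_rna_sets,
    annotation_sources = annotation_sources
  )))
  note("phase1: %d putative lncRNA loci", n_distinct(phase1$loci$gene_id))

  # ---- coding gate --------------------------------------------------------
  gene_probs <- NULL
  if (!is.null(cfg$coding_probs)) {
    raw <- .stage("coding_gate", read_coding_probs(cfg$coding_probs))
    members <- attr(merge_to_gene_loci(bind_rows(
      assembly |> select(transcript_id, gene_id, chrom, strand, start, end),
      reference |> select(transcript_id, gene_id, chrom, strand, start, end)
    )), "member_transcripts")
    by_tx <- raw |>
      inner_join(members, by = c(id = "transcript_id")) |>
      select(gene_id, coding_prob)
    by_gene <- raw |>
      filter(id %in% c(assembly$gene_id, reference$gene_id)) |>
      transmute(gene_id = id, coding_prob)
    # several member-transcript probabilities: gate the gene on the maximum
    gene_probs <- bind_rows(by_tx, by_gene) |>
      group_by(gene_id) |>
      summarise(coding_prob = max(coding_prob), .groups = "drop")
  }
  gate <- .stage("coding_gate", suppressWarnings(
    apply_coding_gate(phase1$loci, gene_probs, cutoff = p$coding_cutoff)
  ))
  loci <- gate$retained
  ledger <- .new_ledger(bind_rows(phase1$ledger, gate$ledger))
  note("coding_gate: %d loci retained (%d excluded as coding)",
       n_distinct(loci$gene_id), length(gate$excluded))

  # ---- expression ---------------------------------------------------------
  loci_all <- .stage("expression", merge_to_gene_loci(bind_rows(
    assembly |> select(transcript_id, gene_id, chrom, strand, start, end),
    reference |> select(transcript_id, gene_id, chrom, strand, start, end)
  )))
  fpkm <- .stage("expression", compute_fpkm(counts, locus_lengths(loci_all)))
  fpkm_lnc <- fpkm |> filter(gene_id %in% loci$gene_id)
  summaries <- .stage("expression", group_summaries(
    fpkm_lnc, sheet$samples, cutoff = p$fpkm_cutoff,
    group_column = p$group_column
  ))

  # ---- histone marks ------------------------------------------------------
  peaks <- tibble(group = character(), mark = character(), chrom = character(),
                  start = integer(), end = integer(), score = double())
  if (!is.null(sheet$peaks) && nrow(sheet$peaks)) {
    peaks <- .stage("marks", pmap(sheet$peaks, function(group, mark, file, ...) {
      b <- read_bed4(file)
      b$group <- group
      b$mark <- mark
      b
    }) |>
      list_rbind() |>
      select(group, mark, chrom, start, end, score))
  }
  groups_all <- unique(sheet$samples[[p$group_column]])
  no_peaks <- setdiff(groups_all, unique(peaks$group))
  if (length(no_peaks)) {
    note("marks: no peak files for group(s) %s; their calls will be 'none'",
         paste(no_peaks, collapse = ", "))
  }
  marks <- .stage("marks", assign_marks(loci, peaks, flank = p$tss_flank,
                                        min_fold = p$min_fold))

  # ---- group calls, pie matrix, ordering ----------------------------------
  rules <- cfg$rules %||% group_call_rules(
    expressed_cutoff = p$fpkm_cutoff
  )
  calls <- .stage("classify", call_groups(summaries, marks, rules))
  pie <- .stage("classify", pie_matrix(calls))
  ordering <- .stage("classify", supervised_order(calls, summaries,
                                                  group_order = sort(groups_all)))
  note("classify: %d lncRNA and %d eRNA (gene, group) calls",
       sum(calls$call == "lncRNA"), sum(calls$call == "eRNA"))

  # ---- segments and Hi-C --------------------------------------------------
  segments <- .stage("segments", annotate_segments(
    loci, lapply(cfg$segments, read_bed4)
  ))
  hic <- tibble(gene_id = character(), partner = character(),
                score = double(), n_pairs = integer())
  if (!is.null(cfg$hic_pairs)) {
    pairs <- .stage("hic", read_hic_pairs(cfg$hic_pairs))
    tads <- if (!is.null(cfg$tads)) {
      .stage("hic", read_bed(cfg$tads) |> select(chrom, start, end))
    } else NULL
    mrna_loci <- merge_to_gene_loci(
      reference |> filter(biotype %in% p$pc_biotypes) |>
        select(transcript_id, gene_id, chrom, strand, start, end)
    )
    hic <- .stage("hic", annotate_hic(loci, mrna_loci, pairs, tads))
  }

  # ---- ORF sizes ----------------------------------------------------------
  orf <- tibble(gene_id = unique(loci$gene_id), orf_size = NA_integer_)
  if (!is.null(cfg$genome_fasta)) {
    genome <- .stage("orf", Biostrings::readDNAStringSet(cfg$genome_fasta))
    names(genome) <- sub("\\s.*$", "", names(genome))
    seqs <- .stage("orf", spliced_sequence(loci, genome))
    orf <- tibble(gene_id = names(seqs), orf_size = longest_orf(seqs))
  }

  # ---- feature report -----------------------------------------------------
  de_tables <- .stage("report", lapply(cfg$de_tables, read_de_table))
  records <- .stage("report", .build_feature_records(
    loci = loci, reference = reference, labels = phase1$labels,
    flags = gate$flags, orf = orf, summaries = summaries, marks = marks,
    calls = calls, segments = segments, hic = hic,
    group_order = sort(groups_all), rules = rules,
    lncrna_biotypes = p$lncrna_biotypes,
    segment_sources = names(cfg$segments) %||% character()
  ))
  records <- .stage("report", attach_de_results(records, de_tables))
  note("report: %d putative lncRNAs in the feature report", nrow(records))

  run <- structure(
    list(
      loci = loci, ledger = ledger, labels = phase1$labels,
      codes = phase1$codes, transcripts = phase1$transcripts,
      fpkm = fpkm_lnc, summaries = summaries, marks = marks, calls = calls,
      pie = pie, ordering = ordering, segments = segments, hic = hic,
      records = records, coding_flags = gate$flags, orf = orf,
      config = cfg, log = log_lines
    ),
    class = "lncscreen_run"
  )

  if (isTRUE(write) && !is.null(cfg$outdir)) {
    run$files <- .stage("write", .write_outputs(run, cfg$outdir))
  }
  run
}

.build_feature_records <- function(loci, reference, labels, flags, orf,
                                   summaries, marks, calls, segments, hic,
                                   group_order, rules, lncrna_biotypes,
                                   segment_sources) {
  spans <- locus_spans(loci)
  lens <- locus_lengths(loci)
  annotated_genes <- unique(reference$gene_id[
    (reference$biotype %||% NA) %in% lncrna_biotypes
  ])
  records <- spans |>
    transmute(
      gene_id,
      locus = sprintf("%s:%d-%d(%s)", chrom, start, end, strand),
      n_exons = n_blocks
    ) |>
    left_join(lens |> rename(gene_body_size = length), by = "gene_id") |>
    left_join(orf, by = "gene_id") |>
    left_join(flags |> select(gene_id, coding_prob), by = "gene_id") |>
    mutate(gencode = if_else(gene_id %in% annotated_genes,
                             "annotated", "novel")) |>
    left_join(labels, by = "gene_id")

  for (src in segment_sources) {
    seg <- segments |> filter(source == src)
    records[[src]] <- map_chr(records$gene_id, function(g) {
      .segment_string(seg |> filter(gene_id == g))
    })
  }
  records$hic_partners <- map_chr(records$gene_id, function(g) {
    h <- hic |> filter(gene_id == g) |> arrange(partner)
    if (nrow(h) == 0) "" else {
      paste(sprintf("%s(%s)", h$partner, format(h$score, trim = TRUE)),
            collapse = ";")
    }
  })

  mark_names <- rules$marks
  for (grp in group_order) {
    s <- summaries |> filter(group == grp)
    records[[paste0(grp, "_mean_fpkm")]] <-
      s$mean_fpkm[match(records$gene_id, s$gene_id)]
    records[[paste0(grp, "_pct_above")]] <-
      100 * s$fraction_above[match(records$gene_id, s$gene_id)]
    for (m in mark_names) {
      a <- marks |> filter(group == grp, mark == m)
      v <- a$max_enrichment[match(records$gene_id, a$gene_id)]
      records[[paste0(grp, "_", m)]] <- coalesce(v, 0)
    }
    cl <- calls |> filter(group == grp)
    records[[paste0(grp, "_call")]] <-
      coalesce(cl$call[match(records$gene_id, cl$gene_id)], "none")
  }
  records |> arrange(gene_id)
}

.write_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  fmt <- function(x) {
    for (col in names(x)) {
      if (is.double(x[[col]])) x[[col]] <- .fmt_num(x[[col]], 4L)
    }
    x
  }
  write_gtf(run$transcripts |> filter(gene_id %in% run$loci$gene_id),
            path("putative_lncrna.gtf"))
  write_tsv(as_tibble(run$ledger), path("filter_ledger.tsv"), progress = FALSE)
  write_tsv(run$labels, path("annotation_labels.tsv"), progress = FALSE)
  write_tsv(fmt(run$fpkm), path("fpkm.tsv"), progress = FALSE)
  write_tsv(fmt(run$summaries), path("group_summaries.tsv"), progress = FALSE)
  write_tsv(fmt(run$marks), path("mark_assignments.tsv"), progress = FALSE)
  write_tsv(run$calls, path("group_calls.tsv"), progress = FALSE)
  write_tsv(as_tibble(run$pie), path("pie_matrix.tsv"), progress = FALSE)
  write_tsv(fmt(run$ordering), path("supervised_order.tsv"), progress = FALSE)
  write_tsv(fmt(run$segments), path("segment_annotations.tsv"), progress = FALSE)
  write_tsv(fmt(run$hic), path("hic_interactions.tsv"), progress = FALSE)
  write_feature_report(run$records, path("feature_report.tsv"))
  write_lines(run$log, path("run.log"))
  list.files(outdir, full.names = TRUE)
}

#' @export
print.lncscreen_run <- function(x, ...) {
  cat(sprintf(
    "<lncscreen_run> %d putative lncRNAs; %d lncRNA and %d eRNA (gene, group) calls\n",
    nrow(x$records), sum(x$calls$call == "lncRNA"), sum(x$calls$call == "eRNA")
  ))
  invisible(x)
}
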