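# Deterministic synthetic fixtures with planted ground truth for every
# pipeline stage: a toy genome, reference annotation (protein-coding +
# annotated lncRNAs), an assembled transcriptome planted per class code and
# per exclusion reason, group-structured counts, per-group histone-mark
# peaks, small-RNA sets, annotation sources, coding probabilities, CNV/SNP
# segments, Hi-C pairs + TADs, and truth tables used as the test oracle.
#
# Geometry (all deterministic given the spec):
#   region A: protein-coding genes, one per 10 kb slot, exons
#             [s, s+300) and [s+2500, s+3000) on '+'; selected hosts carry
#             '='/'j'/'o' decoys, intronic ('i') and antisense ('x')
#             survivors, and TSS decoys.
#   region B: intergenic ('u') novel genes plus short / small-RNA / coding
#             decoys.
#   region C: annotated reference lncRNAs (the add-back set).
#   chr2:     one protein-coding gene (trans Hi-C decoy target) and a
#             library-size filler gene.

#' Specification of a synthetic fixture
#'
#' Defaults emulate a small multi-group study: 4 groups x 3 samples,
#' 140 background protein-coding genes, 28 planted novel survivors (class
#' codes cycled u/i/x), 8 annotated lncRNA add-backs, and decoys for every
#' exclusion reason.  Expression is planted at FPKM `target_fpkm` (10, well
#' above twice the 0.5 call cutoff so calls are never decided at the
#' boundary) by computing the exact count for the planted gene length at a
#' fixed library size; short decoys get length 199 (one below the lncRNA
#' definition).
#'
#' @param seed Integer seed; all fixture randomness flows from it.
#' @param groups Group names.
#' @param samples_per_group Samples per group.
#' @param n_pc Background protein-coding genes on chr1.
#' @param n_lnc_per_group,n_erna_per_group Planted lncRNA/eRNA calls per
#'   group.
#' @param n_silent Novel survivors expressed nowhere (called in no group).
#' @param n_addback Annotated reference lncRNAs (half get a lncRNA call).
#' @param n_eq,n_j,n_o Class-code decoys removed by the class filter.
#' @param n_short,n_tss,n_smallrna,n_coding Decoys per exclusion reason.
#' @param target_fpkm Planted FPKM of expressed genes.
#' @param library_size Planted per-sample library size.
#' @param slot_bp Gene slot spacing in bases.
#' @param with_hic,with_segments,with_de Include the optional annotation
#'   layers.
#' @param chrom_capacity Optional cap on the chr1 length; a layout needing
#'   more space raises an error.
#' @return Object of class `lnc_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         groups = c("A", "B", "C", "D"),
                         samples_per_group = 3,
                         n_pc = 140,
                         n_lnc_per_group = 3,
                         n_erna_per_group = 3,
                         n_silent = 4,
                         n_addback = 8,
                         n_eq = 6, n_j = 6, n_o = 6,
                         n_short = 4, n_tss = 4, n_smallrna = 4, n_coding = 4,
                         target_fpkm = 10,
                         library_size = 1e6,
                         slot_bp = 10000,
                         with_hic = TRUE,
                         with_segments = TRUE,
                         with_de = TRUE,
                         chrom_capacity = NULL) {
  spec <- list(
    seed = seed, groups = groups, samples_per_group = samples_per_group,
    n_pc = n_pc, n_lnc_per_group = n_lnc_per_group,
    n_erna_per_group = n_erna_per_group, n_silent = n_silent,
    n_addback = n_addback, n_eq = n_eq, n_j = n_j, n_o = n_o,
    n_short = n_short, n_tss = n_tss, n_smallrna = n_smallrna,
    n_coding = n_coding, target_fpkm = target_fpkm,
    library_size = library_size, slot_bp = slot_bp,
    with_hic = with_hic, with_segments = with_segments, with_de = with_de,
    chrom_capacity = chrom_capacity
  )
  n_novel <- length(groups) * (n_lnc_per_group + n_erna_per_group) + n_silent
  classes <- rep(c("u", "i", "x"), length.out = n_novel)
  hosts_needed <- n_eq + n_j + n_o + n_tss +
    sum(classes == "i") + sum(classes == "x")
  if (hosts_needed > n_pc) {
    abort(sprintf(
      "fixture_spec: %d protein-coding host slots needed but n_pc = %d",
      hosts_needed, n_pc
    ))
  }
  structure(spec, class = "lnc_fixture_spec")
}

.random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.tx_proto <- function() {
  tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer()
  )
}

.survivor_meta_proto <- function() {
  tibble(
    gene_id = character(), transcript_id = character(), class = character(),
    call = character(), length = integer(), chrom = character(),
    strand = character(), span_start = integer(), span_end = integer(),
    tss = integer()
  )
}

.decoy_meta_proto <- function() {
  tibble(
    gene_id = character(), transcript_id = character(), class = character(),
    reason = character(), length = integer()
  )
}

#' Generate a synthetic fixture with planted truth
#'
#' Builds every input the pipeline consumes, in memory, and (optionally)
#' writes them to `outdir` together with a ready-to-run `config.yaml` and
#' the truth tables.  Identical specs produce byte-identical file sets.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory, or `NULL` for in-memory only.
#' @return List with elements `data` (in-memory inputs: `assembly`,
#'   `reference`, `counts`, `samples`, `peaks`, `small_rna_sets`,
#'   `annotation_sources`, `coding_probs`, `genome`, `segments`,
#'   `hic_pairs`, `tads`, `de_tables`), `truth` (`genes`, `transcripts`),
#'   `phase1_config` (ready for [run_phase1()]), and, when written,
#'   `files` and `config` (the config.yaml path).
#' @export
generate_fixtures <- function(spec = fixture_spec(), outdir = NULL) {
  if (!is(spec, "lnc_fixture_spec")) {
    abort("generate_fixtures: spec must come from fixture_spec()")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  slot <- as.integer(spec$slot_bp)
  groups <- spec$groups
  a0 <- 20000L

  # ---- reference protein-coding genes (region A + chr2) -------------------
  pc_base <- a0 + (seq_len(spec$n_pc) - 1L) * slot
  pc <- tibble(
    gene_id = sprintf("PCG%04d", seq_len(spec$n_pc)),
    transcript_id = sprintf("PCT%04d", seq_len(spec$n_pc)),
    chrom = "chr1", strand = "+", base = pc_base
  )
  pc_exons <- bind_rows(
    pc |> transmute(transcript_id, gene_id, chrom, strand,
                    start = base, end = base + 300L),
    pc |> transmute(transcript_id, gene_id, chrom, strand,
                    start = base + 2500L, end = base + 3000L)
  ) |> mutate(biotype = "protein_coding")
  chr2_pc <- tibble(
    transcript_id = c("PCT9001", "PCT9001", "PCT9002", "PCT9002"),
    gene_id = c("PCG9001", "PCG9001", "PCG9002", "PCG9002"),
    chrom = "chr2", strand = "+",
    start = c(20000L, 22500L, 60000L, 62500L),
    end = c(20300L, 23000L, 60300L, 63000L),
    biotype = "protein_coding"
  )

  # ---- planted novel survivors -------------------------------------------
  n_novel <- length(groups) * (spec$n_lnc_per_group + spec$n_erna_per_group) +
    spec$n_silent
  classes <- rep(c("u", "i", "x"), length.out = n_novel)
  call_plan <- c(
    unlist(lapply(groups, function(g) rep(paste0(g, ":lncRNA"), spec$n_lnc_per_group))),
    unlist(lapply(groups, function(g) rep(paste0(g, ":eRNA"), spec$n_erna_per_group))),
    rep(NA_character_, spec$n_silent)
  )

  # protein-coding host slots handed out in order
  host_idx <- 0L
  next_host <- function() {
    host_idx <<- host_idx + 1L
    pc_base[host_idx]
  }
  eq_hosts <- vapply(seq_len(spec$n_eq), function(i) next_host(), integer(1))
  j_hosts <- vapply(seq_len(spec$n_j), function(i) next_host(), integer(1))
  o_hosts <- vapply(seq_len(spec$n_o), function(i) next_host(), integer(1))
  tss_hosts <- vapply(seq_len(spec$n_tss), function(i) next_host(), integer(1))

  b0 <- a0 + spec$n_pc * slot + 50000L
  n_b_slots <- sum(classes == "u") + spec$n_short + spec$n_smallrna + spec$n_coding
  b_idx <- 0L
  next_b <- function() {
    b_idx <<- b_idx + 1L
    b0 + (b_idx - 1L) * slot
  }

  xid <- 0L
  next_xloc <- function() {
    xid <<- xid + 1L
    c(sprintf("XLOC%04d", xid), sprintf("TCONS%06d", xid))
  }

  survivor_rows <- list()
  survivor_meta <- list()
  for (k in seq_len(n_novel)) {
    ids <- next_xloc()
    cls <- classes[k]
    if (cls == "u") {
      b <- next_b()
      ex <- tibble(start = c(b, b + 800L), end = c(b + 300L, b + 1200L),
                   strand = "+", chrom = "chr1")
    } else if (cls == "i") {
      s <- next_host()
      ex <- tibble(start = s + 1600L, end = s + 1900L,
                   strand = "-", chrom = "chr1")
    } else {
      s <- next_host()
      ex <- tibble(start = s + 2500L, end = s + 2900L,
                   strand = "-", chrom = "chr1")
    }
    survivor_rows[[k]] <- ex |>
      mutate(transcript_id = ids[2], gene_id = ids[1], .before = 1)
    survivor_meta[[k]] <- tibble(
      gene_id = ids[1], transcript_id = ids[2], class = cls,
      call = call_plan[k], length = sum(ex$end - ex$start),
      chrom = ex$chrom[1], strand = ex$strand[1],
      span_start = min(ex$start), span_end = max(ex$end),
      tss = if (ex$strand[1] == "+") min(ex$start) else max(ex$end) - 1L
    )
  }
  survivors <- bind_rows(.tx_proto(), list_rbind(survivor_rows)) |>
    select(transcript_id, gene_id, chrom, strand, start, end)
  survivor_meta <- bind_rows(.survivor_meta_proto(), list_rbind(survivor_meta))

  # ---- decoy transfrags ---------------------------------------------------
  decoy_rows <- list()
  decoy_meta <- list()
  add_decoy <- function(ex, class, reason) {
    ids <- next_xloc()
    decoy_rows[[length(decoy_rows) + 1L]] <<- ex |>
      mutate(transcript_id = ids[2], gene_id = ids[1], .before = 1)
    decoy_meta[[length(decoy_meta) + 1L]] <<- tibble(
      gene_id = ids[1], transcript_id = ids[2], class = class, reason = reason,
      length = sum(ex$end - ex$start)
    )
  }
  for (s in eq_hosts) {
    add_decoy(tibble(chrom = "chr1", strand = "+",
                     start = c(s, s + 2500L), end = c(s + 300L, s + 3000L)),
              "=", "excluded_class")
  }
  for (s in j_hosts) {
    add_decoy(tibble(chrom = "chr1", strand = "+",
                     start = c(s + 100L, s + 2500L, s + 2800L),
                     end = c(s + 300L, s + 2600L, s + 2900L)),
              "j", "excluded_class")
  }
  for (s in o_hosts) {
    add_decoy(tibble(chrom = "chr1", strand = "+",
                     start = s + 2700L, end = s + 3200L),
              "o", "excluded_class")
  }
  for (s in tss_hosts) {
    add_decoy(tibble(chrom = "chr1", strand = "+",
                     start = s - 1300L, end = s - 1000L),
              "u", "excluded_tss")
  }
  for (i in seq_len(spec$n_short)) {
    b <- next_b()
    add_decoy(tibble(chrom = "chr1", strand = "+", start = b, end = b + 199L),
              "u", "excluded_length")
  }
  smallrna_records <- list()
  for (i in seq_len(spec$n_smallrna)) {
    b <- next_b()
    add_decoy(tibble(chrom = "chr1", strand = "+", start = b, end = b + 400L),
              "u", "excluded_smallrna")
    smallrna_records[[i]] <- tibble(
      chrom = "chr1", start = b + 100L, end = b + 250L,
      name = sprintf("tRNA%02d", i), score = 0, strand = "+"
    )
  }
  coding_genes <- character()
  for (i in seq_len(spec$n_coding)) {
    b <- next_b()
    add_decoy(tibble(chrom = "chr1", strand = "+",
                     start = c(b, b + 800L), end = c(b + 300L, b + 1200L)),
              "u", "excluded_coding")
    coding_genes <- c(coding_genes, decoy_meta[[length(decoy_meta)]]$gene_id)
  }
  decoys <- bind_rows(.tx_proto(), list_rbind(decoy_rows)) |>
    select(transcript_id, gene_id, chrom, strand, start, end)
  decoy_meta <- bind_rows(.decoy_meta_proto(), list_rbind(decoy_meta))
  # background tRNA records away from all genes
  smallrna_records[[length(smallrna_records) + 1L]] <- tibble(
    chrom = "chr1", start = 10000L, end = 10100L,
    name = "tRNA_bg", score = 0, strand = "+"
  )
  small_rna_sets <- list(tRNA = list_rbind(smallrna_records))

  # ---- annotated reference lncRNAs (add-back set) ------------------------
  c0 <- b0 + n_b_slots * slot + 50000L
  ab_base <- c0 + (seq_len(spec$n_addback) - 1L) * slot
  addback <- tibble(
    gene_id = sprintf("LNCG%03d", seq_len(spec$n_addback)),
    transcript_id = sprintf("LNCT%03d", seq_len(spec$n_addback)),
    chrom = "chr1", strand = "+", base = ab_base
  )
  addback_exons <- bind_rows(
    addback |> transmute(transcript_id, gene_id, chrom, strand,
                         start = base, end = base + 400L),
    addback |> transmute(transcript_id, gene_id, chrom, strand,
                         start = base + 1100L, end = base + 1500L)
  ) |> mutate(biotype = "lincRNA")
  n_ab_called <- ceiling(spec$n_addback / 2)
  addback_meta <- tibble(
    gene_id = addback$gene_id, transcript_id = addback$transcript_id,
    call = c(
      paste0(rep(groups, length.out = n_ab_called), ":lncRNA"),
      rep(NA_character_, spec$n_addback - n_ab_called)
    ),
    length = 800L, chrom = "chr1", strand = "+",
    span_start = addback$base, span_end = addback$base + 1500L,
    tss = addback$base
  )

  chr1_len <- c0 + spec$n_addback * slot + 20000L
  if (!is.null(spec$chrom_capacity) && chr1_len > spec$chrom_capacity) {
    abort(sprintf(
      "generate_fixtures: layout needs %d bases on chr1 but capacity is %d",
      chr1_len, spec$chrom_capacity
    ))
  }

  reference <- bind_rows(pc_exons, chr2_pc, addback_exons) |>
    arrange(transcript_id, start)
  assembly <- bind_rows(survivors, decoys) |> arrange(transcript_id, start)

  # ---- expression plan and counts ----------------------------------------
  samples <- tibble(
    sample = unlist(lapply(groups, function(g)
      paste0(g, "_", seq_len(spec$samples_per_group)))),
    group = rep(groups, each = spec$samples_per_group)
  )
  expressed <- bind_rows(
    survivor_meta |> filter(!is.na(call)) |> select(gene_id, call, length),
    addback_meta |> filter(!is.na(call)) |> select(gene_id, call, length)
  ) |>
    mutate(
      group = sub(":.*$", "", call),
      call_type = sub("^.*:", "", call),
      planted_count = as.integer(round(
        spec$target_fpkm * length * spec$library_size / 1e9
      ))
    )
  all_genes <- unique(c(assembly$gene_id, reference$gene_id))
  counts <- tibble(gene_id = sort(all_genes))
  pc_bg <- setNames(3000L + (seq_len(spec$n_pc) %% 7L) * 10L, pc$gene_id)
  filler <- "PCG9002"
  for (i in seq_len(nrow(samples))) {
    smp <- samples$sample[i]
    grp <- samples$group[i]
    v <- setNames(rep(0L, nrow(counts)), counts$gene_id)
    v[names(pc_bg)] <- pc_bg
    v["PCG9001"] <- 3000L
    pl <- expressed |> filter(group == grp)
    v[pl$gene_id] <- pl$planted_count
    v[filler] <- as.integer(spec$library_size - sum(v[names(v) != filler]))
    counts[[smp]] <- as.integer(v)
  }

  # ---- histone-mark peaks -------------------------------------------------
  tss_of <- bind_rows(
    survivor_meta |> select(gene_id, chrom, tss),
    addback_meta |> select(gene_id, chrom, tss)
  )
  mark_plan <- tibble(
    gene_id = character(), group = character(), chrom = character(),
    tss = integer(), idx = integer(), mark = character()
  )
  if (nrow(expressed)) mark_plan <- expressed |>
    left_join(tss_of, by = "gene_id") |>
    mutate(idx = row_number()) |>
    rowwise() |>
    reframe(
      gene_id = gene_id, group = group, chrom = chrom, tss = tss, idx = idx,
      mark = if (call_type == "lncRNA") {
        c("H3K4me3",
          if (idx %% 2 == 0) "H3K27ac",
          if (idx %% 3 == 0) "H3K4me1")
      } else {
        c("H3K4me1", "H3K27ac")
      }
    )
  peaks <- mark_plan |>
    transmute(
      group, mark, chrom,
      start = pmax(0L, tss - 200L), end = tss + 200L,
      score = 8 + (idx %% 5)
    )
  # a background peak per (group, mark) far from every TSS
  grid <- tidyr::crossing(group = groups,
                          mark = c("H3K4me3", "H3K27ac", "H3K4me1"))
  peaks <- bind_rows(
    peaks,
    grid |> mutate(chrom = "chr1", start = 3000L, end = 4000L, score = 5)
  ) |> arrange(group, mark, chrom, start)
  truth_marks <- mark_plan |>
    group_by(gene_id, group) |>
    summarise(marks_planted = paste(sort(unique(mark)), collapse = "+"),
              .groups = "drop")

  # ---- annotation sources -------------------------------------------------
  report_meta <- bind_rows(
    survivor_meta |> select(gene_id, transcript_id, chrom, strand,
                            span_start, span_end),
    addback_meta |> select(gene_id, transcript_id, chrom, strand,
                           span_start, span_end)
  ) |> mutate(idx = row_number())
  src_plan <- list(RefSeq = 2L, ENSEMBL = 3L, MiTranscriptome = 5L)
  first_exon <- bind_rows(survivors, addback_exons |> select(-biotype)) |>
    group_by(gene_id) |>
    slice_min(start, n = 1) |>
    ungroup()
  annotation_sources <- imap(src_plan, function(mod, nm) {
    flagged <- report_meta |> filter(idx %% mod == 0)
    first_exon |>
      filter(gene_id %in% flagged$gene_id) |>
      transmute(
        transcript_id = paste0(nm, "_", transcript_id),
        gene_id = paste0(nm, "_", gene_id),
        chrom, strand, start, end
      )
  })
  truth_sources <- report_meta |>
    transmute(
      gene_id,
      RefSeq = idx %% 2 == 0, ENSEMBL = idx %% 3 == 0,
      MiTranscriptome = idx %% 5 == 0
    )

  # ---- coding probabilities ----------------------------------------------
  candidates <- c(survivor_meta$gene_id, addback_meta$gene_id,
                  decoy_meta$gene_id[decoy_meta$reason == "excluded_coding"])
  coding_probs <- tibble(id = candidates) |>
    mutate(coding_prob = if_else(id %in% coding_genes,
                                 0.9, 0.05 + (row_number() %% 5) / 100))

  # ---- segments -----------------------------------------------------------
  segments <- list()
  truth_cnv <- tibble(gene_id = character(), source = character())
  if (spec$with_segments && sum(classes == "u") >= 2) {
    u_meta <- survivor_meta |> filter(class == "u")
    seg_cnv <- tibble(
      chrom = "chr1",
      start = u_meta$span_start[1] - 500L,
      end = u_meta$span_end[2] + 500L,
      score = 2
    )
    seg_far <- tibble(chrom = "chr1", start = pc_base[spec$n_pc] + 5000L,
                      end = pc_base[spec$n_pc] + 6000L, score = -1)
    segments$CNV <- bind_rows(seg_cnv, seg_far)
    segments$SNP <- tibble(
      chrom = "chr1", start = u_meta$span_start[1] + 100L,
      end = u_meta$span_start[1] + 200L, score = 5
    )
    truth_cnv <- bind_rows(
      tibble(gene_id = u_meta$gene_id[1:2], source = "CNV"),
      tibble(gene_id = u_meta$gene_id[1], source = "SNP")
    )
  }

  # ---- Hi-C ---------------------------------------------------------------
  hic_pairs <- NULL
  tads <- NULL
  truth_hic <- tibble(gene_id = character(), partner = character())
  if (spec$with_hic && sum(classes == "u") >= 1) {
    u_meta <- survivor_meta |> filter(class == "u")
    l1 <- u_meta[1, ]
    m1 <- list(start = pc_base[1], end = pc_base[1] + 3000L)
    boundary <- b0 + (n_b_slots %/% 2) * slot
    tads <- tibble(chrom = "chr1", start = c(0L, boundary),
                   end = c(boundary, chr1_len))
    ab1 <- addback_meta[1, ]
    m2 <- list(start = pc_base[2], end = pc_base[2] + 3000L)
    hic_pairs <- tibble(
      chrom1 = "chr1",
      start1 = c(l1$span_start - 100L, ab1$span_start - 100L, l1$span_start - 100L),
      end1 = c(l1$span_end + 100L, ab1$span_end + 100L, l1$span_end + 100L),
      chrom2 = c("chr1", "chr1", "chr2"),
      start2 = c(m1$start - 100L, m2$start - 100L, 19900L),
      end2 = c(m1$end + 100L, m2$end + 100L, 23100L),
      score = c(25, 18, 12)
    )
    truth_hic <- tibble(gene_id = l1$gene_id, partner = "PCG0001")
  }

  # ---- differential expression -------------------------------------------
  de_tables <- list()
  if (spec$with_de) {
    ids <- sort(c(survivor_meta$gene_id, addback_meta$gene_id))
    k <- seq_along(ids)
    de_tables[[paste0(groups[1], "_vs_", groups[2])]] <- tibble(
      gene_id = ids,
      log2fc = ((k * 7) %% 13 - 6) / 2,
      pvalue = ((k %% 9) + 1) / 100,
      fdr = pmin(1, ((k %% 9) + 1) / 50)
    )
  }

  # ---- genome -------------------------------------------------------------
  genome <- c(
    chr1 = .random_chrom(chr1_len),
    chr2 = .random_chrom(80000L)
  )

  # ---- truth tables -------------------------------------------------------
  truth_tx <- bind_rows(
    survivor_meta |> select(transcript_id, gene_id, class),
    decoy_meta |> select(transcript_id, gene_id, class)
  ) |> arrange(transcript_id)
  truth_genes <- bind_rows(
    survivor_meta |>
      transmute(
        gene_id, role = "novel_survivor", class,
        fate = "report",
        call_group = sub(":.*$", "", call),
        call_type = sub("^.*:", "", call),
        length
      ),
    addback_meta |>
      transmute(
        gene_id, role = "addback", class = NA_character_,
        fate = "report",
        call_group = sub(":.*$", "", call),
        call_type = sub("^.*:", "", call),
        length
      ),
    decoy_meta |>
      transmute(gene_id, role = "decoy", class, fate = reason,
                call_group = NA_character_, call_type = NA_character_, length)
  ) |>
    mutate(fate = if_else(gene_id %in% coding_genes, "excluded_coding", fate)) |>
    left_join(truth_marks |> rename(call_group2 = group), by = "gene_id") |>
    select(-any_of("call_group2")) |>
    left_join(truth_sources, by = "gene_id") |>
    arrange(gene_id)

  data <- list(
    assembly = assembly, reference = reference, counts = counts,
    samples = samples, peaks = peaks, small_rna_sets = small_rna_sets,
    annotation_sources = annotation_sources, coding_probs = coding_probs,
    genome = genome, segments = segments, hic_pairs = hic_pairs,
    tads = tads, de_tables = de_tables
  )
  truth <- list(
    genes = truth_genes, transcripts = truth_tx, marks = truth_marks,
    sources = truth_sources, hic = truth_hic, cnv = truth_cnv,
    expressed = expressed |> select(gene_id, group, call_type, planted_count)
  )
  phase1_config <- list(
    small_rna_sets = small_rna_sets,
    annotation_sources = annotation_sources
  )
  out <- list(data = data, truth = truth, phase1_config = phase1_config,
              spec = spec)
  if (!is.null(outdir)) {
    out$files <- .write_fixture_files(out, outdir)
    out$config <- file.path(outdir, "config.yaml")
  }
  out
}

.write_fixture_files <- function(fx, outdir) {
  d <- fx$data
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (subdir in c("peaks", "small_rna", "annotation", "segments", "de")) {
    dir.create(file.path(outdir, subdir), showWarnings = FALSE)
  }
  path <- function(...) file.path(outdir, ...)

  write_gtf(d$assembly, path("assembly.gtf"))
  write_gtf(d$reference, path("reference.gtf"))
  write_tsv(d$counts, path("counts.tsv"), progress = FALSE)
  write_tsv(d$samples, path("samples.tsv"), progress = FALSE)

  marks <- c("H3K4me3", "H3K27ac", "H3K4me1")
  groups <- unique(d$samples$group)
  peak_sheet <- tidyr::crossing(group = groups, mark = marks) |>
    mutate(file = file.path("peaks", paste0(group, "_", mark, ".bed")))
  for (i in seq_len(nrow(peak_sheet))) {
    rows <- d$peaks |>
      filter(group == peak_sheet$group[i], mark == peak_sheet$mark[i]) |>
      transmute(line = paste(chrom, start, end,
                             format(score, trim = TRUE), sep = "\t"))
    write_lines(rows$line, path(peak_sheet$file[i]))
  }
  write_tsv(peak_sheet, path("peak_sheet.tsv"), progress = FALSE)

  for (nm in names(d$small_rna_sets)) {
    s <- d$small_rna_sets[[nm]]
    write_lines(
      paste(s$chrom, s$start, s$end, s$name, format(s$score, trim = TRUE),
            s$strand, sep = "\t"),
      path("small_rna", paste0(nm, ".bed"))
    )
  }
  for (nm in names(d$annotation_sources)) {
    write_gtf(d$annotation_sources[[nm]],
              path("annotation", paste0(nm, ".gtf")))
  }
  write_tsv(d$coding_probs |> rename(gene_id = id), path("coding_probs.tsv"),
            progress = FALSE)

  fa <- unlist(lapply(names(d$genome), function(ch) {
    c(paste0(">", ch),
      substring(d$genome[[ch]],
                seq(1, nchar(d$genome[[ch]]), 60),
                pmin(seq(1, nchar(d$genome[[ch]]), 60) + 59,
                     nchar(d$genome[[ch]]))))
  }))
  write_lines(fa, path("genome.fa"))

  for (nm in names(d$segments)) {
    s <- d$segments[[nm]]
    write_lines(
      paste(s$chrom, s$start, s$end, format(s$score, trim = TRUE), sep = "\t"),
      path("segments", paste0(nm, ".bed"))
    )
  }
  if (!is.null(d$hic_pairs)) {
    p <- d$hic_pairs
    write_lines(
      paste(p$chrom1, p$start1, p$end1, p$chrom2, p$start2, p$end2,
            format(p$score, trim = TRUE), sep = "\t"),
      path("hic_pairs.tsv")
    )
    t <- d$tads
    write_lines(paste(t$chrom, t$start, t$end, sep = "\t"), path("tads.bed"))
  }
  for (nm in names(d$de_tables)) {
    write_tsv(d$de_tables[[nm]], path("de", paste0(nm, ".tsv")),
              progress = FALSE)
  }
  write_tsv(fx$truth$genes, path("truth_genes.tsv"), progress = FALSE)
  write_tsv(fx$truth$transcripts, path("truth_transcripts.tsv"),
            progress = FALSE)

  config <- list(
    assembly_gtf = "assembly.gtf",
    reference_gtf = "reference.gtf",
    counts = "counts.tsv",
    samples = "samples.tsv",
    peaks = "peak_sheet.tsv",
    small_rna = as.list(setNames(
      file.path("small_rna", paste0(names(d$small_rna_sets), ".bed")),
      names(d$small_rna_sets)
    )),
    annotation_sources = as.list(setNames(
      file.path("annotation", paste0(names(d$annotation_sources), ".gtf")),
      names(d$annotation_sources)
    )),
    coding_probs = "coding_probs.tsv",
    genome_fasta = "genome.fa",
    outdir = "results"
  )
  if (length(d$segments)) {
    config$segments <- as.list(setNames(
      file.path("segments", paste0(names(d$segments), ".bed")),
      names(d$segments)
    ))
  }
  if (!is.null(d$hic_pairs)) {
    config$hic_pairs <- "hic_pairs.tsv"
    config$tads <- "tads.bed"
  }
  if (length(d$de_tables)) {
    config$de_tables <- as.list(setNames(
      file.path("de", paste0(names(d$de_tables), ".tsv")),
      names(d$de_tables)
    ))
  }
  yaml::write_yaml(config, path("config.yaml"))
  list.files(outdir, recursive = TRUE, full.names = TRUE)
}
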