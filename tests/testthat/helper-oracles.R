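# Independent brute-force oracles and small constructors used across the
# suite.  The oracles enumerate base-level relations directly and share no
# code with the implementation paths they check.

tx_tbl <- function(tid, exons, strand = "+", chrom = "chr1", gid = tid) {
  tibble::tibble(
    transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
    start = as.integer(vapply(exons, `[`, numeric(1), 1)),
    end = as.integer(vapply(exons, `[`, numeric(1), 2))
  )
}

empty_tx <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer()
  )
}

# per-base overlap count between two single intervals
oracle_overlap <- function(a, b, strand_mode = "ignore") {
  if (a$chrom != b$chrom) return(0L)
  sa <- a$strand %||% "."
  sb <- b$strand %||% "."
  if (strand_mode == "same" &&
      sa != "." && sb != "." && sa != sb) return(0L)
  if (strand_mode == "opposite" &&
      sa != "." && sb != "." && sa == sb) return(0L)
  length(intersect(seq2(a$start, a$end - 1), seq2(b$start, b$end - 1)))
}

seq2 <- function(from, to) if (to < from) integer() else seq.int(from, to)

# per-base union of a set of intervals on one chromosome/strand
oracle_union_blocks <- function(starts, ends) {
  bases <- sort(unique(unlist(mapply(seq2, starts, ends - 1, SIMPLIFY = FALSE))))
  if (length(bases) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  brk <- c(0, which(diff(bases) > 1), length(bases))
  tibble::tibble(
    start = bases[brk[-length(brk)] + 1],
    end = bases[brk[-1]] + 1L
  )
}

# brute-force class code for one query against a reference transcript set,
# following the documented precedence by direct base-set enumeration
oracle_classify <- function(q, ref) {
  stopifnot(dplyr::n_distinct(q$transcript_id) == 1)
  bases <- function(tx) {
    paste(tx$chrom[1], unlist(mapply(seq2, tx$start, tx$end - 1, SIMPLIFY = FALSE)))
  }
  introns_of <- function(tx) {
    tx <- tx[order(tx$start), ]
    if (nrow(tx) < 2) return(tibble::tibble(start = integer(), end = integer()))
    tibble::tibble(start = tx$end[-nrow(tx)], end = tx$start[-1])
  }
  q_in <- introns_of(q)
  q_bases <- bases(q)
  q_intron_bases <- if (nrow(q_in)) {
    paste(q$chrom[1], unlist(mapply(seq2, q_in$start, q_in$end - 1, SIMPLIFY = FALSE)))
  } else character()
  span <- c(min(q$start), max(q$end))
  refs <- split(ref, ref$transcript_id)

  is_eq <- any(vapply(refs, function(r) {
    if (r$chrom[1] != q$chrom[1] || r$strand[1] != q$strand[1]) return(FALSE)
    r_in <- introns_of(r)
    if (nrow(q) >= 2 || nrow(r) >= 2) {
      nrow(r_in) == nrow(q_in) && nrow(q_in) > 0 &&
        all(r_in$start == q_in$start) && all(r_in$end == q_in$end)
    } else {
      length(intersect(q_bases, bases(r))) > 0
    }
  }, logical(1)))
  if (is_eq) return("=")

  is_j <- any(vapply(refs, function(r) {
    if (r$chrom[1] != q$chrom[1] || r$strand[1] != q$strand[1]) return(FALSE)
    r_in <- introns_of(r)
    nrow(r_in) > 0 && nrow(q_in) > 0 &&
      any(paste(q_in$start, q_in$end) %in% paste(r_in$start, r_in$end))
  }, logical(1)))
  if (is_j) return("j")

  is_o <- any(vapply(refs, function(r) {
    r$chrom[1] == q$chrom[1] && r$strand[1] == q$strand[1] &&
      length(intersect(q_bases, bases(r))) > 0
  }, logical(1)))
  if (is_o) return("o")

  is_x <- any(vapply(refs, function(r) {
    if (r$chrom[1] != q$chrom[1] || r$strand[1] == q$strand[1]) return(FALSE)
    if (length(intersect(q_bases, bases(r))) > 0) return(TRUE)
    r_in <- introns_of(r)
    if (nrow(r_in) == 0 || length(q_intron_bases) == 0) return(FALSE)
    r_intron_bases <- paste(
      r$chrom[1], unlist(mapply(seq2, r_in$start, r_in$end - 1, SIMPLIFY = FALSE))
    )
    length(intersect(q_intron_bases, r_intron_bases)) > 0
  }, logical(1)))
  if (is_x) return("x")

  is_i <- any(vapply(refs, function(r) {
    if (r$chrom[1] != q$chrom[1]) return(FALSE)
    r_in <- introns_of(r)
    nrow(r_in) > 0 && any(span[1] >= r_in$start & span[2] <= r_in$end)
  }, logical(1)))
  if (is_i) return("i")
  "u"
}

# exhaustive (start, frame) ORF scan
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < 3) return(0L)
  chars <- strsplit(s, "")[[1]]
  codon <- function(i) paste(chars[i:(i + 2)], collapse = "")
  best <- 0L
  for (i in seq_len(n - 2)) {
    if (codon(i) == "ATG") {
      j <- i + 3L
      while (j + 2L <= n) {
        if (codon(j) %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, j + 2L - i + 1L)
          break
        }
        j <- j + 3L
      }
    }
  }
  as.integer(best)
}

# random multi-exon transcript: distinct sorted breakpoints guarantee
# exon lengths >= 1 and inter-exon gaps >= 1
rand_tx <- function(tid, gid = tid, chroms = c("c1", "c2"), max_coord = 300,
                    max_exons = 3) {
  n_ex <- sample.int(max_exons, 1)
  pts <- sort(sample.int(max_coord + 1, 2 * n_ex) - 1L)
  tibble::tibble(
    transcript_id = tid, gene_id = gid,
    chrom = sample(chroms, 1), strand = sample(c("+", "-"), 1),
    start = pts[seq(1, 2 * n_ex, 2)], end = pts[seq(2, 2 * n_ex, 2)]
  )
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# phase1 + coding gate on an in-memory fixture, as run_pipeline composes them
run_phase1_with_gate <- function(fx) {
  p1 <- run_phase1(fx$data$assembly, fx$data$reference, fx$phase1_config)
  probs <- fx$data$coding_probs |> dplyr::rename(gene_id = id)
  gate <- suppressWarnings(apply_coding_gate(p1$loci, probs))
  list(
    phase1 = p1, gate = gate,
    loci = gate$retained,
    ledger = dplyr::bind_rows(tibble::as_tibble(p1$ledger), gate$ledger)
  )
}

`%||%` <- rlang::`%||%`
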