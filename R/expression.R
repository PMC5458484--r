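# Gene-level FPKM from raw counts, and cutoff-aware per-group summaries.

#' Compute gene-level FPKM from raw counts
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (length(g) * library_size(s)).  The
#' library size of a sample defaults to the column sum of the supplied count
#' table (which should cover the putative lncRNA assembly and the reference
#' annotation together), so FPKM is invariant under uniform scaling of a
#' sample's counts.
#'
#' @param counts Wide count tibble (`gene_id` plus one column per sample).
#' @param lengths Gene lengths in nt: tibble with `gene_id` and `length`
#'   (e.g. from [locus_lengths()]) or a named numeric vector.
#' @param library_sizes Optional named vector of per-sample library sizes;
#'   derived from `counts` when `NULL`.
#' @return Wide FPKM tibble with the same shape as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, library_sizes = NULL) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "gene_id")
  if (!"gene_id" %in% names(counts) || length(samples) == 0) {
    abort("compute_fpkm: counts must have gene_id plus sample columns")
  }
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$gene_id)
  }
  missing <- setdiff(counts$gene_id, names(lengths))
  if (length(missing)) {
    abort(sprintf("compute_fpkm: no length for gene '%s'", missing[1]))
  }
  len <- as.numeric(lengths[counts$gene_id])
  if (any(len <= 0)) abort("compute_fpkm: gene lengths must be > 0")
  mat <- as.matrix(counts[samples])
  if (is.null(library_sizes)) {
    library_sizes <- colSums(mat)
  } else {
    missing <- setdiff(samples, names(library_sizes))
    if (length(missing)) {
      abort(sprintf("compute_fpkm: no library size for sample '%s'", missing[1]))
    }
    library_sizes <- library_sizes[samples]
  }
  if (any(library_sizes <= 0)) {
    abort("compute_fpkm: library sizes must be > 0")
  }
  fpkm <- sweep(mat * 1e9 / len, 2, as.numeric(library_sizes), "/")
  out <- counts
  out[samples] <- as_tibble(fpkm)
  out
}

#' Cutoff-aware per-group FPKM summaries
#'
#' For each gene and sample group, samples whose FPKM is at or below the
#' cutoff are excluded before averaging ("above" is strict `>`); the mean is
#' 0 with `n_above = 0` when no sample exceeds the cutoff, keeping the
#' summary rectangular.  The fraction of samples above the cutoff is taken
#' over the full group size.
#'
#' @param fpkm Wide FPKM tibble from [compute_fpkm()].
#' @param samples Sample sheet tibble with `sample` and the grouping column.
#' @param cutoff FPKM cutoff (default 0.5).
#' @param group_column Name of the grouping column (default `"group"`).
#' @return Tibble with columns `gene_id`, `group`, `mean_fpkm`, `n_above`,
#'   `n_samples`, `fraction_above`.
#' @export
group_summaries <- function(fpkm, samples, cutoff = 0.5, group_column = "group") {
  fpkm <- as_tibble(fpkm)
  samples <- as_tibble(samples)
  if (!group_column %in% names(samples)) {
    abort(sprintf("group_summaries: no grouping column '%s'", group_column))
  }
  sheet <- samples |>
    transmute(sample, group = .data[[group_column]])
  if (any(is.na(sheet$group) | !nzchar(sheet$group))) {
    abort("group_summaries: every sample must be assigned to a group")
  }
  sample_cols <- setdiff(names(fpkm), "gene_id")
  missing <- setdiff(sample_cols, sheet$sample)
  if (length(missing)) {
    abort(sprintf("group_summaries: sample '%s' is not on the sample sheet", missing[1]))
  }
  fpkm |>
    pivot_longer(-gene_id, names_to = "sample", values_to = "fpkm") |>
    inner_join(sheet, by = "sample") |>
    group_by(gene_id, group) |>
    summarise(
      mean_fpkm = if (any(fpkm > cutoff)) mean(fpkm[fpkm > cutoff]) else 0,
      n_above = sum(fpkm > cutoff),
      n_samples = n(),
      .groups = "drop"
    ) |>
    mutate(fraction_above = n_above / n_samples)
}
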