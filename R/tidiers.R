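# broom-style accessors for pipeline results.

#' Tidy a pipeline run into the feature-record tibble
#'
#' @param x An `lncscreen_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The comprehensive feature-record tibble (one row per putative
#'   lncRNA).
#' @export
tidy.lncscreen_run <- function(x, ...) {
  as_tibble(x$records)
}

#' One-row summary of a pipeline run
#'
#' @param x An `lncscreen_run` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble: putative lncRNA count, novel/annotated split,
#'   unique group-enriched lncRNA and eRNA counts, group and sample counts,
#'   coding-gate exclusions and Hi-C interacting lncRNAs.
#' @export
glance.lncscreen_run <- function(x, ...) {
  gate <- as_tibble(x$ledger) |> filter(step == "coding_potential_gate")
  tibble(
    n_putative_lncrnas = nrow(x$records),
    n_novel = sum(x$records$gencode == "novel"),
    n_annotated = sum(x$records$gencode == "annotated"),
    n_lncrna_genes = n_distinct(x$calls$gene_id[x$calls$call == "lncRNA"]),
    n_erna_genes = n_distinct(x$calls$gene_id[x$calls$call == "eRNA"]),
    n_groups = n_distinct(x$calls$group),
    n_samples = length(setdiff(names(x$fpkm), "gene_id")),
    n_coding_excluded = if (nrow(gate)) gate$n_excluded else NA_integer_,
    n_hic_interacting = n_distinct(x$hic$gene_id)
  )
}

#' Tidy a filtration ledger
#'
#' @param x An `lnc_ledger` tibble.
#' @param ... Unused.
#' @return The ledger as a plain tibble.
#' @export
tidy.lnc_ledger <- function(x, ...) {
  class(x) <- setdiff(class(x), "lnc_ledger")
  as_tibble(x)
}
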