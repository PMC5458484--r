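# ggplot2 views of the filtration ledger and the pie matrix.

#' Plot a filtration ledger as a step-by-step bar chart
#'
#' @param object An `lnc_ledger` (e.g. from [run_phase1()] or
#'   [run_pipeline()]).
#' @param ... Unused.
#' @return A ggplot object: retained counts per filtration step, annotated
#'   with exclusions/additions.
#' @export
autoplot.lnc_ledger <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      step = factor(step, levels = rev(unique(step))),
      delta = case_when(
        !is.na(n_added) ~ sprintf("+%d", n_added),
        !is.na(n_excluded) & n_excluded > 0 ~ sprintf("-%d", n_excluded),
        .default = ""
      )
    )
  ggplot(df, aes(x = step, y = n_retained, fill = unit)) +
    geom_col() +
    geom_text(aes(label = delta), hjust = -0.1, size = 3) +
    coord_flip() +
    labs(
      x = NULL, y = "entities retained",
      title = "lncRNA filtration cascade",
      fill = "counting unit"
    ) +
    theme_minimal()
}

#' @rdname autoplot.lnc_ledger
#' @param ledger An `lnc_ledger`.
#' @export
plot_ledger <- function(ledger, ...) autoplot.lnc_ledger(ledger, ...)

#' Plot a pie matrix of group-enriched lncRNA counts
#'
#' Dot-matrix rendering of the pie-matrix statistics: the diagonal shows
#' per-group called-gene counts split by histone-mark-combination category;
#' off-diagonal cells show pairwise group overlaps.
#'
#' @param object An `lnc_pie_matrix` from [pie_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_pie_matrix <- function(object, ...) {
  df <- as_tibble(object) |> filter(n > 0, category != "(all)")
  totals <- as_tibble(object) |> filter(category == "(all)")
  ggplot(df, aes(x = category, y = 1, size = n, colour = category)) +
    geom_point() +
    geom_text(aes(label = n), size = 3, vjust = -1.5, colour = "black") +
    facet_grid(group_a ~ group_b) +
    scale_size_area(max_size = 8) +
    labs(
      x = "histone-mark category", y = NULL,
      title = "Group-enriched lncRNAs by histone-mark category",
      subtitle = sprintf(
        "diagonal: per-group totals; off-diagonal: pairwise overlaps (total called: %d)",
        sum(totals$n[totals$group_a == totals$group_b])
      )
    ) +
    theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' @rdname autoplot.lnc_pie_matrix
#' @param pm An `lnc_pie_matrix`.
#' @export
plot_pie_matrix <- function(pm, ...) autoplot.lnc_pie_matrix(pm, ...)
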