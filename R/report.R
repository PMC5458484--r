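# Phase-II classification: group-enriched lncRNA / enhancer-RNA calls from
# cutoff-aware group means plus histone-mark presence, pie-matrix
# statistics, supervised ordering, and the comprehensive feature report.

#' Construct group-call rules
#'
#' A call rule is a set of histone marks that must be present and a set
#' that must be absent at the extended TSS region, combined with a group
#' mean-FPKM cutoff.  Defaults: a lncRNA is expressed in a group when its
#' cutoff-aware mean FPKM exceeds the cutoff while H3K4me3 overlaps its
#' extended TSS; an enhancer-RNA additionally requires H3K4me1 and H3K27ac
#' but no H3K4me3.  The two rules must be mutually exclusive (under the
#' defaults H3K4me3 presence separates them); rules that can hold
#' simultaneously are rejected.
#'
#' @param lncrna_required,lncrna_forbidden Marks required/forbidden for the
#'   lncRNA call.
#' @param erna_required,erna_forbidden Marks required/forbidden for the
#'   enhancer-RNA call.
#' @param expressed_cutoff Group mean-FPKM cutoff for the lncRNA call
#'   (default 0.5).
#' @param erna_cutoff Cutoff for the eRNA call; defaults to
#'   `expressed_cutoff`.
#' @return Object of class `lnc_call_rules`.
#' @export
group_call_rules <- function(lncrna_required = "H3K4me3",
                             lncrna_forbidden = character(),
                             erna_required = c("H3K4me1", "H3K27ac"),
                             erna_forbidden = "H3K4me3",
                             expressed_cutoff = 0.5,
                             erna_cutoff = expressed_cutoff) {
  disjoint <- length(intersect(lncrna_required, erna_forbidden)) > 0 ||
    length(intersect(erna_required, lncrna_forbidden)) > 0
  if (!disjoint) {
    abort(paste(
      "group_call_rules: the lncRNA and eRNA rules can be satisfied",
      "simultaneously; one rule's required marks must intersect the other's",
      "forbidden marks"
    ))
  }
  structure(
    list(
      lncrna = list(required = lncrna_required, forbidden = lncrna_forbidden,
                    cutoff = expressed_cutoff),
      erna = list(required = erna_required, forbidden = erna_forbidden,
                  cutoff = erna_cutoff),
      marks = sort(unique(c(lncrna_required, lncrna_forbidden,
                            erna_required, erna_forbidden)))
    ),
    class = "lnc_call_rules"
  )
}

.rule_holds <- function(present, rule, mean_fpkm) {
  mean_fpkm > rule$cutoff &
    Reduce(`&`, lapply(rule$required, function(m) present[[m]]), TRUE) &
    !Reduce(`|`, lapply(rule$forbidden, function(m) present[[m]]), FALSE)
}

#' Call group-enriched lncRNAs and enhancer-RNAs
#'
#' Combines the cutoff-aware group summaries with histone-mark presence at
#' the extended TSS region: per (gene, group), the call is `"lncRNA"` when
#' the lncRNA rule holds, `"eRNA"` when the eRNA rule holds, `"none"`
#' otherwise.  A gene may be called in several groups.
#'
#' @param summaries Tibble from [group_summaries()].
#' @param marks Tibble from [assign_marks()].
#' @param rules Rules from [group_call_rules()].
#' @return Tibble with columns `gene_id`, `group`, `call` and one logical
#'   presence column per rule mark.
#' @export
call_groups <- function(summaries, marks, rules = group_call_rules()) {
  if (!is(rules, "lnc_call_rules")) {
    abort("call_groups: rules must come from group_call_rules()")
  }
  summaries <- as_tibble(summaries)
  marks <- as_tibble(marks)
  mark_names <- rules$marks
  wide <- summaries |> select(gene_id, group, mean_fpkm)
  for (m in mark_names) {
    present <- marks |> filter(mark == m) |> distinct(gene_id, group)
    wide[[m]] <- paste(wide$gene_id, wide$group) %in%
      paste(present$gene_id, present$group)
  }
  present <- wide[mark_names]
  is_lnc <- .rule_holds(present, rules$lncrna, wide$mean_fpkm)
  is_erna <- .rule_holds(present, rules$erna, wide$mean_fpkm)
  wide |>
    mutate(call = case_when(is_lnc ~ "lncRNA", is_erna ~ "eRNA",
                            .default = "none")) |>
    select(gene_id, group, call, all_of(mark_names))
}

#' Pie-matrix statistics of called lncRNAs
#'
#' Counts called genes per group and histone-mark-combination category
#' (the diagonal of the pie matrix) and, for every group pair, the genes
#' called in both groups in the same category plus the total overlap
#' (off-diagonal).  Categories are the observed combinations of the rule
#' marks, written as `+`-joined sorted mark names (`"(none)"` when no rule
#' mark is present); `"(all)"` rows carry the per-pair and per-group totals.
#'
#' @param calls Tibble from [call_groups()] (with mark presence columns).
#' @param mark_names Marks spanning the category space; defaults to the
#'   presence columns found in `calls`.
#' @return Object of class `lnc_pie_matrix`: tibble with columns
#'   `group_a`, `group_b`, `category`, `n` (symmetric in the group pair;
#'   `group_a == group_b` rows are the diagonal).
#' @export
pie_matrix <- function(calls, mark_names = NULL) {
  calls <- as_tibble(calls)
  if (is.null(mark_names)) {
    mark_names <- setdiff(names(calls), c("gene_id", "group", "call"))
  }
  called <- calls |> filter(call != "none")
  category <- vapply(seq_len(nrow(called)), function(i) {
    present <- mark_names[unlist(called[i, mark_names])]
    if (length(present) == 0) "(none)" else paste(sort(present), collapse = "+")
  }, character(1))
  called$category <- if (nrow(called)) category else character()
  groups <- sort(unique(calls$group))
  cells <- list()
  for (a in groups) {
    ga <- called |> filter(group == a)
    for (b in groups) {
      gb <- called |> filter(group == b)
      shared <- inner_join(
        ga |> select(gene_id, category),
        gb |> select(gene_id, category),
        by = "gene_id", suffix = c("_a", "_b")
      ) |>
        filter(category_a == category_b)
      by_cat <- shared |> count(category = category_a)
      cells[[length(cells) + 1L]] <- bind_rows(
        by_cat,
        tibble(
          category = "(all)",
          n = n_distinct(inner_join(
            ga |> select(gene_id), gb |> select(gene_id), by = "gene_id"
          )$gene_id)
        )
      ) |>
        mutate(group_a = a, group_b = b, .before = 1)
    }
  }
  out <- list_rbind(cells) |>
    select(group_a, group_b, category, n) |>
    arrange(group_a, group_b, category)
  structure(out, class = c("lnc_pie_matrix", class(tibble())))
}

#' Supervised ordering of called genes
#'
#' Produces the row order of a supervised expression heatmap: groups in the
#' supplied order, and within each group its called genes by descending
#' group mean FPKM (ties by gene id).  Genes called in several groups
#' appear once per group.
#'
#' @param calls Tibble from [call_groups()].
#' @param summaries Tibble from [group_summaries()] (provides the ordering
#'   means).
#' @param group_order Character vector of groups; defaults to sorted unique
#'   groups.
#' @return Tibble with columns `group`, `gene_id`, `mean_fpkm`, `position`.
#' @export
supervised_order <- function(calls, summaries, group_order = NULL) {
  calls <- as_tibble(calls)
  summaries <- as_tibble(summaries)
  group_order <- group_order %||% sort(unique(calls$group))
  out <- calls |>
    filter(call != "none", group %in% group_order) |>
    left_join(summaries |> select(gene_id, group, mean_fpkm),
              by = c("gene_id", "group")) |>
    mutate(group = factor(group, levels = group_order)) |>
    arrange(group, desc(mean_fpkm), gene_id) |>
    transmute(group = as.character(group), gene_id, mean_fpkm)
  out |> mutate(position = row_number())
}

#' Attach differential-expression results to feature records
#'
#' Appends, for each named comparison, three columns
#' (`<name>_log2fc`, `<name>_pvalue`, `<name>_fdr`); genes absent from a
#' table get `NA` cells.  Column order follows the order of `de_tables`.
#'
#' @param records Feature-record tibble with a `gene_id` column.
#' @param de_tables Named list of tibbles with columns `gene_id`, `log2fc`,
#'   `pvalue`, `fdr`.
#' @return `records` with the comparison columns appended.
#' @export
attach_de_results <- function(records, de_tables = list()) {
  records <- as_tibble(records)
  if (length(de_tables) == 0) return(records)
  nms <- names(de_tables)
  if (is.null(nms) || any(!nzchar(nms))) {
    abort("attach_de_results: de_tables must be named")
  }
  if (anyDuplicated(nms)) abort("attach_de_results: duplicate comparison names")
  for (nm in nms) {
    de <- as_tibble(de_tables[[nm]]) |>
      select(gene_id, log2fc, pvalue, fdr) |>
      distinct(gene_id, .keep_all = TRUE)
    names(de)[-1] <- paste0(nm, "_", names(de)[-1])
    records <- records |> left_join(de, by = "gene_id")
  }
  records
}

# deterministic cell formatting for byte-stable reports
.fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
}

#' Write the comprehensive feature report
#'
#' Writes the per-lncRNA feature table as a TSV (the canonical, spreadsheet
#' -filterable artifact) and as a static sortable HTML table of the same
#' cells.  Numeric cells are formatted to fixed precision so re-runs on
#' identical inputs are byte-identical.
#'
#' @param records Feature-record tibble (one row per putative lncRNA).
#' @param path Output TSV path; the HTML twin replaces the extension with
#'   `.html`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_feature_report <- function(records, path) {
  records <- as_tibble(records)
  out <- records
  for (col in names(out)) {
    x <- out[[col]]
    if (is.numeric(x) && !is.integer(x)) {
      digits <- if (grepl("pct_above", col)) 2L else 4L
      out[[col]] <- .fmt_num(x, digits)
    } else if (is.integer(x)) {
      out[[col]] <- ifelse(is.na(x), "", as.character(x))
    } else if (is.logical(x)) {
      out[[col]] <- ifelse(is.na(x), "", ifelse(x, "yes", "no"))
    } else {
      out[[col]] <- ifelse(is.na(x), "", as.character(x))
    }
  }
  write_tsv(out, path, progress = FALSE)
  html_path <- sub("\\.[^.]*$", ".html", path)
  if (identical(html_path, path)) html_path <- paste0(path, ".html")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  header <- paste0("<th>", esc(names(out)), "</th>", collapse = "")
  rows <- vapply(seq_len(nrow(out)), function(i) {
    paste0("<tr>", paste0("<td>", esc(unlist(out[i, ])), "</td>", collapse = ""), "</tr>")
  }, character(1))
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'><title>Putative lncRNA feature report</title>",
    "<style>table{border-collapse:collapse;font-family:sans-serif;font-size:12px}",
    "td,th{border:1px solid #ccc;padding:2px 6px}th{cursor:pointer;background:#eee}</style>",
    "<script>function sortBy(c){var t=document.getElementById('report');",
    "var r=Array.from(t.tBodies[0].rows);var d=t.dataset.dir!=='asc';",
    "r.sort(function(a,b){var x=a.cells[c].innerText,y=b.cells[c].innerText;",
    "var nx=parseFloat(x),ny=parseFloat(y);",
    "if(!isNaN(nx)&&!isNaN(ny)){return d?nx-ny:ny-nx;}",
    "return d?x.localeCompare(y):y.localeCompare(x);});",
    "t.dataset.dir=d?'asc':'desc';r.forEach(function(e){t.tBodies[0].appendChild(e);});}",
    "window.onload=function(){var h=document.querySelectorAll('th');",
    "h.forEach(function(e,i){e.onclick=function(){sortBy(i);};});};</script>",
    "</head><body>",
    "<table id='report'><thead><tr>", header, "</tr></thead><tbody>",
    rows,
    "</tbody></table></body></html>"
  )
  write_lines(html, html_path)
  invisible(c(tsv = path, html = html_path))
}
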