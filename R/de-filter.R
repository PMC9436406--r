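de_required_columns <- c("gene_id", "total_reads", "log2fc", "p_value", "p_adjusted")

check_de_table <- function(table) {
  missing_cols <- setdiff(de_required_columns, names(table))
  if (length(missing_cols) > 0)
    stop("DE table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  invisible(table)
}

#' First-stage significance flags for a differential-expression table
#'
#' A gene is initially significant when its adjusted p-value is at most
#' `p_adj_max` and its absolute log2 fold change is at least `lfc_min`
#' (both thresholds inclusive; defaults 0.05 and 1). Direction is `up` for
#' log2fc >= `lfc_min`, `down` for log2fc <= -`lfc_min`, otherwise `none`.
#'
#' @param table data.frame with columns `gene_id`, `total_reads`, `log2fc`,
#'   `p_value`, `p_adjusted`.
#' @param p_adj_max adjusted p-value threshold.
#' @param lfc_min absolute log2 fold-change threshold.
#' @return The table with `initial_significant` (logical) and `direction`
#'   columns added.
#' @export
initial_significance <- function(table, p_adj_max = 0.05, lfc_min = 1) {
  check_de_table(table)
  table$direction <- ifelse(table$log2fc >= lfc_min, "up",
                     ifelse(table$log2fc <= -lfc_min, "down", "none"))
  table$initial_significant <-
    table$p_adjusted <= p_adj_max & abs(table$log2fc) >= lfc_min
  table
}

#' Second-stage strict filter
#'
#' Restricts to genes with (raw, by default) p-value at most `p_max` and at
#' least `min_reads` aligned reads — transcripts below 350 reads are
#' excluded as too low-abundance to trust. The retained list is ordered
#' deterministically: ascending p, ties by descending |log2fc|, then
#' gene_id, so the top-gene list is reproducible.
#'
#' @inheritParams initial_significance
#' @param p_max p-value cutpoint (default 1e-4).
#' @param min_reads minimum aligned read count (default 350; genes with
#'   fewer are excluded).
#' @param use_adjusted apply `p_max` to `p_adjusted` instead of `p_value`.
#' @return The retained subset, ordered as described, with a
#'   `strict_significant` column (all TRUE).
#' @export
strict_filter <- function(table, p_max = 1e-4, min_reads = 350,
                          use_adjusted = FALSE) {
  check_de_table(table)
  p <- if (use_adjusted) table$p_adjusted else table$p_value
  keep <- p <= p_max & table$total_reads >= min_reads
  out <- table[keep, , drop = FALSE]
  p_kept <- p[keep]
  out <- out[order(p_kept, -abs(out$log2fc), out$gene_id), , drop = FALSE]
  out$strict_significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarise a flagged differential-expression table
#'
#' Counts and percentages of initially significant genes by direction, and
#' the size of the strict list. Percentages are kept at full precision here;
#' [render_summary()] rounds them to one decimal for display.
#'
#' @inheritParams initial_significance
#' @param p_max,min_reads,use_adjusted passed to [strict_filter()].
#' @return List: `n_total`, `n_up`, `n_down`, `pct_up`, `pct_down`,
#'   `n_strict`.
#' @export
summarize_de <- function(table, p_adj_max = 0.05, lfc_min = 1,
                         p_max = 1e-4, min_reads = 350, use_adjusted = FALSE) {
  if (nrow(table) == 0)
    return(list(n_total = 0L, n_up = 0L, n_down = 0L,
                pct_up = 0, pct_down = 0, n_strict = 0L))
  if (!"initial_significant" %in% names(table))
    table <- initial_significance(table, p_adj_max, lfc_min)
  n <- nrow(table)
  n_up <- sum(table$initial_significant & table$direction == "up")
  n_down <- sum(table$initial_significant & table$direction == "down")
  strict <- strict_filter(table, p_max, min_reads, use_adjusted)
  list(
    n_total = n,
    n_up = n_up,
    n_down = n_down,
    pct_up = 100 * n_up / n,
    pct_down = 100 * n_down / n,
    n_strict = nrow(strict)
  )
}
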