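#' Run the full slice-culture drug-response analysis
#'
#' End-to-end orchestration: simulate (or ingest) annotation measurements,
#' compute per-slice readouts, average duplicates, assemble cohort matrices,
#' run paired exact Wilcoxon tests against the control with
#' Benjamini-Hochberg adjustment, a Friedman test with Kendall's W per
#' readout, map damage at each condition to Evans regression grades, and
#' (optionally) apply the two-stage filter to a differential-expression
#' table. Each stage aborts with a stage-named error on invalid input.
#'
#' @param config a [synthetic_config()]; used to simulate the cohort when
#'   `annotations` is NULL, and to define the condition order either way.
#' @param annotations optional annotation table (as read by
#'   [read_annotation_table()]); overrides simulation.
#' @param de_table optional differential-expression results table.
#' @param control control condition label (must be in the condition set).
#' @param family comparison family for the BH adjustment; defaults to all
#'   non-control conditions.
#' @param readouts readouts to test; any of `"viability_pct"`,
#'   `"outgrowth_pct"`, `"tvi"`.
#' @param grouping a [morphology_grouping()] (carries the TVI weights).
#' @param out_dir optional directory; when given, every artifact is written
#'   there (per-slice readouts, cohort matrices, test tables, JSON summary,
#'   run manifest).
#' @param zero_method zero-difference handling for the signed-rank test.
#' @return Object of class `slicequant_run`: list with `config`, `truth`
#'   (NULL for ingested data), `slice_readouts`, `condition_summaries`,
#'   `matrices` (per readout), `tests` (per readout), `friedman` (per
#'   readout), `evans` (grade per culture x condition from viability),
#'   `normality`, `de_summary`, `de_table`.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         annotations = NULL,
                         de_table = NULL,
                         control = "control_72h",
                         family = NULL,
                         readouts = c("viability_pct", "outgrowth_pct", "tvi"),
                         grouping = morphology_grouping(),
                         out_dir = NULL,
                         zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  readouts <- match.arg(readouts, several.ok = TRUE)
  conditions <- config$conditions$condition
  if (!control %in% conditions)
    stop("configuration: control condition '", control,
         "' is not in the condition set")
  family <- family %||% setdiff(conditions, control)

  truth <- NULL
  if (is.null(annotations)) {
    cohort <- generate_cohort(config)
    annotations <- cohort$annotations
    truth <- cohort$truth
  } else {
    annotations <- tryCatch(validate_annotations(annotations),
                            error = function(e) stop("ingest: ", conditionMessage(e)))
  }
  message(sprintf("ingest: %d annotation records, %d slices",
                  nrow(annotations), length(unique(annotations$slice_id))))

  slices <- tryCatch(quantify_slices(annotations, grouping),
                     error = function(e) stop("readouts: ", conditionMessage(e)))
  message(sprintf("readouts: %d slices quantified", nrow(slices)))

  summaries <- average_duplicates(slices)
  if (length(unique(summaries$culture_id)) < 2)
    stop("stats: need at least 2 cultures for paired inference")

  matrices <- tests <- friedman <- normality <- list()
  selenite <- config$conditions$condition[config$conditions$selenite]
  for (rd in readouts) {
    cm <- cohort_matrix(summaries, rd, conditions = conditions,
                        selenite_conditions = selenite)
    keep <- colSums(!is.na(cm$matrix)) > 0   # drop all-NA readouts (area mode)
    if (!keep[control] || sum(keep) < 2) next
    matrices[[rd]] <- cm
    fam_rd <- intersect(family, colnames(cm$matrix)[keep])
    tests[[rd]] <- compare_conditions(cm$matrix[, keep, drop = FALSE], control,
                                      family = fam_rd,
                                      zero_method = zero_method)
    friedman[[rd]] <- suppressMessages(
      friedman_test(cm$matrix[, keep, drop = FALSE]))
    normality[[rd]] <- normality_screen(cm$matrix)
  }
  message(sprintf("stats: %d readout(s) tested against '%s'",
                  length(tests), control))

  evans <- NULL
  if (!is.null(matrices$viability_pct)) {
    vm <- matrices$viability_pct$matrix
    evans <- matrix(evans_grade(pmin(pmax(100 - vm, 0), 100)),
                    nrow = nrow(vm), dimnames = dimnames(vm))
  }

  de_summary <- NULL
  if (!is.null(de_table)) {
    de_table <- initial_significance(de_table)
    de_summary <- summarize_de(de_table)
    message(sprintf("de_filter: %d genes, %d up / %d down, %d strict",
                    de_summary$n_total, de_summary$n_up, de_summary$n_down,
                    de_summary$n_strict))
  }

  bundle <- structure(list(
    config = config, truth = truth, control = control, family = family,
    slice_readouts = slices, condition_summaries = summaries,
    matrices = matrices, tests = tests, friedman = friedman,
    evans = evans, normality = normality,
    de_summary = de_summary, de_table = de_table
  ), class = "slicequant_run")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write every artifact of a pipeline run to a directory
#'
#' Per-slice readouts, condition summaries, one cohort-matrix CSV per
#' readout, the paired-test table, a JSON summary (medians, Friedman blocks,
#' Evans grades, DE summary) and a run manifest holding the full
#' configuration and seed — enough to reproduce the bundle byte-identically.
#'
#' @param bundle a `slicequant_run`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_readout_table(bundle$slice_readouts, fp("slice_readouts.csv"))
  write_readout_table(bundle$condition_summaries, fp("condition_summaries.csv"))
  for (rd in names(bundle$matrices)) {
    m <- as.data.frame(bundle$matrices[[rd]]$matrix)
    m <- cbind(culture_id = rownames(m), m)
    write_readout_table(m, fp(sprintf("matrix_%s.csv", rd)))
  }
  if (length(bundle$tests) > 0) {
    all_tests <- do.call(rbind, lapply(names(bundle$tests), function(rd)
      cbind(readout = rd, bundle$tests[[rd]])))
    write_readout_table(all_tests, fp("paired_tests.csv"))
  }
  if (!is.null(bundle$de_table))
    write_readout_table(bundle$de_table, fp("de_flagged.csv"))

  summary_json <- list(
    condition_medians = lapply(bundle$matrices, function(m)
      as.list(m$condition_medians)),
    pooled_selenite_median = lapply(bundle$matrices, function(m)
      m$pooled_selenite_median),
    friedman = lapply(bundle$friedman, function(f)
      f[c("n_blocks", "k_treatments", "statistic", "df", "p_value", "kendalls_w")]),
    evans_grades = if (!is.null(bundle$evans))
      as.list(as.data.frame(bundle$evans)),
    de_summary = bundle$de_summary
  )
  jsonlite::write_json(summary_json, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "slicequant",
    package_version = as.character(utils::packageVersion("slicequant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = bundle$config$seed,
    control = bundle$control,
    family = bundle$family,
    config = unclass(bundle$config)
  )
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  invisible(out_dir)
}

#' Render a one-page text summary of a pipeline run
#'
#' Markdown-flavoured report: per-condition medians for each readout (one
#' decimal), the number of cultures with a major response (>90% damaged,
#' Evans III-IV) per condition, the paired-test table, Friedman blocks and
#' the DE summary (or "not run").
#'
#' @param bundle a `slicequant_run`.
#' @return Character scalar (the report); also returned by [print()] methods.
#' @export
render_summary <- function(bundle) {
  out <- c("# Slice-culture drug-response summary", "")
  fmt1 <- function(x) formatC(x, format = "f", digits = 1)

  for (rd in names(bundle$matrices)) {
    cm <- bundle$matrices[[rd]]
    out <- c(out, sprintf("## %s", rd),
             sprintf("- condition medians: %s",
                     paste(sprintf("%s = %s", names(cm$condition_medians),
                                   fmt1(cm$condition_medians)), collapse = ", ")),
             sprintf("- pooled selenite median: %s",
                     fmt1(cm$pooled_selenite_median)))
    if (!is.null(bundle$normality[[rd]]))
      out <- c(out, sprintf("- Shapiro-Wilk (pooled values): W = %.3f, p = %.3g",
                            bundle$normality[[rd]]$statistic,
                            bundle$normality[[rd]]$p_value))
    tt <- bundle$tests[[rd]]
    out <- c(out, "", "| comparison | n_eff | W | p | p_adj |",
             "|---|---|---|---|---|",
             sprintf("| %s | %d | %g | %.4g | %.4g |", tt$comparison,
                     tt$n_effective, tt$statistic, tt$p_value, tt$p_adjusted))
    fr <- bundle$friedman[[rd]]
    out <- c(out, "",
             sprintf("Friedman: chi2 = %.3f (df = %d), p = %.3g, Kendall's W = %.3f",
                     fr$statistic, fr$df, fr$p_value, fr$kendalls_w), "")
  }

  if (!is.null(bundle$evans)) {
    out <- c(out, "## Major responses (Evans III-IV, >90% damaged)")
    major <- colSums(bundle$evans %in% c("III", "IV") &
                       !is.na(bundle$evans), na.rm = TRUE)
    dim(major) <- NULL
    counts <- apply(bundle$evans, 2, function(g)
      sum(g %in% c("III", "IV"), na.rm = TRUE))
    out <- c(out, sprintf("- %s: %d of %d cultures", names(counts), counts,
                          nrow(bundle$evans)), "")
  }

  out <- c(out, "## Differential expression")
  if (is.null(bundle$de_summary)) {
    out <- c(out, "not run")
  } else {
    s <- bundle$de_summary
    out <- c(out, sprintf(
      "- %d of %d genes up (%s%%), %d down (%s%%); strict list: %d genes",
      s$n_up, s$n_total, fmt1(s$pct_up), s$n_down, fmt1(s$pct_down), s$n_strict))
  }
  paste(out, collapse = "\n")
}

#' @export
print.slicequant_run <- function(x, ...) {
  cat(sprintf("slicequant run: %d cultures, %d conditions, %d slices\n",
              length(unique(x$condition_summaries$culture_id)),
              length(unique(x$condition_summaries$condition)),
              nrow(x$slice_readouts)))
  cat(sprintf("  control: %s; readouts tested: %s\n", x$control,
              paste(names(x$tests), collapse = ", ")))
  if (!is.null(x$matrices$viability_pct)) {
    cm <- x$matrices$viability_pct
    cat(sprintf("  median viability: control %.1f%%, pooled selenite %.1f%%\n",
                cm$condition_medians[x$control], cm$pooled_selenite_median))
  }
  cat("  use summary() for the full report\n")
  invisible(x)
}

#' @export
summary.slicequant_run <- function(object, ...) {
  cat(render_summary(object), "\n")
  invisible(object)
}

#' Box plot of a readout across conditions
#'
#' Base-graphics boxes of duplicate-averaged culture values per condition,
#' in the configured condition order.
#'
#' @param x a `slicequant_run`.
#' @param readout readout to plot.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.slicequant_run <- function(x, readout = "viability_pct", ...) {
  if (is.null(x$matrices[[readout]])) stop("readout not available: ", readout)
  m <- x$matrices[[readout]]$matrix
  graphics::boxplot(as.data.frame(m), ylab = readout,
                    xlab = "condition", ...)
  invisible(x)
}
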