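#' Morphology grouping and viability weights
#'
#' Maps each outgrowth morphology to the viable group (flat, cubic,
#' cylindrical, clear) or the damaged group (swollen, necro_apoptotic), and
#' carries the tumor-viability-index weights: 3 for viable and 1 for damaged
#' outgrowth by default. Weights are configurable; the grouping is fixed by
#' the morphological definition of the classes.
#'
#' @param viable_weight,damaged_weight strictly positive index weights.
#' @return Object of class `morphology_grouping`: list with `groups` (named
#'   character vector class -> group) and `weights` (named numeric).
#' @export
morphology_grouping <- function(viable_weight = 3, damaged_weight = 1) {
  if (viable_weight <= 0 || damaged_weight <= 0)
    stop("weights must be strictly positive")
  g <- list(
    groups = c(flat = "viable", cubic = "viable", cylindrical = "viable",
               clear = "viable", swollen = "damaged", necro_apoptotic = "damaged"),
    weights = c(viable = viable_weight, damaged = damaged_weight)
  )
  class(g) <- "morphology_grouping"
  g
}

#' Classify an outgrowth morphology as viable or damaged
#'
#' @param annotation_class character vector of outgrowth morphology classes.
#' @param grouping a [morphology_grouping()].
#' @return Character vector of `"viable"` / `"damaged"`.
#' @export
classify_group <- function(annotation_class, grouping = morphology_grouping()) {
  out <- unname(grouping$groups[annotation_class])
  if (anyNA(out))
    stop("not an outgrowth morphology class: ",
         paste(unique(annotation_class[is.na(out)]), collapse = ", "))
  out
}

#' Tumor viability index
#'
#' Weighted sum of the viable and damaged outgrowth length percentages:
#' `weight_viable * viable_len_pct + weight_damaged * damaged_len_pct`
#' (defaults 3 and 1), ranging 0 for no outgrowth to 300 for a fully viable
#' outgrowth covering the whole perimeter. The index rewards viable outgrowth
#' three-fold, so treatment both shortens the outgrowth and shifts it to the
#' damaged classes drive the index down.
#'
#' @param viable_len_pct,damaged_len_pct outgrowth length percentages of the
#'   slice perimeter, >= 0 (vectorised).
#' @param weights named numeric vector with elements `viable` and `damaged`.
#' @return Numeric index value(s).
#' @examples
#' tumor_viability_index(100, 0)   # 300
#' tumor_viability_index(50, 10)   # 160
#' @export
tumor_viability_index <- function(viable_len_pct, damaged_len_pct,
                                  weights = c(viable = 3, damaged = 1)) {
  if (any(viable_len_pct < 0) || any(damaged_len_pct < 0))
    stop("length percentages must be >= 0")
  unname(weights["viable"] * viable_len_pct + weights["damaged"] * damaged_len_pct)
}

#' Evans tumor regression grade from percent damaged tumor
#'
#' Band mapping: < 10 -> I; 10-50 -> IIa; > 50-90 -> IIb; > 90 and < 100 ->
#' III; 100 (no viable tumor) -> IV. Grades III-IV correspond to a major
#' response with over 90% of tumor cells damaged.
#'
#' @param damaged_pct percent of tumor damaged, in [0, 100] (vectorised).
#' @return Character vector of grades `"I"`, `"IIa"`, `"IIb"`, `"III"`, `"IV"`.
#' @export
evans_grade <- function(damaged_pct) {
  if (any(is.na(damaged_pct)) || any(damaged_pct < 0 | damaged_pct > 100))
    stop("damaged_pct must be in [0, 100]")
  ifelse(damaged_pct < 10, "I",
  ifelse(damaged_pct <= 50, "IIa",
  ifelse(damaged_pct <= 90, "IIb",
  ifelse(damaged_pct < 100, "III", "IV"))))
}

#' Per-slice readouts from annotation records
#'
#' Computes the three drug-response readouts for one slice. In outgrowth
#' mode (perimeter record present) the per-class outgrowth lengths are
#' expressed as percentages of the slice perimeter, grouped into viable and
#' damaged, and combined into the tumor viability index; viability is the
#' viable share of the total outgrowth. In area mode (within-slice tumor
#' annotations) viability is the viable share of the annotated tumor area
#' and the length-based readouts are undefined. Duplicate rows for the same
#' class (disjoint annotations of one morphology, e.g. on halved slice
#' pieces) are summed.
#'
#' @param records annotation records for exactly one slice.
#' @param grouping a [morphology_grouping()].
#' @return One-row data.frame: `culture_id`, `condition`, `slice_id`, `mode`,
#'   per-class percentages (`pct_<class>`), `viable_len_pct`,
#'   `damaged_len_pct`, `outgrowth_pct`, `viability_pct`, `tvi`.
#' @export
slice_readouts <- function(records, grouping = morphology_grouping()) {
  records <- validate_annotations(records)
  if (length(unique(records$slice_id)) != 1)
    stop("records must belong to exactly one slice")

  base <- data.frame(culture_id = records$culture_id[1],
                     condition = records$condition[1],
                     slice_id = records$slice_id[1],
                     stringsAsFactors = FALSE)
  perim_rows <- records$measure_kind == "perimeter"
  outgrowth_mode <- any(perim_rows)

  morph <- names(grouping$groups)
  if (outgrowth_mode) {
    perimeter <- sum(records$value[perim_rows])
    if (length(unique(records$slice_id[perim_rows])) != 1 || sum(perim_rows) > 1)
      stop("expected exactly one perimeter record per slice, found ",
           sum(perim_rows))
    if (perimeter <= 0) stop("slice perimeter must be > 0")
    len <- vapply(morph, function(cl)
      sum(records$value[records$annotation_class == cl &
                          records$measure_kind == "length"]), numeric(1))
    pct <- 100 * len / perimeter
    group <- classify_group(morph, grouping)
    viable_pct <- sum(pct[group == "viable"])
    damaged_pct <- sum(pct[group == "damaged"])
    out <- cbind(base, mode = "outgrowth", as.data.frame(as.list(
      stats::setNames(pct, paste0("pct_", morph)))))
    out$viable_len_pct <- viable_pct
    out$damaged_len_pct <- damaged_pct
    out$outgrowth_pct <- viable_pct + damaged_pct
    out$viability_pct <- if (viable_pct + damaged_pct > 0) {
      100 * viable_pct / (viable_pct + damaged_pct)
    } else {
      warning("slice ", base$slice_id, " has no outgrowth; viability undefined")
      NA_real_
    }
    out$tvi <- tumor_viability_index(viable_pct, damaged_pct, grouping$weights)
  } else {
    viable_area <- sum(records$value[records$annotation_class == "tumor_viable_area"])
    damaged_area <- sum(records$value[records$annotation_class == "tumor_damaged_area"])
    if (viable_area + damaged_area <= 0)
      stop("area-mode slice must have viable + damaged tumor area > 0")
    out <- cbind(base, mode = "area", as.data.frame(as.list(
      stats::setNames(rep(NA_real_, length(morph)), paste0("pct_", morph)))))
    out$viable_len_pct <- NA_real_
    out$damaged_len_pct <- NA_real_
    out$outgrowth_pct <- NA_real_
    out$viability_pct <- 100 * viable_area / (viable_area + damaged_area)
    out$tvi <- NA_real_
  }
  out
}

#' Per-slice readouts for a whole annotation table
#'
#' Splits an annotation table by slice and applies [slice_readouts()].
#'
#' @param annotations validated annotation table (several slices).
#' @param grouping a [morphology_grouping()].
#' @return data.frame of per-slice readouts, one row per slice.
#' @export
quantify_slices <- function(annotations, grouping = morphology_grouping()) {
  annotations <- validate_annotations(annotations)
  key <- interaction(annotations$culture_id, annotations$condition,
                     annotations$slice_id, drop = TRUE)
  parts <- split(annotations, key)
  out <- do.call(rbind, lapply(parts, slice_readouts, grouping = grouping))
  rownames(out) <- NULL
  out[order(out$culture_id, out$condition, out$slice_id), , drop = FALSE]
}

#' Average duplicate slices per culture and condition
#'
#' Arithmetic mean of each readout over the slices contributing to one
#' culture x condition cell, ignoring missing values; the number of slices
#' used is recorded.
#'
#' @param readouts per-slice readouts from [quantify_slices()].
#' @return data.frame with one row per culture x condition: `culture_id`,
#'   `condition`, `mode`, `viability_pct`, `outgrowth_pct`, `tvi`, `n_slices`.
#' @export
average_duplicates <- function(readouts) {
  key <- interaction(readouts$culture_id, readouts$condition, drop = TRUE)
  parts <- split(readouts, key)
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) data.frame(
    culture_id = g$culture_id[1],
    condition = g$condition[1],
    mode = g$mode[1],
    viability_pct = mean_na(g$viability_pct),
    outgrowth_pct = mean_na(g$outgrowth_pct),
    tvi = mean_na(g$tvi),
    n_slices = nrow(g),
    stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out[order(out$culture_id, out$condition), , drop = FALSE]
}

#' Culture-by-condition cohort matrix for one readout
#'
#' Assembles duplicate-averaged condition summaries into a culture x
#' condition matrix (missing cells allowed) with per-condition medians over
#' cultures, plus a pooled median over all selenite conditions combined.
#'
#' @param summaries condition summaries from [average_duplicates()].
#' @param readout one of `"viability_pct"`, `"outgrowth_pct"`, `"tvi"`.
#' @param conditions column order; defaults to the order of appearance.
#' @param selenite_conditions condition labels pooled for the combined
#'   treated median.
#' @return List of class `cohort_matrix`: `readout`, `matrix`,
#'   `condition_medians`, `pooled_selenite_median`.
#' @export
cohort_matrix <- function(summaries, readout,
                          conditions = unique(summaries$condition),
                          selenite_conditions = c("se5", "se15", "se30")) {
  if (!readout %in% c("viability_pct", "outgrowth_pct", "tvi"))
    stop("unknown readout: ", readout)
  cultures <- unique(summaries$culture_id)
  m <- matrix(NA_real_, nrow = length(cultures), ncol = length(conditions),
              dimnames = list(cultures, conditions))
  for (i in seq_len(nrow(summaries))) {
    if (summaries$condition[i] %in% conditions)
      m[summaries$culture_id[i], summaries$condition[i]] <- summaries[[readout]][i]
  }
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  pooled <- stats::median(m[, intersect(selenite_conditions, colnames(m)),
                            drop = FALSE], na.rm = TRUE)
  structure(list(readout = readout, matrix = m, condition_medians = med,
                 pooled_selenite_median = pooled),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort matrix (%s), %d cultures x %d conditions\n",
              x$readout, nrow(x$matrix), ncol(x$matrix)))
  print(round(x$matrix, digits))
  cat("condition medians: ",
      paste(sprintf("%s = %.1f", names(x$condition_medians),
                    x$condition_medians), collapse = ", "), "\n")
  cat(sprintf("pooled selenite median: %.1f\n", x$pooled_selenite_median))
  invisible(x)
}
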