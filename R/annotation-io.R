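#' Recognised annotation classes
#'
#' Six cancer cell outgrowth morphologies (flat, cubic, cylindrical and clear
#' count as viable; swollen and necro_apoptotic as damaged), the slice
#' perimeter, and the two within-slice tumor-area classes used for cultures
#' that do not form a surface outgrowth. The vocabulary is closed: unknown
#' classes are rejected at read time because grouping drives every readout.
#'
#' @return Character vector of valid `annotation_class` values.
#' @export
annotation_classes <- function() {
  c("flat", "cubic", "cylindrical", "clear", "swollen", "necro_apoptotic",
    "perimeter", "tumor_viable_area", "tumor_damaged_area")
}

annotation_columns <- c("culture_id", "slice_id", "replicate", "condition",
                        "annotation_class", "measure_kind", "value")

#' Validate an annotation measurement table
#'
#' Checks the schema used throughout the package: required columns present,
#' annotation classes in the closed vocabulary, measure kinds consistent,
#' values non-negative. Rows with a missing `value` are dropped with a
#' message. A `unit` column, if present, must agree with `measure_kind`
#' (um for lengths/perimeters, um2 for areas).
#'
#' @param records data.frame of annotation measurements.
#' @return The validated (possibly row-filtered) data.frame.
#' @export
validate_annotations <- function(records) {
  missing_cols <- setdiff(annotation_columns, names(records))
  if (length(missing_cols) > 0)
    stop("annotation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  n_na <- sum(is.na(records$value))
  if (n_na > 0) {
    message(sprintf("dropping %d row(s) with missing value", n_na))
    records <- records[!is.na(records$value), , drop = FALSE]
  }

  bad_class <- setdiff(unique(records$annotation_class), annotation_classes())
  if (length(bad_class) > 0)
    stop("unknown annotation_class value(s): ", paste(bad_class, collapse = ", "))

  bad_kind <- setdiff(unique(records$measure_kind), c("length", "area", "perimeter"))
  if (length(bad_kind) > 0)
    stop("unknown measure_kind value(s): ", paste(bad_kind, collapse = ", "))

  neg <- which(records$value < 0)
  if (length(neg) > 0)
    stop("negative measurement value at row(s): ", paste(neg, collapse = ", "))

  if ("unit" %in% names(records)) {
    expected <- ifelse(records$measure_kind == "area", "um2", "um")
    bad <- which(records$unit != expected)
    if (length(bad) > 0)
      stop("unit inconsistent with measure_kind at row(s): ",
           paste(bad, collapse = ", "))
  }
  records
}

#' Read an annotation measurement table (CSV or TSV)
#'
#' @param path path to a comma- or tab-separated table with columns
#'   `culture_id`, `slice_id`, `replicate`, `condition`, `annotation_class`,
#'   `measure_kind`, `value` (and optionally `dose_um`, `unit`).
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return Validated data.frame of annotation records.
#' @export
read_annotation_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  validate_annotations(records)
}

#' Write a tidy readout or annotation table to CSV
#'
#' Numeric columns are serialized with 15 significant digits so that a
#' written table read back reproduces values to full double precision.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_readout_table <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Length of a planar polyline in micrometres
#'
#' Sum of Euclidean segment lengths, scaled by micrometres per coordinate
#' unit. Whole-slide exports are in pixel space; `microns_per_unit` carries
#' the image calibration.
#'
#' @param coordinates numeric matrix (or two-column data.frame) of ordered
#'   planar points, one row per vertex.
#' @param microns_per_unit micrometres per coordinate unit, > 0.
#' @return Length in micrometres (0 for a single point).
#' @examples
#' polyline_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polyline_length <- function(coordinates, microns_per_unit = 1) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 1) stop("need at least one point")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (microns_per_unit <= 0) stop("microns_per_unit must be > 0")
  if (nrow(coordinates) == 1) return(0)
  d <- diff(coordinates)
  sum(sqrt(rowSums(d^2))) * microns_per_unit
}

#' Perimeter and area of a planar polygon ring
#'
#' The ring is closed implicitly (a last-to-first edge is added when absent).
#' Perimeter is the closed polyline length in um; area is the absolute
#' shoelace area in um^2, independent of traversal orientation.
#'
#' @inheritParams polyline_length
#' @param ring numeric matrix of ordered planar vertices, >= 3 distinct points.
#' @return Named numeric vector `c(perimeter = , area = )`.
#' @examples
#' polygon_perimeter_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
polygon_perimeter_area <- function(ring, microns_per_unit = 1) {
  ring <- as.matrix(ring)
  if (!all(is.finite(ring))) stop("coordinates must be finite")
  if (microns_per_unit <= 0) stop("microns_per_unit must be > 0")
  # drop an explicit closing vertex before counting distinct points
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(unique(ring)) < 3) stop("need at least 3 distinct points")
  closed <- rbind(ring, ring[1, ])
  perim <- polyline_length(closed, microns_per_unit)
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  area <- abs(sum(x * ys - xs * y)) / 2 * microns_per_unit^2
  c(perimeter = perim, area = area)
}

#' Convert GeoJSON annotation geometry to measurement records
#'
#' Reads a GeoJSON FeatureCollection as exported by whole-slide annotation
#' software: `LineString` features become length records, `Polygon` outer
#' rings become area records (perimeter-class polygons become perimeter
#' records). Coordinates are treated as planar pixel units and scaled by
#' `microns_per_unit`. The annotation class is taken from a configurable
#' feature property (export software differs in the key it writes).
#'
#' @param path path to a GeoJSON file.
#' @param microns_per_unit micrometres per coordinate unit, > 0.
#' @param classification_key name of the feature property holding the
#'   annotation class (a string, or an object with a `name` field).
#' @param culture_id,slice_id,replicate,condition metadata attached to every
#'   record read from this file.
#' @return Validated data.frame of annotation records.
#' @export
read_annotation_geojson <- function(path, microns_per_unit = 1,
                                    classification_key = "classification",
                                    culture_id = "unknown",
                                    slice_id = "unknown",
                                    replicate = 1L,
                                    condition = "unknown") {
  if (microns_per_unit <= 0) stop("microns_per_unit must be > 0")
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  rows <- lapply(feats, function(f) {
    cls <- f$properties[[classification_key]]
    if (is.list(cls)) cls <- cls$name
    if (is.null(cls)) stop("feature lacks a '", classification_key, "' property")
    geom <- f$geometry
    coords_to_matrix <- function(cc)
      do.call(rbind, lapply(cc, function(pt) unlist(pt)[1:2]))
    if (identical(geom$type, "LineString")) {
      val <- polyline_length(coords_to_matrix(geom$coordinates), microns_per_unit)
      kind <- if (identical(cls, "perimeter")) "perimeter" else "length"
      unit <- "um"
    } else if (identical(geom$type, "Polygon")) {
      pa <- polygon_perimeter_area(coords_to_matrix(geom$coordinates[[1]]),
                                   microns_per_unit)
      if (identical(cls, "perimeter")) {
        val <- pa[["perimeter"]]; kind <- "perimeter"; unit <- "um"
      } else {
        val <- pa[["area"]]; kind <- "area"; unit <- "um2"
      }
    } else {
      stop("unsupported geometry type: ", geom$type)
    }
    data.frame(culture_id = culture_id, slice_id = slice_id,
               replicate = replicate, condition = condition,
               annotation_class = cls, measure_kind = kind,
               value = val, unit = unit, stringsAsFactors = FALSE)
  })
  validate_annotations(do.call(rbind, rows))
}
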