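#' Column dialect for segmented-cell tables
#'
#' Describes how the columns of a per-cell segmentation export map onto the
#' fields used by this package.  The default mirrors the header set of an
#' inForm-style "cell seg data" export; platforms and software versions vary,
#' so every column name is configurable, as is the unit scale (coordinates
#' are converted to micrometres by multiplying with `um_per_unit`).
#'
#' @param markers Character vector of marker names carried as per-cell mean
#'   intensities (e.g. `c("CD68", "CD163", "PD-L1", "PD-1")`).
#' @param sample,cell_id,x,y,tissue,confidence Column names for the sample
#'   identifier, cell identifier, x/y position, tissue category and
#'   phenotype confidence.
#' @param phenotype,area Optional column names for the platform phenotype
#'   label and the cell area in square micrometres (`NA` to skip).
#' @param marker_cols Named character vector mapping marker name to intensity
#'   column name.  Defaults to `"Entire Cell <marker> Mean"`.
#' @param um_per_unit Micrometres per coordinate unit (e.g. `0.5` for
#'   half-micron pixels).
#' @param tissue_map Named character vector mapping (lower-cased) tissue
#'   labels in the file onto `"EPI_TUMOR"`, `"STROMA"` or `"OTHER"`.
#'   Unlisted labels map to `"OTHER"`.
#' @param sep Field separator (`","` or `"\t"`).
#' @return An object of class `cell_dialect`.
#' @export
#' @examples
#' d <- cell_dialect(markers = c("CD68", "CD163"))
#' d$marker_cols
cell_dialect <- function(markers = c("CD68", "CD163"),
                         sample = "Sample Name",
                         cell_id = "Cell ID",
                         x = "Cell X Position",
                         y = "Cell Y Position",
                         tissue = "Tissue Category",
                         confidence = "Confidence",
                         phenotype = "Phenotype",
                         area = "Entire Cell Area (square microns)",
                         marker_cols = NULL,
                         um_per_unit = 1,
                         tissue_map = c(tumor = "EPI_TUMOR",
                                        epithelium = "EPI_TUMOR",
                                        "sc/hnscc" = "EPI_TUMOR",
                                        stroma = "STROMA"),
                         sep = ",") {
  if (is.null(marker_cols)) {
    marker_cols <- setNames(sprintf("Entire Cell %s Mean", markers), markers)
  }
  stopifnot(length(marker_cols) == length(markers),
            um_per_unit > 0)
  structure(list(markers = markers, sample = sample, cell_id = cell_id,
                 x = x, y = y, tissue = tissue, confidence = confidence,
                 phenotype = phenotype, area = area,
                 marker_cols = marker_cols, um_per_unit = um_per_unit,
                 tissue_map = tissue_map, sep = sep),
            class = "cell_dialect")
}

#' @export
print.cell_dialect <- function(x, ...) {
  cat("<cell_dialect> markers:", paste(x$markers, collapse = ", "),
      "| um/unit:", x$um_per_unit, "\n")
  invisible(x)
}

TISSUE_LEVELS <- c("EPI_TUMOR", "STROMA", "OTHER")

num_or_stop <- function(v, col, what) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out) & !is.na(v) & v != "")
  if (length(bad)) {
    stop(sprintf("non-numeric %s in column '%s' at row %d", what, col, bad[1]),
         call. = FALSE)
  }
  out
}

#' Read a per-cell segmentation table
#'
#' Reads a CSV/TSV export of segmented cells and returns a standardized
#' cell table: one row per cell with columns `sample_id`, `cell_id`, `x_um`,
#' `y_um`, `tissue_class`, `phenotype`, `confidence`, `cell_area_um2` and one
#' numeric column per marker.  Coordinates are converted to micrometres via
#' the dialect's `um_per_unit`; tissue labels not listed in the dialect's
#' `tissue_map` become `"OTHER"`.  Confidence values given as percentages
#' (strings such as `"97.5%"`, or numerics above 1) are rescaled to `[0, 1]`.
#'
#' @param path Path to the table.
#' @param dialect A [cell_dialect()].
#' @return A `data.frame` cell table with attribute `"markers"`.
#' @export
read_cell_table <- function(path, dialect = cell_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = dialect$sep, check.names = FALSE,
                  stringsAsFactors = FALSE, colClasses = "character")
  mandatory <- c(dialect$sample, dialect$cell_id, dialect$x, dialect$y,
                 dialect$tissue, dialect$confidence,
                 unname(dialect$marker_cols))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  conf <- raw[[dialect$confidence]]
  conf <- num_or_stop(gsub("%", "", conf, fixed = TRUE),
                      dialect$confidence, "confidence")
  if (any(conf > 1, na.rm = TRUE)) conf <- conf / 100
  cells <- data.frame(
    sample_id = as.character(raw[[dialect$sample]]),
    cell_id = as.character(raw[[dialect$cell_id]]),
    x_um = num_or_stop(raw[[dialect$x]], dialect$x, "coordinate") *
      dialect$um_per_unit,
    y_um = num_or_stop(raw[[dialect$y]], dialect$y, "coordinate") *
      dialect$um_per_unit,
    tissue_class = map_tissue(raw[[dialect$tissue]], dialect$tissue_map),
    confidence = conf,
    stringsAsFactors = FALSE
  )
  cells$phenotype <- if (!is.na(dialect$phenotype) &&
                         dialect$phenotype %in% names(raw)) {
    as.character(raw[[dialect$phenotype]])
  } else rep(NA_character_, n)
  cells$cell_area_um2 <- if (!is.na(dialect$area) &&
                             dialect$area %in% names(raw)) {
    num_or_stop(raw[[dialect$area]], dialect$area, "area")
  } else rep(NA_real_, n)
  for (m in dialect$markers) {
    cells[[m]] <- num_or_stop(raw[[dialect$marker_cols[[m]]]],
                              dialect$marker_cols[[m]], "intensity")
  }
  if (n > 0 && any(!is.finite(cells$x_um) | !is.finite(cells$y_um))) {
    stop("non-finite coordinate at row ",
         which(!is.finite(cells$x_um) | !is.finite(cells$y_um))[1],
         call. = FALSE)
  }
  if (any(cells$confidence < 0 | cells$confidence > 1, na.rm = TRUE)) {
    stop("confidence outside [0, 1]", call. = FALSE)
  }
  attr(cells, "markers") <- dialect$markers
  cells
}

map_tissue <- function(labels, tissue_map) {
  key <- tolower(trimws(as.character(labels)))
  mapped <- unname(tissue_map[key])
  mapped[is.na(mapped) | !(mapped %in% TISSUE_LEVELS)] <- "OTHER"
  if (length(labels) == 0) mapped <- character(0)
  factor(mapped, levels = TISSUE_LEVELS)
}

#' Write a standardized cell table
#'
#' Writes a cell table (as returned by [read_cell_table()] or
#' [sample_cells()]) as RFC 4180 CSV using the standardized column names.
#' A write/read round trip through [read_standard_cell_table()] reproduces
#' all fields.
#'
#' @param cells Standardized cell table.
#' @param path Output path.
#' @export
write_cell_table <- function(cells, path) {
  out <- cells
  out$tissue_class <- as.character(out$tissue_class)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#'
#' @param path Path to the CSV.
#' @param markers Marker columns to expect; by default every column that is
#'   not one of the standardized fields.
#' @return A standardized cell table.
#' @export
read_standard_cell_table <- function(path, markers = NULL) {
  std <- c("sample_id", "cell_id", "x_um", "y_um", "tissue_class",
           "confidence", "phenotype", "cell_area_um2")
  hdr <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (is.null(markers)) markers <- setdiff(hdr, std)
  d <- cell_dialect(markers = markers, sample = "sample_id",
                    cell_id = "cell_id", x = "x_um", y = "y_um",
                    tissue = "tissue_class", confidence = "confidence",
                    phenotype = "phenotype", area = "cell_area_um2",
                    marker_cols = setNames(markers, markers),
                    tissue_map = c(epi_tumor = "EPI_TUMOR",
                                   stroma = "STROMA", other = "OTHER"))
  read_cell_table(path, d)
}

#' Filter cells by phenotype confidence
#'
#' Keeps only cells whose phenotype confidence is strictly greater than
#' `min_conf`.  The default reproduces the usual quality rule of keeping
#' cells called with more than 50% confidence.  Order is preserved and the
#' filter is idempotent.
#'
#' @param cells Standardized cell table.
#' @param min_conf Minimum confidence in `[0, 1]`; cells with
#'   `confidence > min_conf` are retained.
#' @return The filtered cell table.
#' @export
filter_by_confidence <- function(cells, min_conf = 0.5) {
  stopifnot(min_conf >= 0, min_conf <= 1)
  keep <- !is.na(cells$confidence) & cells$confidence > min_conf
  out <- cells[keep, , drop = FALSE]
  attr(out, "markers") <- attr(cells, "markers")
  out
}

#' Read a clinical (survival) table
#'
#' Expects columns `patient_id`, `time_months` and `event` (`0/1` or
#' `TRUE/FALSE`; `1`/`TRUE` = death).  An optional `sample_ids` column lists
#' this patient's tissue sample ids separated by `;`.  Any further columns
#' are carried along as stratification variables.
#'
#' @param path Path to the CSV.
#' @return A `data.frame` with one row per patient and a `sample_ids`
#'   list-column.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$patient_id)) {
    stop("duplicate patient_id: ",
         raw$patient_id[duplicated(raw$patient_id)][1], call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(raw$time_months))
  bad <- which(is.na(tm) | !is.finite(tm) | tm <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive or invalid time_months at row %d", bad[1]),
         call. = FALSE)
  }
  ev <- raw$event
  if (is.character(ev)) ev <- toupper(trimws(ev)) %in% c("1", "TRUE", "T")
  ev <- as.logical(as.integer(as.logical(as.numeric(ev))))
  out <- data.frame(patient_id = as.character(raw$patient_id),
                    time_months = tm, event = ev,
                    stringsAsFactors = FALSE)
  out$sample_ids <- if ("sample_ids" %in% names(raw)) {
    strsplit(as.character(raw$sample_ids), ";", fixed = TRUE)
  } else {
    as.list(out$patient_id)
  }
  extra <- setdiff(names(raw), c(need, "sample_ids"))
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

#' Write a clinical table readable by [read_clinical_table()]
#'
#' @param clinical Clinical table.
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  if (is.list(out$sample_ids)) {
    out$sample_ids <- vapply(out$sample_ids, paste, "", collapse = ";")
  }
  out$event <- as.integer(out$event)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
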