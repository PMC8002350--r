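peak_table_columns <- c(
  "metabolite_id", "sample_id", "condition", "compartment",
  "timepoint_h", "replicate", "experiment", "area"
)

#' Read and validate a long-format peak-area table
#'
#' One row per (metabolite, sample) integrated peak area, with the design
#' metadata needed downstream and one external-standard row per sample.
#' The delimiter is sniffed (comma vs tab) unless given. Row order is
#' irrelevant. Validation is total: every malformed input produces a
#' diagnostic naming the offending row or sample, never a silent pass.
#'
#' @param path CSV or TSV file with columns `metabolite_id`, `sample_id`,
#'   `condition`, `compartment`, `timepoint_h`, `replicate`, `experiment`,
#'   `area`.
#' @param standard_id Metabolite id of the external standard (default
#'   `"lamivudine"`); every sample must carry exactly one such row with a
#'   strictly positive area.
#' @param delim Optional explicit field delimiter.
#' @return A validated peak-table tibble with the standard id recorded in
#'   the `"standard_id"` attribute.
#' @seealso [validate_peak_table()], [write_peak_table()]
#' @export
read_peak_table <- function(path, standard_id = "lamivudine", delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_peak_table(tab, standard_id = standard_id)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

#' Validate an in-memory peak table
#'
#' @param table Data frame with the peak-table columns (see
#'   [read_peak_table()]).
#' @inheritParams read_peak_table
#' @return The table as a tibble, columns coerced, with attribute
#'   `standard_id`; errors describe the first problem found.
#' @export
validate_peak_table <- function(table, standard_id = "lamivudine") {
  tab <- as_tibble(table)
  missing_cols <- setdiff(peak_table_columns, names(tab))
  if (length(missing_cols)) {
    abort(paste0("peak table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tab |>
    mutate(
      metabolite_id = as.character(.data$metabolite_id),
      sample_id = as.character(.data$sample_id),
      condition = as.character(.data$condition),
      compartment = as.character(.data$compartment),
      timepoint_h = as.numeric(.data$timepoint_h),
      replicate = as.integer(.data$replicate),
      experiment = as.integer(.data$experiment),
      area = as.numeric(.data$area)
    )
  bad_area <- which(!is.finite(tab$area) | tab$area < 0)
  if (length(bad_area)) {
    abort(sprintf("row %d: area must be a non-negative number (got %s)",
                  bad_area[1], format(tab$area[bad_area[1]])))
  }
  dup <- duplicated(tab[c("metabolite_id", "sample_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("row %d: duplicate (metabolite, sample) pair: %s / %s",
                  i, tab$metabolite_id[i], tab$sample_id[i]))
  }
  ok_cond <- c(.cond_levels, .medium_control)
  bad_cond <- which(!tab$condition %in% ok_cond)
  if (length(bad_cond)) {
    abort(sprintf("row %d: condition '%s' not one of %s",
                  bad_cond[1], tab$condition[bad_cond[1]],
                  paste(ok_cond, collapse = ", ")))
  }
  bad_comp <- which(!tab$compartment %in% .comp_levels)
  if (length(bad_comp)) {
    abort(sprintf("row %d: compartment '%s' not one of %s",
                  bad_comp[1], tab$compartment[bad_comp[1]],
                  paste(.comp_levels, collapse = ", ")))
  }
  std <- tab |>
    summarise(
      n_std = sum(.data$metabolite_id == standard_id &
                    .data$area > 0),
      .by = "sample_id"
    )
  bad_std <- std$sample_id[std$n_std != 1L]
  if (length(bad_std)) {
    abort(sprintf(
      "sample '%s' lacks exactly one external-standard ('%s') row with area > 0",
      bad_std[1], standard_id
    ))
  }
  attr(tab, "standard_id") <- standard_id
  tab
}

#' Write a peak table (or simulation output) to CSV
#'
#' @param peaks A peak-table tibble or a `metr_sim` object (its `$peaks` is
#'   written).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  if (inherits(peaks, "metr_sim")) peaks <- peaks$peaks
  readr::write_csv(peaks, path)
  invisible(path)
}

#' Read a metabolite -> class annotation table
#'
#' Two-column (metabolite, class) file; repeated metabolite rows express
#' multi-membership. Metabolite names are mapped to canonical catalog ids
#' via [canonical_metabolite()]; class labels must come from
#' [annotation_vocabulary()].
#'
#' @param path CSV/TSV with columns `metabolite_id` and `class`.
#' @param delim Optional explicit delimiter.
#' @return Tibble with columns `metabolite_id`, `class` (one row per
#'   membership); empty input yields an empty map with a warning.
#' @export
read_annotation <- function(path, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("metabolite_id", "class"), names(tab))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tab |>
    mutate(
      metabolite_id = canonical_metabolite(as.character(.data$metabolite_id)),
      class = as.character(.data$class)
    ) |>
    select("metabolite_id", "class") |>
    distinct()
  if (nrow(tab) == 0) {
    warn("annotation file is empty; returning an empty map")
    return(tab)
  }
  unknown <- setdiff(tab$class, annotation_vocabulary())
  if (length(unknown)) {
    abort(paste0(
      "unknown class label(s): ", paste(unknown, collapse = ", "),
      "; allowed labels are: ",
      paste(annotation_vocabulary(), collapse = ", ")
    ))
  }
  tab
}

#' Write a percent heat-map matrix to CSV
#'
#' Metabolites as rows; one column per condition x timepoint, ordered by
#' ascending timepoint within condition. Re-reading with [read_matrix()] is
#' lossless.
#'
#' @param matrix Numeric matrix with metabolite row names and
#'   `condition_timepoint` column names (as produced by
#'   [heatmap_matrix()]), or a list of equal-length rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  if (is.list(matrix) && !is.data.frame(matrix)) {
    if (length(unique(lengths(matrix))) > 1) {
      abort("ragged matrix: all rows must have the same length")
    }
    matrix <- do.call(rbind, matrix)
  }
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!is.matrix(matrix)) abort("`matrix` must be a matrix")
  out <- as_tibble(matrix, rownames = "metabolite_id")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a heat-map matrix written by [write_matrix()]
#'
#' @param path CSV path.
#' @return Numeric matrix with metabolite row names.
#' @export
read_matrix <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}
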