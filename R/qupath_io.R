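#' Read a QuPath detection-measurement export
#'
#' Parses one detection table as exported by QuPath's measurement exporter: one
#' row per detection object (whole cells and subcellular spot/cluster
#' detections), with per-channel measurement columns. Morphometric columns
#' (cell area, nucleus and cytoplasm shape, ...) are dropped; only columns
#' matching the dialect's spot-count or intensity pattern for some channel are
#' retained as measurements.
#'
#' Numeric fields are parsed strictly: a value that is not a plain
#' dot-decimal number (e.g. a comma decimal mark from a locale drift) raises a
#' parse error naming the row rather than being coerced. Non-finite
#' measurement values are rejected.
#'
#' @param path Path to a TSV/CSV export.
#' @param dialect A [qupath_dialect()] describing the file layout.
#' @param allow_empty Permit a file with a valid header and zero data rows
#'   (returns an empty table). Default `FALSE`: an empty export is almost
#'   always an upstream mistake and is reported as an error.
#'
#' @return A `detection_tbl`: a tibble with columns `image_id`, `object_id`,
#'   `object_type` (`"cell"` / `"subcellular"`), `parent_id`, `centroid_x`,
#'   `centroid_y` (micrometres) plus one numeric column per retained
#'   measurement, in file row order. Attributes `source_files` and `dialect`
#'   record provenance.
#' @seealso [split_branches()], [concatenate_exports()]
#' @export
read_detection_export <- function(path, dialect = qupath_dialect(), allow_empty = FALSE) {
  if (!file.exists(path)) {
    stop("read_detection_export: file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(path,
    delim = dialect$sep, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    locale = readr::locale(encoding = "UTF-8"), show_col_types = FALSE
  )
  mandated <- c(dialect$object_type_col, dialect$centroid_x_col, dialect$centroid_y_col)
  missing_cols <- setdiff(mandated, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_detection_export: missing mandated column(s) in ", basename(path), ": ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(raw) == 0) {
    if (!allow_empty) {
      stop("read_detection_export: export has a valid header but no data rows: ",
        basename(path),
        call. = FALSE
      )
    }
    return(empty_detection_tbl(path, dialect))
  }

  file_stem <- sub("\\.[^.]*$", "", basename(path))
  image_id <- if (dialect$image_col %in% names(raw)) {
    blank_to(raw[[dialect$image_col]], file_stem)
  } else {
    rep(file_stem, nrow(raw))
  }
  object_id <- if (dialect$object_id_col %in% names(raw)) {
    blank_to(raw[[dialect$object_id_col]], NA_character_)
  } else {
    rep(NA_character_, nrow(raw))
  }
  auto <- sprintf("obj-%06d", seq_len(nrow(raw)))
  object_id <- ifelse(is.na(object_id), auto, object_id)
  parent_id <- if (dialect$parent_id_col %in% names(raw)) {
    blank_to(raw[[dialect$parent_id_col]], NA_character_)
  } else {
    rep(NA_character_, nrow(raw))
  }

  type_raw <- raw[[dialect$object_type_col]]
  object_type <- dplyr::case_when(
    type_raw == dialect$cell_label ~ "cell",
    type_raw == dialect$subcellular_label ~ "subcellular",
    TRUE ~ type_raw # unknown labels surface in split_branches
  )

  cx <- parse_strict_numeric(raw[[dialect$centroid_x_col]], dialect$centroid_x_col, path)
  cy <- parse_strict_numeric(raw[[dialect$centroid_y_col]], dialect$centroid_y_col, path)
  if (any(stats::na.omit(c(cx, cy)) < 0)) {
    stop("read_detection_export: negative centroid coordinate in ", basename(path),
      call. = FALSE
    )
  }

  meas_cols <- measurement_columns(names(raw), dialect)
  out <- tibble::tibble(
    image_id = image_id, object_id = object_id, object_type = object_type,
    parent_id = parent_id, centroid_x = cx, centroid_y = cy
  )
  for (mc in meas_cols) {
    v <- parse_strict_numeric(raw[[mc]], mc, path)
    if (any(!is.finite(v) & !is.na(v))) {
      stop("read_detection_export: non-finite measurement in column '", mc, "' of ",
        basename(path),
        call. = FALSE
      )
    }
    out[[mc]] <- v
  }
  new_detection_tbl(out, source_files = path, dialect = dialect)
}

blank_to <- function(x, fill) {
  x <- as.character(x)
  ifelse(is.na(x) | !nzchar(x), fill, x)
}

# Strict dot-decimal parsing; comma decimals and other junk fail loudly with
# the first offending data row number.
parse_strict_numeric <- function(x, col, path) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(x)
  ok <- grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$|^(NaN|Inf|-Inf)$", x)
  bad <- which(!ok & !blank)
  if (length(bad) > 0) {
    stop("read_detection_export: unparseable numeric value '", x[bad[1]],
      "' in column '", col, "', data row ", bad[1], " of ", basename(path),
      call. = FALSE
    )
  }
  out <- rep(NA_real_, length(x))
  out[!blank] <- as.numeric(x[!blank])
  out
}

measurement_columns <- function(nms, dialect) {
  rx_spot <- pattern_regex(dialect$spot_count_pattern)
  rx_int <- pattern_regex(dialect$intensity_pattern)
  nms[grepl(rx_spot, nms) | grepl(rx_int, nms)]
}

empty_detection_tbl <- function(path, dialect) {
  out <- tibble::tibble(
    image_id = character(), object_id = character(), object_type = character(),
    parent_id = character(), centroid_x = double(), centroid_y = double()
  )
  new_detection_tbl(out, source_files = path, dialect = dialect)
}

new_detection_tbl <- function(tbl, source_files, dialect) {
  attr(tbl, "source_files") <- source_files
  attr(tbl, "dialect") <- dialect
  class(tbl) <- c("detection_tbl", class(tbl))
  tbl
}

#' Split a detection table into cellular and subcellular branches
#'
#' QuPath exports interleave whole-cell rows and subcellular spot/cluster rows;
#' downstream processing isolates the two into separate tables (the
#' two-branched layout). The split is an exhaustive, disjoint partition.
#'
#' @param table A `detection_tbl` from [read_detection_export()] or
#'   [concatenate_exports()].
#' @return A named list with tibbles `cells` and `subcellular`.
#' @export
split_branches <- function(table) {
  stopifnot(is.data.frame(table), "object_type" %in% names(table))
  bad <- setdiff(unique(table$object_type), c("cell", "subcellular"))
  if (length(bad) > 0) {
    stop("split_branches: unrecognised object type label(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    cells = dplyr::filter(table, .data$object_type == "cell"),
    subcellular = dplyr::filter(table, .data$object_type == "subcellular")
  )
}

#' Concatenate multiple QuPath exports into one detection table
#'
#' Experiments produce one export per image; analysis runs on the pooled
#' dataset. Records keep file order; image identifiers come from each file's
#' image column (file stem as fallback), and `(image_id, object_id)` pairs
#' must be unique across files — a duplicate indicates the same image was
#' exported twice and is a hard error.
#'
#' @inheritParams read_detection_export
#' @param paths Character vector of export file paths (at least one).
#' @return A pooled `detection_tbl`; `attr(, "source_files")` lists the inputs.
#' @export
concatenate_exports <- function(paths, dialect = qupath_dialect(), allow_empty = FALSE) {
  stopifnot(length(paths) >= 1)
  tables <- lapply(paths, function(p) {
    tryCatch(read_detection_export(p, dialect, allow_empty = allow_empty),
      error = function(e) {
        stop("concatenate_exports: while reading '", p, "': ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  })
  out <- dplyr::bind_rows(lapply(tables, as_plain_tibble))
  key <- paste(out$image_id, out$object_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), c("image_id", "object_id")][1, ]
    stop("concatenate_exports: duplicate (image_id, object_id) across files: (",
      d$image_id, ", ", d$object_id, ")",
      call. = FALSE
    )
  }
  new_detection_tbl(out, source_files = unlist(paths), dialect = dialect)
}

as_plain_tibble <- function(x) {
  attr(x, "source_files") <- NULL
  attr(x, "dialect") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Write a detection table back to disk in a QuPath dialect
#'
#' Inverse of [read_detection_export()] for harvested fields: writing a table
#' and reading it back reproduces the identifiers, centroids and measurement
#' columns exactly.
#'
#' @param table A `detection_tbl`.
#' @param path Output file path.
#' @param dialect A [qupath_dialect()].
#' @return `path`, invisibly.
#' @export
write_detections <- function(table, path, dialect = qupath_dialect()) {
  core <- c("image_id", "object_id", "object_type", "parent_id", "centroid_x", "centroid_y")
  stopifnot(all(core %in% names(table)))
  meas <- setdiff(names(table), core)
  out <- tibble::tibble(
    !!dialect$image_col := table$image_id,
    !!dialect$object_id_col := table$object_id,
    !!dialect$object_type_col := dplyr::case_when(
      table$object_type == "cell" ~ dialect$cell_label,
      table$object_type == "subcellular" ~ dialect$subcellular_label,
      TRUE ~ table$object_type
    ),
    !!dialect$parent_id_col := table$parent_id,
    !!dialect$centroid_x_col := table$centroid_x,
    !!dialect$centroid_y_col := table$centroid_y
  )
  for (mc in meas) out[[mc]] <- table[[mc]]
  readr::write_delim(out, path, delim = dialect$sep, na = "", progress = FALSE)
  invisible(path)
}

#' Write an analysis result table as CSV
#'
#' All analysis outputs are persisted as RFC-4180-style CSV with a header row,
#' numeric fields at full (round-trippable) precision, so downstream
#' statistics can be done in any environment.
#'
#' @param rows A data frame of results.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  # serialise doubles at 17 significant digits so read-back is bit-exact
  rows <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(function(v) is.double(v) && !inherits(v, "integer64")),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  ))
  tryCatch(readr::write_csv(rows, path, na = "", progress = FALSE),
    error = function(e) {
      stop("write_results_csv: cannot write '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(path)
}
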