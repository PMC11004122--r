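#' QuPath export dialect
#'
#' Describes the column layout of a QuPath detection-measurement export so the
#' reader can locate the cell/subcellular split, centroids and the per-channel
#' spot-count and intensity measurements. QuPath versions and localisations
#' differ in exact column names; the dialect makes the mapping explicit
#' configuration instead of hard-coded strings.
#'
#' The defaults model QuPath 0.3.x tab-separated measurement exports produced
#' by "Cell Detection" plus "Subcellular Detection": object rows labelled
#' `"Cell"` / `"Subcellular"`, centroids in micrometres, and per-channel
#' measurements named like `"Subcellular: Channel 1: Num spots estimated"`.
#' The `{c}` placeholder in the two patterns stands for the channel identifier
#' (e.g. `"1"` for C1).
#'
#' @param sep Field separator; `"\t"` for QuPath's default TSV export.
#' @param object_type_col Column holding the detection-object class.
#' @param cell_label,subcellular_label Values of `object_type_col` marking
#'   whole-cell and subcellular (spot/cluster) detections.
#' @param image_col Column with the source image name. Optional in the file;
#'   when absent the file stem is used as the image identifier.
#' @param object_id_col Column with a per-object identifier. Optional; when
#'   absent row-numbered identifiers are generated per file.
#' @param parent_id_col Column linking a subcellular detection to its parent
#'   cell. Optional.
#' @param centroid_x_col,centroid_y_col Centroid columns, in micrometres.
#' @param spot_count_pattern,intensity_pattern Templates for the per-channel
#'   measurement columns; each must contain the placeholder `{c}` exactly once.
#'
#' @return An object of class `qupath_dialect` (a named list).
#' @examples
#' d <- qupath_dialect()
#' d$spot_count_pattern
#' @export
qupath_dialect <- function(sep = "\t",
                           object_type_col = "Object type",
                           cell_label = "Cell",
                           subcellular_label = "Subcellular",
                           image_col = "Image",
                           object_id_col = "Object ID",
                           parent_id_col = "Parent ID",
                           centroid_x_col = "Centroid X µm",
                           centroid_y_col = "Centroid Y µm",
                           spot_count_pattern = "Subcellular: Channel {c}: Num spots estimated",
                           intensity_pattern = "Subcellular: Channel {c}: Total intensity") {
  d <- list(
    sep = sep,
    object_type_col = object_type_col,
    cell_label = cell_label,
    subcellular_label = subcellular_label,
    image_col = image_col,
    object_id_col = object_id_col,
    parent_id_col = parent_id_col,
    centroid_x_col = centroid_x_col,
    centroid_y_col = centroid_y_col,
    spot_count_pattern = spot_count_pattern,
    intensity_pattern = intensity_pattern
  )
  class(d) <- "qupath_dialect"
  validate_dialect(d)
  d
}

validate_dialect <- function(d) {
  cols <- c(
    d$object_type_col, d$image_col, d$object_id_col, d$parent_id_col,
    d$centroid_x_col, d$centroid_y_col
  )
  if (any(!nzchar(cols))) {
    stop("qupath_dialect: all column names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(cols)) {
    stop("qupath_dialect: column names must be mutually distinct", call. = FALSE)
  }
  for (p in c(d$spot_count_pattern, d$intensity_pattern)) {
    n <- length(gregexpr("{c}", p, fixed = TRUE)[[1]])
    if (!grepl("{c}", p, fixed = TRUE) || n != 1L) {
      stop("qupath_dialect: pattern must contain the placeholder {c} exactly once: ", p,
        call. = FALSE
      )
    }
  }
  invisible(d)
}

#' @export
print.qupath_dialect <- function(x, ...) {
  cat("<qupath_dialect>\n")
  sep_show <- if (identical(x$sep, "\t")) "\\t" else x$sep
  cat("  separator: '", sep_show, "'\n", sep = "")
  for (f in setdiff(names(x), "sep")) cat("  ", f, ": ", x[[f]], "\n", sep = "")
  invisible(x)
}

# Expand a pattern for one channel, e.g. channel_column("... {c} ...", "1").
channel_column <- function(pattern, channel) {
  sub("{c}", channel, pattern, fixed = TRUE)
}

# Regex matching any channel instantiation of a pattern; captures the channel.
pattern_regex <- function(pattern) {
  parts <- strsplit(pattern, "{c}", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  paste0("^", esc(parts[[1]]), "(.+)", esc(parts[[2]]), "$")
}

#' Read or write a dialect configuration file
#'
#' The dialect can be stored as a plain YAML key-value file so an analysis run
#' is fully described by its configuration.
#'
#' @param path File path.
#' @return `read_dialect()` returns a [qupath_dialect()]; `write_dialect()`
#'   returns `path` invisibly.
#' @export
read_dialect <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(qupath_dialect, vals)
}

#' @param dialect A [qupath_dialect()].
#' @rdname read_dialect
#' @export
write_dialect <- function(dialect, path) {
  stopifnot(inherits(dialect, "qupath_dialect"))
  yaml::write_yaml(unclass(dialect), path)
  invisible(path)
}
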