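#' Map detection channels to gene targets
#'
#' smFISH multiplexing assigns one probe per fluorescence channel (C1-C4 in a
#' 4-plex RNAScope assay). The target configuration names each channel's gene
#' so harvested profiles are keyed by gene symbol rather than channel number.
#'
#' @param channels Named character vector, names = channel identifiers as they
#'   appear in the measurement columns (e.g. `"1"`), values = gene symbols.
#' @return A `target_config` object. `genes()` lists the gene symbols in
#'   configuration order.
#' @examples
#' tc <- target_config(c("1" = "Cd79a", "4" = "Cd4"))
#' genes(tc)
#' @export
target_config <- function(channels) {
  stopifnot(is.character(channels), length(channels) >= 1, !is.null(names(channels)))
  if (any(!nzchar(names(channels)))) {
    stop("target_config: every channel needs an identifier", call. = FALSE)
  }
  if (anyDuplicated(unname(channels))) {
    stop("target_config: gene symbols must be unique", call. = FALSE)
  }
  structure(list(channels = channels), class = "target_config")
}

#' @param x A `target_config`.
#' @rdname target_config
#' @export
genes <- function(x) {
  stopifnot(inherits(x, "target_config"))
  unname(x$channels)
}

#' @export
print.target_config <- function(x, ...) {
  cat("<target_config> ", paste0("C", names(x$channels), " -> ", x$channels,
    collapse = ", "
  ), "\n", sep = "")
  invisible(x)
}

#' Harvest per-cell expression profiles from the cellular branch
#'
#' Turns whole-cell detection rows into one tidy row per (cell, gene):
#' transcript count (from the per-channel spot-count measurement) and total
#' fluorescence intensity. QuPath's cluster decomposition can report
#' fractional estimated spot counts; these are rounded half-up to integers
#' because positivity thresholds are integer transcript counts.
#'
#' A configured channel whose spot-count measurement is absent (or blank) on a
#' cell row is an error, not a silent zero — unless `require_counts = FALSE`,
#' the mode used for child-row exports where counts live on subcellular rows
#' and are added afterwards by [attach_subcellular()].
#'
#' @param cells_table The `cells` branch from [split_branches()].
#' @param targets A [target_config()].
#' @param dialect The [qupath_dialect()] the table was read with.
#' @param require_counts Error on missing spot-count measurements (default).
#'   When `FALSE`, counts and intensities start at zero.
#' @param permissive_intensity When `TRUE`, a missing intensity column yields
#'   zero intensity instead of an error.
#' @return A `cell_profiles` tibble with columns `image_id`, `cell_id`,
#'   `centroid_x`, `centroid_y`, `gene`, `count` (integer), `intensity`.
#'   Rows are ordered by input cell then configured gene.
#' @export
harvest_cells <- function(cells_table, targets, dialect = qupath_dialect(),
                          require_counts = TRUE, permissive_intensity = FALSE) {
  stopifnot(is.data.frame(cells_table), inherits(targets, "target_config"))
  if (nrow(cells_table) > 0 && any(cells_table$object_type != "cell")) {
    stop("harvest_cells: table contains non-cell records; run split_branches() first",
      call. = FALSE
    )
  }
  gs <- genes(targets)
  base <- tibble::tibble(
    image_id = cells_table$image_id,
    cell_id = cells_table$object_id,
    centroid_x = cells_table$centroid_x,
    centroid_y = cells_table$centroid_y,
    .row = seq_len(nrow(cells_table))
  )
  per_gene <- purrr::imap(targets$channels, function(gene, ch) {
    spot_col <- channel_column(dialect$spot_count_pattern, ch)
    int_col <- channel_column(dialect$intensity_pattern, ch)
    if (require_counts) {
      if (!spot_col %in% names(cells_table)) {
        stop("harvest_cells: spot-count measurement '", spot_col,
          "' missing for channel ", ch, " (", gene, ")",
          call. = FALSE
        )
      }
      spots <- cells_table[[spot_col]]
      if (anyNA(spots)) {
        bad <- cells_table$object_id[which(is.na(spots))[1]]
        stop("harvest_cells: missing spot count for channel ", ch, " (", gene,
          ") on cell ", bad,
          call. = FALSE
        )
      }
    } else {
      spots <- if (spot_col %in% names(cells_table)) {
        tidyr::replace_na(cells_table[[spot_col]], 0)
      } else {
        rep(0, nrow(cells_table))
      }
    }
    if (any(spots < 0)) {
      stop("harvest_cells: negative spot count for channel ", ch, call. = FALSE)
    }
    if (int_col %in% names(cells_table)) {
      ints <- tidyr::replace_na(cells_table[[int_col]], 0)
    } else if (permissive_intensity || !require_counts) {
      ints <- rep(0, nrow(cells_table))
    } else {
      stop("harvest_cells: intensity measurement '", int_col,
        "' missing for channel ", ch,
        " (set permissive_intensity = TRUE to treat as zero)",
        call. = FALSE
      )
    }
    dplyr::mutate(base,
      gene = gene,
      count = as.integer(round_half_up(spots, 0)),
      intensity = ints
    )
  })
  out <- dplyr::bind_rows(per_gene) |>
    dplyr::mutate(gene = factor(.data$gene, levels = gs)) |>
    dplyr::arrange(.data$.row, .data$gene) |>
    dplyr::mutate(gene = as.character(.data$gene)) |>
    dplyr::select(-".row")
  new_cell_profiles(out, targets)
}

new_cell_profiles <- function(tbl, targets, orphans = NULL) {
  attr(tbl, "targets") <- targets
  attr(tbl, "orphans") <- orphans
  class(tbl) <- unique(c("cell_profiles", class(tbl)))
  tbl
}

#' Re-associate subcellular detections with their parent cells
#'
#' The second branch of the split: each subcellular spot/cluster detection is
#' assigned to a cell and its spot count added to that cell's tally for the
#' channel's gene. Parent resolution tries the export's parent link first and
#' falls back to the nearest cell centroid in the same image within
#' `capture_radius`. Detections that resolve to no cell are never silently
#' dropped: they accumulate in the orphan tally returned via
#' `orphan_report()`.
#'
#' @param cells A `cell_profiles` tibble from [harvest_cells()].
#' @param subcellular_table The `subcellular` branch from [split_branches()].
#' @param targets A [target_config()].
#' @param dialect The [qupath_dialect()] of the export.
#' @param capture_radius Maximum centroid distance (micrometres) for
#'   nearest-cell fallback assignment; mirrors the radius-based cell-boundary
#'   approximation used upstream.
#' @return The updated `cell_profiles`; `orphan_report()` on the result gives
#'   a tibble of unassignable transcripts per gene.
#' @export
attach_subcellular <- function(cells, subcellular_table, targets,
                               dialect = qupath_dialect(), capture_radius = 5) {
  stopifnot(inherits(cells, "cell_profiles"), is.data.frame(subcellular_table))
  gs <- genes(targets)
  cell_index <- dplyr::distinct(
    tibble::as_tibble(cells[c("image_id", "cell_id", "centroid_x", "centroid_y")])
  )
  counts <- cells # modified in place via keyed adds below
  key <- paste(counts$image_id, counts$cell_id, counts$gene, sep = "\r")
  add_count <- integer(nrow(counts))
  add_int <- numeric(nrow(counts))
  orphans <- stats::setNames(rep(0L, length(gs)), gs)

  for (i in seq_len(nrow(subcellular_table))) {
    row <- subcellular_table[i, ]
    target_cell <- resolve_parent(row, cell_index, capture_radius)
    for (ch in names(targets$channels)) {
      spot_col <- channel_column(dialect$spot_count_pattern, ch)
      if (!spot_col %in% names(row)) next
      n <- row[[spot_col]]
      if (is.na(n) || n == 0) next
      n <- as.integer(round_half_up(n, 0))
      gene <- targets$channels[[ch]]
      if (is.na(target_cell)) {
        orphans[gene] <- orphans[gene] + n
        next
      }
      j <- which(key == paste(row$image_id, target_cell, gene, sep = "\r"))
      add_count[j] <- add_count[j] + n
      int_col <- channel_column(dialect$intensity_pattern, ch)
      if (int_col %in% names(row) && !is.na(row[[int_col]])) {
        add_int[j] <- add_int[j] + row[[int_col]]
      }
    }
  }
  counts$count <- counts$count + add_count
  counts$intensity <- counts$intensity + add_int
  orphan_tbl <- tibble::tibble(gene = gs, transcripts = as.integer(orphans))
  new_cell_profiles(counts, targets, orphans = orphan_tbl)
}

resolve_parent <- function(row, cell_index, capture_radius) {
  in_image <- cell_index[cell_index$image_id == row$image_id, ]
  if (!is.na(row$parent_id) && row$parent_id %in% in_image$cell_id) {
    return(row$parent_id)
  }
  if (nrow(in_image) == 0 || is.na(row$centroid_x) || is.na(row$centroid_y)) {
    return(NA_character_)
  }
  d2 <- (in_image$centroid_x - row$centroid_x)^2 + (in_image$centroid_y - row$centroid_y)^2
  j <- which.min(d2)
  if (sqrt(d2[j]) <= capture_radius) in_image$cell_id[j] else NA_character_
}

#' @param cells A `cell_profiles` tibble.
#' @rdname attach_subcellular
#' @export
orphan_report <- function(cells) {
  o <- attr(cells, "orphans")
  if (is.null(o)) {
    tc <- attr(cells, "targets")
    o <- tibble::tibble(gene = genes(tc), transcripts = 0L)
  }
  o
}

#' Bundle cell profiles into a labelled study dataset
#'
#' A study dataset is the unit of analysis: all cells of one experimental
#' condition (e.g. naive or infected), pooled across images, with the target
#' configuration attached.
#'
#' @param cells A `cell_profiles` tibble.
#' @param label Condition label (e.g. `"naive"`).
#' @param images Optional full image list; defaults to the images present.
#'   Supplying it lets empty images be reported in per-image analyses.
#' @return A `study_dataset` tibble (the cell profiles, with `label`,
#'   `targets` and `images` attributes).
#' @export
study_dataset <- function(cells, label = "dataset", images = NULL) {
  stopifnot(inherits(cells, "cell_profiles"))
  if (is.null(images)) images <- unique(cells$image_id)
  counts_per_cell <- table(paste(cells$image_id, cells$cell_id))
  if (length(counts_per_cell) > 0 && length(unique(as.integer(counts_per_cell))) > 1) {
    stop("study_dataset: ragged profiles; every cell must carry every target gene",
      call. = FALSE
    )
  }
  attr(cells, "label") <- label
  attr(cells, "images") <- images
  class(cells) <- unique(c("study_dataset", class(cells)))
  cells
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(
    "<study_dataset> label:", attr(x, "label"), "|", n_cells(x), "cells,",
    length(attr(x, "images")), "image(s), targets:",
    paste(genes(attr(x, "targets")), collapse = ", "), "\n"
  )
  NextMethod()
}

dataset_targets <- function(data) {
  tc <- attr(data, "targets")
  if (is.null(tc)) {
    tc <- target_config(stats::setNames(
      unique(as.character(data$gene)),
      seq_along(unique(as.character(data$gene)))
    ))
  }
  tc
}

n_cells <- function(data) {
  nrow(dplyr::distinct(tibble::as_tibble(data[c("image_id", "cell_id")])))
}

# Half-up decimal rounding (R's round() is banker's): round_half_up(0.15, 1) = 0.2
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
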