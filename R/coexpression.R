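#' Identify cells matching a multi-target expression profile
#'
#' A cell is positive for a profile query when it carries at least `threshold`
#' transcripts of EVERY queried gene (conjunction): this is how multiplex
#' cell types (e.g. Cd79a+ Il10+ regulatory B cells) are called from smFISH
#' counts, and raising the threshold removes cells whose apparent
#' co-expression rests on one or two stray transcripts.
#'
#' @param data A `study_dataset` or `cell_profiles` tibble.
#' @param query_genes Character vector of >= 1 target gene symbols.
#' @param threshold Minimum transcripts of each queried gene (default 1).
#' @return Tibble of positive cells in dataset order: `image_id`, `cell_id`,
#'   plus one count column per queried gene.
#' @export
classify_cells <- function(data, query_genes, threshold = 1L) {
  check_query(data, query_genes)
  check_threshold(threshold)
  tbl <- tibble::as_tibble(data)
  tbl |>
    dplyr::filter(.data$gene %in% query_genes) |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::summarise(
      positive = all(.data$count >= .env$threshold),
      .ord = min(.data$.ord),
      .by = c("image_id", "cell_id")
    ) |>
    dplyr::filter(.data$positive) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("image_id", "cell_id") |>
    dplyr::left_join(
      tidyr::pivot_wider(
        tbl[tbl$gene %in% query_genes, c("image_id", "cell_id", "gene", "count")],
        names_from = "gene", values_from = "count"
      ),
      by = c("image_id", "cell_id")
    )
}

#' Summarise a co-expression query over a dataset
#'
#' Counts, against two denominators, the cells positive for a multi-target
#' query: all cells in the dataset, and transcript-expressing cells (at least
#' one transcript of any configured target — deliberately independent of the
#' query threshold, so percentages at different thresholds share a
#' denominator). Percentages are rounded half-up to one decimal.
#'
#' @inheritParams classify_cells
#' @return A one-row tibble: `query`, `threshold`, `n_total`, `n_expressing`,
#'   `n_positive`, `pct_all`, `pct_expressing`. `pct_expressing` is `NA` when
#'   no cell expresses any target.
#' @seealso [coexpression_from_counts()] for computing the percentages from
#'   already-tabulated counts.
#' @export
coexpression_summary <- function(data, query_genes, threshold = 1L) {
  check_query(data, query_genes)
  check_threshold(threshold)
  tbl <- tibble::as_tibble(data)
  n_total <- n_cells(tbl)
  if (n_total == 0) stop("coexpression_summary: empty dataset", call. = FALSE)
  n_expressing <- tbl |>
    dplyr::summarise(expr = sum(.data$count) >= 1, .by = c("image_id", "cell_id")) |>
    dplyr::pull(.data$expr) |>
    sum()
  n_positive <- nrow(classify_cells(data, query_genes, threshold))
  out <- coexpression_from_counts(n_total, n_expressing, n_positive)
  tibble::tibble(
    query = paste(query_genes, collapse = "+"),
    threshold = as.integer(threshold),
    out
  )
}

#' Co-expression percentages from tabulated counts
#'
#' The arithmetic core of [coexpression_summary()], exposed so published or
#' externally tabulated counts (total cells, transcript-expressing cells,
#' double-positive cells) can be converted to the same rounded percentages.
#'
#' @param n_total Total cells in the dataset.
#' @param n_expressing Cells with >= 1 transcript of any analysed target.
#' @param n_positive Cells satisfying the profile query.
#' @return A one-row tibble: `n_total`, `n_expressing`, `n_positive`,
#'   `pct_all`, `pct_expressing` (percentages, half-up to 1 decimal).
#' @examples
#' coexpression_from_counts(1229, 273, 18) # 1.5% of all, 6.6% of expressing
#' @export
coexpression_from_counts <- function(n_total, n_expressing, n_positive) {
  stopifnot(
    n_total >= 0, n_expressing >= 0, n_positive >= 0,
    n_positive <= n_expressing, n_expressing <= n_total
  )
  if (n_total == 0) stop("coexpression_from_counts: n_total must be positive", call. = FALSE)
  tibble::tibble(
    n_total = as.integer(n_total),
    n_expressing = as.integer(n_expressing),
    n_positive = as.integer(n_positive),
    pct_all = round_half_up(100 * n_positive / n_total, 1),
    pct_expressing = if (n_expressing == 0) {
      NA_real_
    } else {
      round_half_up(100 * n_positive / n_expressing, 1)
    }
  )
}

#' Per-image positive-cell percentages
#'
#' Computes the query-positive percentage image by image, the unit of
#' replication for between-condition statistics (each image contributes one
#' percentage). Images known to the dataset but containing no cells are
#' returned with `NA` percentage and flagged, so they can be excluded from
#' downstream tests explicitly rather than vanishing.
#'
#' @inheritParams classify_cells
#' @return A tibble `image_id`, `n_cells`, `n_positive`, `pct`, `empty`.
#' @export
per_image_positive_fraction <- function(data, query_genes, threshold = 1L) {
  check_query(data, query_genes)
  check_threshold(threshold)
  tbl <- tibble::as_tibble(data)
  images <- attr(data, "images")
  if (is.null(images)) images <- unique(tbl$image_id)
  per_img <- tbl |>
    dplyr::distinct(.data$image_id, .data$cell_id) |>
    dplyr::count(.data$image_id, name = "n_cells")
  pos <- classify_cells(data, query_genes, threshold) |>
    dplyr::count(.data$image_id, name = "n_positive")
  tibble::tibble(image_id = images) |>
    dplyr::left_join(per_img, by = "image_id") |>
    dplyr::left_join(pos, by = "image_id") |>
    dplyr::mutate(
      n_cells = tidyr::replace_na(.data$n_cells, 0L),
      n_positive = tidyr::replace_na(.data$n_positive, 0L),
      pct = dplyr::if_else(.data$n_cells > 0, 100 * .data$n_positive / .data$n_cells,
        NA_real_
      ),
      empty = .data$n_cells == 0
    )
}

#' Calibrate the positivity threshold against impossible marker combinations
#'
#' A biologically impossible gene combination (one no real cell type in the
#' tissue co-expresses, e.g. a B-cell marker with a T-cell marker) provides a
#' direct estimate of the mis-categorisation rate caused by transcript
#' spillover between neighbouring cells. The threshold is swept upward from 1
#' and the smallest value whose impossible-combination rate falls at or below
#' `max_rate` is chosen; the full sweep is recorded. If no threshold up to
#' `t_max` achieves the rate, the result carries `achieved = FALSE` rather
#' than a silent success.
#'
#' @inheritParams classify_cells
#' @param impossible_genes Gene combination assumed co-expressed by no real
#'   cell type.
#' @param max_rate Maximum acceptable impossible-positive percentage.
#' @param denominator `"expressing"` (default) rates against
#'   transcript-expressing cells; `"all"` against all cells.
#' @param t_max Largest threshold to try.
#' @return A `calibration_result`; `tidy()` returns the sweep,
#'   `glance()` the one-row outcome.
#' @export
calibrate_threshold <- function(data, impossible_genes, max_rate,
                                denominator = c("expressing", "all"), t_max = 10L) {
  denominator <- match.arg(denominator)
  check_query(data, impossible_genes)
  stopifnot(max_rate > 0, max_rate < 100, t_max >= 1)
  sweep <- purrr::map_dfr(seq_len(t_max), function(t) {
    s <- coexpression_summary(data, impossible_genes, t)
    rate <- if (denominator == "all") s$pct_all else s$pct_expressing
    tibble::tibble(threshold = as.integer(t), n_positive = s$n_positive, rate = rate)
  })
  ok <- which(!is.na(sweep$rate) & sweep$rate <= max_rate)
  achieved <- length(ok) > 0
  chosen <- if (achieved) sweep$threshold[ok[1]] else max(sweep$threshold)
  structure(
    list(
      impossible_genes = impossible_genes, max_rate = max_rate,
      denominator = denominator,
      chosen_threshold = chosen,
      rate_at_threshold = sweep$rate[sweep$threshold == chosen],
      achieved = achieved, sweep = sweep
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(
    "<calibration_result>", paste(x$impossible_genes, collapse = "+"),
    "| max rate", paste0(x$max_rate, "% of ", x$denominator, " cells"), "\n"
  )
  if (x$achieved) {
    cat(
      "  chosen threshold:", x$chosen_threshold, "(rate",
      paste0(x$rate_at_threshold, "%)"), "\n"
    )
  } else {
    cat("  NOT achieved within t_max =", max(x$sweep$threshold), "\n")
  }
  invisible(x)
}

#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$sweep

#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    query = paste(x$impossible_genes, collapse = "+"),
    max_rate = x$max_rate, denominator = x$denominator,
    chosen_threshold = x$chosen_threshold,
    rate_at_threshold = x$rate_at_threshold, achieved = x$achieved
  )
}

check_query <- function(data, query_genes) {
  stopifnot(is.character(query_genes), length(query_genes) >= 1)
  gs <- genes(dataset_targets(data))
  bad <- setdiff(query_genes, gs)
  if (length(bad) > 0) {
    stop("query gene(s) not in target configuration: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
}
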