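#' Single-target transcript abundance within positive cells
#'
#' The core differential-abundance readout: restrict to cells that pass the
#' positivity threshold for one gene (count >= t, default t = 1) and collect
#' their transcript counts, e.g. Cd4 expression within Cd4-positive cells.
#'
#' @param data A `study_dataset` or `cell_profiles` tibble.
#' @param gene Gene symbol, one of the configured targets.
#' @param threshold Minimum transcripts for a cell to count as positive
#'   (positive integer, default 1).
#' @return An `abundance_result`: per-positive-cell counts plus `n_positive`
#'   and `mean_count`. Use [tidy()][generics::tidy] for the per-cell table and
#'   [glance()][generics::glance] for the one-row summary.
#' @examples
#' tc <- target_config(c("1" = "Cd4"))
#' prof <- tibble::tibble(
#'   image_id = "img", cell_id = as.character(1:4),
#'   centroid_x = 0, centroid_y = 0, gene = "Cd4",
#'   count = c(0L, 2L, 5L, 1L), intensity = c(0, 20, 50, 10)
#' )
#' ds <- study_dataset(qufish:::new_cell_profiles(prof, tc))
#' glance(transcript_abundance(ds, "Cd4", threshold = 2))
#' @export
transcript_abundance <- function(data, gene, threshold = 1L) {
  check_gene(data, gene)
  check_threshold(threshold)
  pos <- data |>
    tibble::as_tibble() |>
    dplyr::filter(.data$gene == .env$gene, .data$count >= .env$threshold) |>
    dplyr::select("image_id", "cell_id", "count", "intensity")
  if (nrow(pos) == 0) {
    stop("transcript_abundance: no cells positive for ", gene, " at threshold ",
      threshold, " (mean undefined)",
      call. = FALSE
    )
  }
  structure(
    list(
      gene = gene, threshold = as.integer(threshold), per_cell = pos,
      n_positive = nrow(pos), mean_count = mean(pos$count),
      label = attr(data, "label")
    ),
    class = "abundance_result"
  )
}

#' @export
print.abundance_result <- function(x, ...) {
  cat(
    "<abundance_result>", x$gene, "at threshold", x$threshold, "|",
    x$n_positive, "positive cells, mean", format(x$mean_count, digits = 4),
    "transcripts/cell\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy abundance_result
#' @export
tidy.abundance_result <- function(x, ...) x$per_cell

#' @method glance abundance_result
#' @export
glance.abundance_result <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, threshold = x$threshold,
    n_positive = x$n_positive, mean_count = x$mean_count
  )
}

#' Five-number fluorescence-intensity summary
#'
#' Box-plot statistics for one gene's total fluorescence per cell: quartiles,
#' whiskers at the most extreme data points within 1.5 interquartile ranges of
#' the quartiles, and points beyond the fences listed as outliers. By default
#' the summary is over transcript-expressing cells (at least one transcript of
#' any analysed target), matching how intensity distributions are usually
#' reported; `expressing_only = FALSE` summarises all cells.
#'
#' @inheritParams transcript_abundance
#' @param expressing_only Restrict to cells with >= 1 transcript of any
#'   configured target (default `TRUE`).
#' @return A one-row `box_summary` tibble: `gene`, `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, and an `outliers` list-column.
#' @export
intensity_summary <- function(data, gene, expressing_only = TRUE) {
  check_gene(data, gene)
  tbl <- tibble::as_tibble(data)
  if (expressing_only) {
    keep <- tbl |>
      dplyr::summarise(expr = sum(.data$count) >= 1, .by = c("image_id", "cell_id")) |>
      dplyr::filter(.data$expr)
    tbl <- dplyr::semi_join(tbl, keep, by = c("image_id", "cell_id"))
  }
  vals <- tbl$intensity[tbl$gene == gene]
  if (length(vals) == 0) {
    stop("intensity_summary: empty selection for ", gene, call. = FALSE)
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- vals[vals >= lo_fence & vals <= hi_fence]
  out <- tibble::tibble(
    gene = gene, n = length(vals),
    median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = min(inside), whisker_high = max(inside),
    outliers = list(sort(vals[vals < lo_fence | vals > hi_fence]))
  )
  class(out) <- c("box_summary", class(out))
  out
}

#' Two-sample Mann-Whitney U test
#'
#' Nonparametric two-sided comparison of two independent samples, the test of
#' choice here because per-cell transcript counts and per-image percentages
#' are far from normal. Policy: exact null distribution when the combined
#' sample size is at most `exact_limit` (default 16) and there are no ties;
#' otherwise the normal approximation with midranks, tie-corrected variance
#' and continuity correction.
#'
#' @param x,y Numeric vectors (each of length >= 1).
#' @param exact_limit Combined-size cutoff for the exact distribution.
#' @return An `mwu_result` with `u_statistic` (U for the first sample),
#'   `p_value`, `n1`, `n2` and `method` (`"exact"`, `"normal_approx"`, or
#'   `"degenerate"` when every value in both samples is identical, for which
#'   p = 1 is returned).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, exact_limit = 16L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1L) {
    return(structure(
      list(
        u_statistic = n1 * n2 / 2, p_value = 1, n1 = n1, n2 = n2,
        method = "degenerate"
      ),
      class = "mwu_result"
    ))
  }
  exact <- (n1 + n2) <= exact_limit && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  structure(
    list(
      u_statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
      n1 = n1, n2 = n2,
      method = if (exact) "exact" else "normal_approx"
    ),
    class = "mwu_result"
  )
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(
    "Mann-Whitney U =", x$u_statistic, "(n1 =", paste0(x$n1, ","), "n2 =",
    paste0(x$n2, ")"), "p =", format.pval(x$p_value, digits = 4),
    paste0("[", x$method, "]"), "\n"
  )
  invisible(x)
}

#' @method glance mwu_result
#' @export
glance.mwu_result <- function(x, ...) {
  tibble::tibble(
    u_statistic = x$u_statistic, p_value = x$p_value,
    n1 = x$n1, n2 = x$n2, method = x$method
  )
}

#' Per-cell abundance table for CSV export
#'
#' Long table of every (cell, gene) observation — the persisted form of the
#' harvested profiles for downstream statistics outside R.
#'
#' @inheritParams transcript_abundance
#' @return A tibble `image_id, cell_id, gene, count, intensity`.
#' @export
abundance_table <- function(data) {
  tibble::as_tibble(data)[c("image_id", "cell_id", "gene", "count", "intensity")]
}

check_gene <- function(data, gene) {
  gs <- genes(dataset_targets(data))
  if (!(is.character(gene) && length(gene) == 1 && gene %in% gs)) {
    stop("unknown target gene: ", paste(gene, collapse = ", "),
      " (configured: ", paste(gs, collapse = ", "), ")",
      call. = FALSE
    )
  }
}

check_threshold <- function(threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1 && threshold >= 1 &&
    threshold == as.integer(threshold))) {
    stop("threshold must be a positive integer", call. = FALSE)
  }
}
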