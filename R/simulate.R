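#' Configure a synthetic tissue
#'
#' Describes a simulated tissue section: cell placement, cell-type mixture
#' with per-gene expression means, the count model, fluorescence intensity
#' per transcript, and the boundary-spillover artefact probability. The
#' defaults emulate the canonical validation design for this kind of
#' pipeline: two mutually exclusive round cell types in secondary lymphoid
#' tissue — a helper-T-like type expressing only `Cd4` and a B-like type
#' expressing only `Cd79a`, in equal proportion — so that any
#' `Cd4`+`Cd79a` double-positive cell is by construction a mis-categorisation
#' artefact.
#'
#' @param extent Tissue extent `c(width, height)` in micrometres.
#' @param n_cells Number of cells to place.
#' @param cell_radius Schematic cell radius (micrometres); also the default
#'   capture radius for orphan assignment downstream.
#' @param min_spacing Minimum centroid-to-centroid distance (micrometres).
#' @param cell_types Tibble with columns `name`, `proportion`, and
#'   `expression` (list-column of named numeric vectors: mean transcripts per
#'   cell per gene).
#' @param count_model `"poisson"` or `"negative_binomial"`.
#' @param nb_size Negative-binomial size (inverse-dispersion) parameter; only
#'   used for `count_model = "negative_binomial"`.
#' @param intensity_mean,intensity_sd Per-transcript fluorescence (arbitrary
#'   units); a cell's intensity for a gene is the sum over its observed
#'   transcripts of draws from N(mean, sd) truncated at zero.
#' @param spillover_p Probability, in `[0, 1)`, that a transcript is
#'   mis-allocated to the nearest neighbouring cell (boundary-approximation
#'   artefact).
#' @param seed Integer seed; the same seed reproduces the tissue exactly.
#' @return A `tissue_config` list.
#' @export
tissue_config <- function(extent = c(300, 300),
                          n_cells = 200L,
                          cell_radius = 5,
                          min_spacing = 12,
                          cell_types = default_cell_types(),
                          count_model = c("poisson", "negative_binomial"),
                          nb_size = 2,
                          intensity_mean = 100,
                          intensity_sd = 15,
                          spillover_p = 0,
                          seed = 1L) {
  count_model <- match.arg(count_model)
  stopifnot(
    length(extent) == 2, all(extent > 0), n_cells >= 0,
    cell_radius > 0, min_spacing > 0,
    is.data.frame(cell_types),
    all(c("name", "proportion", "expression") %in% names(cell_types)),
    spillover_p >= 0, spillover_p < 1
  )
  if (abs(sum(cell_types$proportion) - 1) > 1e-8) {
    stop("tissue_config: cell-type proportions must sum to 1", call. = FALSE)
  }
  # crude packing feasibility: each cell excludes a disk of radius spacing/2
  if (n_cells * pi * (min_spacing / 2)^2 > 0.7 * prod(extent)) {
    stop("tissue_config: ", n_cells, " cells cannot be packed at ", min_spacing,
      " µm spacing within ", extent[1], " x ", extent[2], " µm",
      call. = FALSE
    )
  }
  structure(
    list(
      extent = extent, n_cells = as.integer(n_cells), cell_radius = cell_radius,
      min_spacing = min_spacing, cell_types = cell_types,
      count_model = count_model, nb_size = nb_size,
      intensity_mean = intensity_mean, intensity_sd = intensity_sd,
      spillover_p = spillover_p, seed = as.integer(seed)
    ),
    class = "tissue_config"
  )
}

#' @param mean_own Mean transcripts of the type's own marker gene.
#' @rdname tissue_config
#' @export
default_cell_types <- function(mean_own = 8) {
  tibble::tibble(
    name = c("Tcell", "Bcell"),
    proportion = c(0.5, 0.5),
    expression = list(c(Cd4 = mean_own, Cd79a = 0), c(Cd4 = 0, Cd79a = mean_own))
  )
}

#' @rdname tissue_config
#' @export
default_targets <- function() {
  target_config(c("1" = "Cd4", "2" = "Cd79a"))
}

# Deterministic substream seeds below 2^31 derived from the global seed.
substream <- function(seed, k) {
  (as.double(seed) * 7 + k * 104729) %% 2147483647
}

#' Simulate a ground-truth tissue
#'
#' Places cells by seeded rejection sampling at the configured minimum
#' spacing, assigns each a type by the mixture proportions, draws per-gene
#' true transcript counts from the count model, then applies the spillover
#' artefact (see [apply_spillover()]). The result carries both true and
#' observed counts, so every downstream analysis can be checked against
#' ground truth. The same configuration (including seed) reproduces the
#' tissue bit for bit.
#'
#' @param config A [tissue_config()].
#' @return A `tissue_truth` list: `config`, `genes`, `cells` (tibble
#'   `cell_id`, `x`, `y`, `type`), `true_counts` and `observed_counts` (long
#'   tibbles `cell_id`, `gene`, `count`), and `spill_events` (tibble `gene`,
#'   `from_cell`, `to_cell`, `n`).
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  gene_names <- unique(unlist(lapply(config$cell_types$expression, names)))
  cells <- withr::with_seed(
    substream(config$seed, 1),
    place_cells(config$n_cells, config$extent, config$min_spacing)
  )
  types <- withr::with_seed(
    substream(config$seed, 2),
    sample(config$cell_types$name,
      size = nrow(cells), replace = TRUE,
      prob = config$cell_types$proportion
    )
  )
  cells$type <- types
  true_counts <- withr::with_seed(
    substream(config$seed, 3),
    draw_counts(cells, config, gene_names)
  )
  truth <- structure(
    list(
      config = config, genes = gene_names, cells = cells,
      true_counts = true_counts, observed_counts = true_counts,
      spill_events = tibble::tibble(
        gene = character(), from_cell = character(),
        to_cell = character(), n = integer()
      )
    ),
    class = "tissue_truth"
  )
  if (config$spillover_p > 0) {
    truth <- apply_spillover(truth, config$spillover_p, substream(config$seed, 4))
  }
  truth
}

place_cells <- function(n, extent, min_spacing, max_attempts_per_cell = 200) {
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max_attempts_per_cell * max(n, 1)
  while (placed < n) {
    if (attempts >= max_attempts) {
      stop("place_cells: failed to place ", n, " cells at ", min_spacing,
        " µm spacing after ", max_attempts, " attempts",
        call. = FALSE
      )
    }
    attempts <- attempts + 1L
    x <- stats::runif(1, 0, extent[1])
    y <- stats::runif(1, 0, extent[2])
    if (placed > 0) {
      d2 <- (xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    xs[placed] <- x
    ys[placed] <- y
  }
  tibble::tibble(
    cell_id = sprintf("cell-%04d", seq_len(n)),
    x = xs, y = ys
  )
}

draw_counts <- function(cells, config, gene_names) {
  if (nrow(cells) == 0) {
    return(tibble::tibble(cell_id = character(), gene = character(), count = integer()))
  }
  type_expr <- stats::setNames(config$cell_types$expression, config$cell_types$name)
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    mus <- type_expr[[cells$type[i]]]
    mus <- stats::setNames(
      vapply(gene_names, function(g) if (g %in% names(mus)) mus[[g]] else 0, 0),
      gene_names
    )
    counts <- vapply(mus, function(mu) {
      if (mu == 0) {
        0L
      } else if (config$count_model == "poisson") {
        stats::rpois(1, mu)
      } else {
        stats::rnbinom(1, mu = mu, size = config$nb_size)
      }
    }, 0L)
    tibble::tibble(
      cell_id = cells$cell_id[i], gene = gene_names,
      count = as.integer(counts)
    )
  })
}

#' Apply the boundary-spillover artefact
#'
#' Each observed transcript is independently mis-allocated with probability
#' `p` to the nearest other cell's tally — the in-silico analogue of
#' radius-approximated cell boundaries overlapping a close neighbour, which
#' is what makes, say, a B cell appear to contain a single `Cd4` transcript.
#' Transcripts are conserved exactly; every reassignment is recorded in
#' `spill_events`.
#'
#' @param truth A `tissue_truth` from [simulate_tissue()].
#' @param p Per-transcript mis-allocation probability in `[0, 1)`.
#' @param seed Integer seed for the reassignment draws.
#' @return The `tissue_truth` with updated `observed_counts` and
#'   `spill_events`.
#' @export
apply_spillover <- function(truth, p, seed = truth$config$seed + 4) {
  stopifnot(inherits(truth, "tissue_truth"), p >= 0, p < 1)
  if (p == 0) {
    return(truth)
  }
  if (nrow(truth$cells) < 2) {
    stop("apply_spillover: need at least 2 cells for spillover", call. = FALSE)
  }
  cells <- truth$cells
  nn <- nearest_neighbour(cells$x, cells$y)
  nn_id <- cells$cell_id[nn]
  names(nn_id) <- cells$cell_id

  base <- truth$true_counts
  withr::with_seed(seed, {
    spilled <- stats::rbinom(nrow(base), base$count, p)
  })
  events <- tibble::tibble(
    gene = base$gene, from_cell = base$cell_id,
    to_cell = unname(nn_id[base$cell_id]), n = as.integer(spilled)
  ) |> dplyr::filter(.data$n > 0)

  observed <- base
  observed$count <- observed$count - as.integer(spilled)
  if (nrow(events) > 0) {
    gains <- events |>
      dplyr::summarise(gain = sum(.data$n), .by = c("to_cell", "gene"))
    key_obs <- paste(observed$cell_id, observed$gene, sep = "\r")
    key_gain <- paste(gains$to_cell, gains$gene, sep = "\r")
    idx <- match(key_gain, key_obs)
    observed$count[idx] <- observed$count[idx] + gains$gain
  }
  truth$observed_counts <- observed
  truth$spill_events <- events
  truth
}

nearest_neighbour <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    which.min(d2)
  }, 0L)
}

#' @export
print.tissue_truth <- function(x, ...) {
  cat(
    "<tissue_truth>", nrow(x$cells), "cells,", length(x$genes), "gene(s),",
    "spillover p =", x$config$spillover_p, "|",
    sum(x$spill_events$n), "transcript(s) mis-allocated\n"
  )
  invisible(x)
}

#' Export a synthetic tissue as a QuPath-dialect detection table
#'
#' Writes the simulated tissue in the format the reader consumes, in either
#' of the two layouts QuPath data arrives in: `"columns"` (per-channel
#' spot-count and intensity columns on each cell row) or `"child_rows"` (cell
#' rows plus one subcellular row per expressed (cell, channel), linked by the
#' parent column). Harvesting the export reproduces the tissue's observed
#' counts exactly; intensities are seeded per-transcript draws, zero whenever
#' the observed count is zero.
#'
#' @param truth A `tissue_truth`.
#' @param path Output file path (TSV in the given dialect).
#' @param targets A [target_config()] whose genes cover the tissue's genes.
#' @param dialect A [qupath_dialect()].
#' @param layout `"columns"` or `"child_rows"`.
#' @param image_id Image name written to the image column.
#' @param seed Seed for the intensity draws (defaults to a substream of the
#'   tissue seed, so repeated export is reproducible).
#' @return `path`, invisibly. The intensity table used is attached as
#'   attribute `"intensities"` for oracle use.
#' @export
export_qupath_dialect <- function(truth, path, targets = default_targets(),
                                  dialect = qupath_dialect(),
                                  layout = c("columns", "child_rows"),
                                  image_id = "synthetic-image-01",
                                  seed = substream(truth$config$seed, 5)) {
  layout <- match.arg(layout)
  stopifnot(inherits(truth, "tissue_truth"))
  if (!all(truth$genes %in% genes(targets))) {
    stop("export_qupath_dialect: target config does not cover tissue genes",
      call. = FALSE
    )
  }
  gene_to_channel <- stats::setNames(names(targets$channels), unname(targets$channels))
  obs <- truth$observed_counts
  ints <- withr::with_seed(seed, draw_intensities(obs, truth$config))

  wide_counts <- tidyr::pivot_wider(obs, names_from = "gene", values_from = "count")
  wide_ints <- tidyr::pivot_wider(ints, names_from = "gene", values_from = "intensity")
  cells <- truth$cells

  if (layout == "columns") {
    out <- tibble::tibble(
      !!dialect$image_col := image_id,
      !!dialect$object_id_col := cells$cell_id,
      !!dialect$object_type_col := dialect$cell_label,
      !!dialect$parent_id_col := NA_character_,
      !!dialect$centroid_x_col := cells$x,
      !!dialect$centroid_y_col := cells$y
    )
    for (g in genes(targets)) {
      ch <- gene_to_channel[[g]]
      cnt <- if (g %in% names(wide_counts)) wide_counts[[g]][match(cells$cell_id, wide_counts$cell_id)] else 0L
      itv <- if (g %in% names(wide_ints)) wide_ints[[g]][match(cells$cell_id, wide_ints$cell_id)] else 0
      out[[channel_column(dialect$spot_count_pattern, ch)]] <- cnt
      out[[channel_column(dialect$intensity_pattern, ch)]] <- itv
    }
  } else {
    cell_rows <- tibble::tibble(
      !!dialect$image_col := image_id,
      !!dialect$object_id_col := cells$cell_id,
      !!dialect$object_type_col := dialect$cell_label,
      !!dialect$parent_id_col := NA_character_,
      !!dialect$centroid_x_col := cells$x,
      !!dialect$centroid_y_col := cells$y
    )
    sub <- obs |>
      dplyr::filter(.data$count > 0) |>
      dplyr::left_join(ints, by = c("cell_id", "gene")) |>
      dplyr::left_join(cells, by = "cell_id")
    sub_rows <- tibble::tibble(
      !!dialect$image_col := rep(image_id, nrow(sub)),
      !!dialect$object_id_col := sprintf("sub-%05d", seq_len(nrow(sub))),
      !!dialect$object_type_col := rep(dialect$subcellular_label, nrow(sub)),
      !!dialect$parent_id_col := sub$cell_id,
      !!dialect$centroid_x_col := sub$x,
      !!dialect$centroid_y_col := sub$y
    )
    all_rows <- dplyr::bind_rows(cell_rows, sub_rows)
    for (g in genes(targets)) {
      ch <- gene_to_channel[[g]]
      spot_col <- channel_column(dialect$spot_count_pattern, ch)
      int_col <- channel_column(dialect$intensity_pattern, ch)
      v_cnt <- rep(NA_real_, nrow(all_rows))
      v_int <- rep(NA_real_, nrow(all_rows))
      is_g <- c(rep(FALSE, nrow(cell_rows)), sub$gene == g)
      v_cnt[is_g] <- sub$count[sub$gene == g]
      v_int[is_g] <- sub$intensity[sub$gene == g]
      all_rows[[spot_col]] <- v_cnt
      all_rows[[int_col]] <- v_int
    }
    out <- all_rows
  }
  readr::write_delim(out, path, delim = dialect$sep, na = "", progress = FALSE)
  attr(path, "intensities") <- ints
  invisible(path)
}

draw_intensities <- function(obs, config) {
  obs |>
    dplyr::mutate(
      intensity = vapply(.data$count, function(k) {
        if (k == 0) {
          0
        } else {
          sum(pmax(stats::rnorm(k, config$intensity_mean, config$intensity_sd), 0))
        }
      }, 0)
    ) |>
    dplyr::select("cell_id", "gene", "intensity")
}

#' Render a schematic micrograph of a synthetic tissue
#'
#' Draws each cell as a filled disk of the configured radius on a grayscale
#' raster — no point-spread or spot rendering, just enough structure to test
#' plot/micrograph overlay alignment.
#'
#' @param truth A `tissue_truth`.
#' @param px_per_um Pixels per micrometre (default 1).
#' @return A numeric matrix in `[0, 1]`, `nrow` = height pixels; attribute
#'   `extent_um` carries the physical extent.
#' @export
render_schematic <- function(truth, px_per_um = 1) {
  ext <- truth$config$extent
  w <- ceiling(ext[1] * px_per_um)
  h <- ceiling(ext[2] * px_per_um)
  img <- matrix(0, nrow = h, ncol = w)
  r_px <- truth$config$cell_radius * px_per_um
  for (i in seq_len(nrow(truth$cells))) {
    cx <- truth$cells$x[i] * px_per_um
    cy <- truth$cells$y[i] * px_per_um
    rows <- max(1, floor(cy - r_px)):min(h, ceiling(cy + r_px))
    cols <- max(1, floor(cx - r_px)):min(w, ceiling(cx + r_px))
    for (rr in rows) {
      dy <- (rr - 0.5) - cy
      dx <- (cols - 0.5) - cx
      img[rr, cols[dx^2 + dy^2 <= r_px^2]] <- 0.8
    }
  }
  attr(img, "extent_um") <- c(w / px_per_um, h / px_per_um)
  img
}

#' Harvest a synthetic export end to end
#'
#' Convenience wrapper running the full pipeline (read, split, harvest,
#' attach subcellular when present) on a file produced by
#' [export_qupath_dialect()].
#'
#' @inheritParams export_qupath_dialect
#' @param label Condition label for the resulting dataset.
#' @param capture_radius Orphan-assignment radius passed to
#'   [attach_subcellular()] for child-row exports.
#' @return A `study_dataset`.
#' @export
harvest_export <- function(path, targets = default_targets(),
                           dialect = qupath_dialect(), label = "synthetic",
                           capture_radius = 5) {
  tab <- read_detection_export(path, dialect, allow_empty = TRUE)
  br <- split_branches(tab)
  child_layout <- nrow(br$subcellular) > 0
  profiles <- harvest_cells(br$cells, targets, dialect,
    require_counts = !child_layout,
    permissive_intensity = child_layout
  )
  if (child_layout) {
    profiles <- attach_subcellular(profiles, br$subcellular, targets, dialect,
      capture_radius = capture_radius
    )
  }
  study_dataset(profiles, label = label)
}
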