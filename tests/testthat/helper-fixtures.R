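# Shared fixtures: all generated in code, nothing on disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

canonical_targets <- function() target_config(c("1" = "Cd79a", "4" = "Cd4"))

# Hand-written 3-row export (2 cells + 1 subcellular) in the canonical dialect.
write_three_row_fixture <- function(path, dialect = qupath_dialect()) {
  spot1 <- channel_column(dialect$spot_count_pattern, "1")
  int1 <- channel_column(dialect$intensity_pattern, "1")
  spot4 <- channel_column(dialect$spot_count_pattern, "4")
  int4 <- channel_column(dialect$intensity_pattern, "4")
  tbl <- tibble::tibble(
    !!dialect$image_col := c("imgA", "imgA", "imgA"),
    !!dialect$object_id_col := c("c1", "c2", "s1"),
    !!dialect$object_type_col := c(
      dialect$cell_label, dialect$cell_label, dialect$subcellular_label
    ),
    !!dialect$parent_id_col := c(NA, NA, "c1"),
    !!dialect$centroid_x_col := c(10, 30, 11),
    !!dialect$centroid_y_col := c(20, 40, 21),
    "Cell area" = c(55.2, 60.1, NA), # morphometric noise, must be dropped
    !!spot1 := c(3, 0, 2),
    !!int1 := c(310.5, 0, 205),
    !!spot4 := c(0, 5, NA),
    !!int4 := c(0, 480.25, NA)
  )
  readr::write_delim(tbl, path, delim = dialect$sep, na = "", progress = FALSE)
  path
}

# Build a study_dataset straight from simulated ground truth (no file I/O),
# for property tests that loop over many tissues.
dataset_from_truth <- function(truth, label = "synthetic", image_id = "img-1") {
  prof <- truth$observed_counts |>
    dplyr::left_join(truth$cells, by = "cell_id") |>
    dplyr::transmute(
      image_id = image_id, cell_id = .data$cell_id,
      centroid_x = .data$x, centroid_y = .data$y,
      gene = .data$gene, count = as.integer(.data$count), intensity = 0
    )
  tc <- target_config(stats::setNames(truth$genes, as.character(seq_along(truth$genes))))
  study_dataset(qufish:::new_cell_profiles(prof, tc), label = label)
}

# Tiny hand-built dataset: counts given per cell as a named list of gene vectors.
dataset_from_counts <- function(count_list, genes_all, image_id = "img-1") {
  prof <- purrr::imap_dfr(count_list, function(cnts, id) {
    tibble::tibble(
      image_id = image_id, cell_id = id, centroid_x = 0, centroid_y = 0,
      gene = genes_all, count = as.integer(cnts[genes_all]), intensity = 0
    )
  })
  tc <- target_config(stats::setNames(genes_all, as.character(seq_along(genes_all))))
  study_dataset(qufish:::new_cell_profiles(prof, tc))
}

# Independent Mann-Whitney oracle: full enumeration of group assignments.
# U = number of (x, y) pairs with x > y (valid without ties); two-sided p by
# symmetric tail counting around n1*n2/2.
mwu_perm_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v <- c(x, y)
  u_of <- function(idx) sum(outer(v[idx], v[-idx], ">"))
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  us <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  list(u = obs, p = mean(abs(us - mu) >= abs(obs - mu)))
}
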