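test_that("counts and intensities map channel measurements to configured genes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_three_row_fixture(f)
  br <- split_branches(read_detection_export(f))
  prof <- harvest_cells(br$cells, canonical_targets())
  expect_s3_class(prof, "cell_profiles")
  expect_equal(nrow(prof), 4) # 2 cells x 2 genes
  c1 <- dplyr::filter(prof, cell_id == "c1")
  expect_equal(c1$count[c1$gene == "Cd79a"], 3L)
  expect_equal(c1$count[c1$gene == "Cd4"], 0L)
  expect_equal(c1$intensity[c1$gene == "Cd79a"], 310.5)
  c2 <- dplyr::filter(prof, cell_id == "c2")
  expect_equal(c2$count[c2$gene == "Cd4"], 5L)
  # empty table -> empty profiles
  expect_equal(nrow(harvest_cells(br$cells[0, ], canonical_targets())), 0)
})

test_that("fractional estimated spot counts are rounded half-up", {
  d <- qupath_dialect()
  tr <- simulate_tissue(tissue_config(n_cells = 3, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_qupath_dialect(tr, f)
  tab <- read_detection_export(f)
  spot <- channel_column(d$spot_count_pattern, "1")
  tab[[spot]] <- c(2.5, 1.49, 0.5) # cluster-decomposition estimates
  prof <- harvest_cells(split_branches(tab)$cells, default_targets())
  expect_equal(
    dplyr::filter(prof, gene == "Cd4")$count,
    c(3L, 1L, 1L)
  )
})

test_that("missing spot-count measurements error instead of silently zeroing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_three_row_fixture(f)
  cells <- split_branches(read_detection_export(f))$cells
  # configured channel with no measurement column at all
  expect_error(
    harvest_cells(cells, target_config(c("9" = "Il10"))),
    "Channel 9"
  )
  # blank value on one cell row
  d <- qupath_dialect()
  cells2 <- cells
  cells2[[channel_column(d$spot_count_pattern, "4")]][1] <- NA
  expect_error(harvest_cells(cells2, canonical_targets()), "cell c1")
  # require_counts = FALSE initialises at zero instead
  prof <- harvest_cells(cells2, canonical_targets(), require_counts = FALSE)
  expect_equal(dplyr::filter(prof, cell_id == "c1", gene == "Cd4")$count, 0L)
})

test_that("attach_subcellular resolves parents, falls back to nearest cell, tallies orphans", {
  d <- qupath_dialect()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_three_row_fixture(f)
  br <- split_branches(read_detection_export(f))
  prof <- harvest_cells(br$cells, canonical_targets())
  # fixture subcellular row: parent c1, channel 1 (Cd79a), 2 spots
  prof2 <- attach_subcellular(prof, br$subcellular, canonical_targets())
  expect_equal(dplyr::filter(prof2, cell_id == "c1", gene == "Cd79a")$count, 5L)
  expect_equal(sum(orphan_report(prof2)$transcripts), 0)
  # orphan: no parent, nearest centroid beyond the capture radius
  orphan_row <- br$subcellular
  orphan_row$parent_id <- NA_character_
  orphan_row$centroid_x <- 500
  orphan_row$centroid_y <- 500
  prof3 <- attach_subcellular(prof, orphan_row, canonical_targets(), capture_radius = 5)
  expect_equal(tibble::as_tibble(prof3), tibble::as_tibble(prof), ignore_attr = TRUE)
  expect_equal(
    orphan_report(prof3)$transcripts[orphan_report(prof3)$gene == "Cd79a"], 2L
  )
  # nearest-centroid fallback within radius
  near_row <- orphan_row
  near_row$centroid_x <- 31
  near_row$centroid_y <- 41 # ~1.4 µm from c2
  prof4 <- attach_subcellular(prof, near_row, canonical_targets(), capture_radius = 5)
  expect_equal(dplyr::filter(prof4, cell_id == "c2", gene == "Cd79a")$count, 2L)
})

test_that("transcripts are conserved: assigned + orphaned = total subcellular spots", {
  tr <- simulate_tissue(tissue_config(n_cells = 30, spillover_p = 0.1, seed = 21))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_qupath_dialect(tr, f, layout = "child_rows")
  br <- split_branches(read_detection_export(f))
  prof0 <- harvest_cells(br$cells, default_targets(), require_counts = FALSE)
  prof <- attach_subcellular(prof0, br$subcellular, default_targets(),
    capture_radius = 5
  )
  d <- qupath_dialect()
  for (ch in c("1", "2")) {
    g <- default_targets()$channels[[ch]]
    total_sub <- sum(br$subcellular[[channel_column(d$spot_count_pattern, ch)]],
      na.rm = TRUE
    )
    assigned <- sum(dplyr::filter(prof, gene == g)$count)
    orphaned <- orphan_report(prof)$transcripts[orphan_report(prof)$gene == g]
    expect_equal(assigned + orphaned, total_sub)
  }
})

test_that("column and child-row layouts harvest identically", {
  tr <- simulate_tissue(tissue_config(n_cells = 40, spillover_p = 0.15, seed = 8))
  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  export_qupath_dialect(tr, fa, layout = "columns")
  export_qupath_dialect(tr, fb, layout = "child_rows")
  da <- harvest_export(fa)
  db <- harvest_export(fb)
  key <- function(x) dplyr::arrange(tibble::as_tibble(x)[c("cell_id", "gene", "count")], cell_id, gene)
  expect_equal(key(da), key(db), ignore_attr = TRUE)
})

test_that("harvest commutes with concatenation (image-wise independence)", {
  tr1 <- simulate_tissue(tissue_config(n_cells = 12, seed = 31))
  tr2 <- simulate_tissue(tissue_config(n_cells = 12, seed = 32))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_qupath_dialect(tr1, f1, image_id = "img-1")
  export_qupath_dialect(tr2, f2, image_id = "img-2")
  pooled <- harvest_cells(
    split_branches(concatenate_exports(c(f1, f2)))$cells, default_targets()
  )
  separate <- dplyr::bind_rows(
    tibble::as_tibble(harvest_cells(split_branches(read_detection_export(f1))$cells, default_targets())),
    tibble::as_tibble(harvest_cells(split_branches(read_detection_export(f2))$cells, default_targets()))
  )
  expect_equal(tibble::as_tibble(pooled), separate, ignore_attr = TRUE)
})

test_that("study_dataset records label, images and targets", {
  tr <- simulate_tissue(tissue_config(n_cells = 10, seed = 2))
  ds <- dataset_from_truth(tr, label = "naive")
  expect_s3_class(ds, "study_dataset")
  expect_equal(attr(ds, "label"), "naive")
  expect_equal(attr(ds, "images"), "img-1")
  expect_equal(genes(attr(ds, "targets")), c("Cd4", "Cd79a"))
})
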