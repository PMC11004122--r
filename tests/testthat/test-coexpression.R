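test_that("a cell co-expressing both markers at 1 transcript drops out at threshold 2", {
  ds <- dataset_from_counts(
    list(
      ambiguous = c(Cd79a = 3, Cd4 = 1), # B-cell with one stray Cd4 transcript
      tcell = c(Cd79a = 0, Cd4 = 6),
      empty = c(Cd79a = 0, Cd4 = 0)
    ),
    genes_all = c("Cd79a", "Cd4")
  )
  pos1 <- classify_cells(ds, c("Cd79a", "Cd4"), 1)
  expect_equal(pos1$cell_id, "ambiguous")
  pos2 <- classify_cells(ds, c("Cd79a", "Cd4"), 2)
  expect_equal(nrow(pos2), 0)
  expect_error(classify_cells(ds, c("Cd79a", "Nope")), "Nope")
})

test_that("classification equals a brute-force scan of ground-truth counts", {
  withr::local_seed(7)
  tr <- simulate_tissue(tissue_config(n_cells = 200, spillover_p = 0.1, seed = 77))
  ds <- dataset_from_truth(tr)
  wide <- tidyr::pivot_wider(tr$observed_counts, names_from = gene, values_from = count)
  for (rep in 1:5) {
    q <- sample(c("Cd4", "Cd79a"), sample(1:2, 1))
    t <- sample(1:3, 1)
    got <- classify_cells(ds, q, t)$cell_id
    brute <- wide$cell_id[rowSums(as.matrix(wide[q]) >= t) == length(q)]
    expect_equal(got, brute)
  }
})

test_that("summary percentages reproduce printed-count arithmetic", {
  # published spleen counts: half-up rounding to 1 decimal
  s <- coexpression_from_counts(1229, 273, 18)
  expect_equal(s$pct_all, 1.5)
  expect_equal(s$pct_expressing, 6.6)
  s2 <- coexpression_from_counts(1631, 914, 30)
  expect_equal(s2$pct_all, 1.8)
  expect_equal(s2$pct_expressing, 3.3)
  # zero positives
  s3 <- coexpression_from_counts(100, 40, 0)
  expect_equal(s3$pct_all, 0)
  expect_equal(s3$pct_expressing, 0)
  # zero expressing -> undefined, flagged as NA
  expect_true(is.na(coexpression_from_counts(10, 0, 0)$pct_expressing))
  expect_error(coexpression_from_counts(0, 0, 0), "n_total")
})

test_that("n_expressing denominator is threshold-independent", {
  ds <- dataset_from_counts(
    list(
      a = c(G = 1, H = 1), b = c(G = 5, H = 0),
      c = c(G = 0, H = 0), d = c(G = 3, H = 2)
    ),
    genes_all = c("G", "H")
  )
  s1 <- coexpression_summary(ds, c("G", "H"), 1)
  s2 <- coexpression_summary(ds, c("G", "H"), 2)
  expect_equal(s1$n_total, 4)
  expect_equal(s1$n_expressing, 3)
  expect_equal(s2$n_expressing, 3) # unchanged by query threshold
  expect_equal(s1$n_positive, 2)
  expect_equal(s2$n_positive, 1)
  expect_true(s2$n_positive <= s1$n_positive)
})

test_that("threshold monotonicity holds across random tissues and queries", {
  for (i in 1:15) {
    tr <- simulate_tissue(tissue_config(
      n_cells = 40, spillover_p = c(0, 0.1, 0.2)[(i %% 3) + 1], seed = 100 + i
    ))
    ds <- dataset_from_truth(tr)
    q <- if (i %% 2 == 0) c("Cd4", "Cd79a") else "Cd4"
    ns <- sapply(1:4, function(t) nrow(classify_cells(ds, q, t)))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("every expressing cell is positive for at least one single-gene query at t = 1", {
  tr <- simulate_tissue(tissue_config(n_cells = 60, spillover_p = 0.1, seed = 9))
  ds <- dataset_from_truth(tr)
  s <- coexpression_summary(ds, "Cd4", 1)
  n_single <- nrow(classify_cells(ds, "Cd4", 1)) + nrow(classify_cells(ds, "Cd79a", 1))
  expect_true(n_single >= s$n_expressing)
})

test_that("per-image fractions are per-image arithmetic and flag empty images", {
  prof <- dplyr::bind_rows(
    tibble::as_tibble(dataset_from_counts(
      stats::setNames(
        lapply(1:10, function(i) c(G = as.integer(i == 1))), paste0("a", 1:10)
      ), "G",
      image_id = "img-1"
    )),
    tibble::as_tibble(dataset_from_counts(
      stats::setNames(
        lapply(1:20, function(i) c(G = as.integer(i <= 5))), paste0("b", 1:20)
      ), "G",
      image_id = "img-2"
    ))
  )
  tc <- target_config(c("1" = "G"))
  ds <- study_dataset(qufish:::new_cell_profiles(prof, tc),
    images = c("img-1", "img-2", "img-3")
  )
  out <- per_image_positive_fraction(ds, "G", 1)
  expect_equal(out$pct[1:2], c(10, 25))
  expect_true(out$empty[3])
  expect_true(is.na(out$pct[3]))
  # single-image consistency with the dataset-level summary
  ds1 <- dataset_from_counts(
    stats::setNames(lapply(1:10, function(i) c(G = as.integer(i == 1))), paste0("a", 1:10)),
    "G"
  )
  expect_equal(
    per_image_positive_fraction(ds1, "G", 1)$pct,
    coexpression_summary(ds1, "G", 1)$pct_all
  )
})

test_that("calibration picks the smallest threshold under the target rate", {
  # engineered dataset; chosen must equal an independent brute-force sweep
  tr <- simulate_tissue(tissue_config(n_cells = 150, spillover_p = 0.1, seed = 55))
  ds <- dataset_from_truth(tr)
  cal <- calibrate_threshold(ds, c("Cd4", "Cd79a"),
    max_rate = 10,
    denominator = "expressing", t_max = 6
  )
  brute <- sapply(1:6, function(t) {
    coexpression_summary(ds, c("Cd4", "Cd79a"), t)$pct_expressing
  })
  expect_equal(cal$chosen_threshold, which(brute <= 10)[1])
  expect_equal(cal$sweep$rate, unname(brute))
  expect_true(cal$achieved)
  expect_true(cal$rate_at_threshold <= 10)
  # zero impossible positives -> threshold 1
  tr0 <- simulate_tissue(tissue_config(n_cells = 30, spillover_p = 0, seed = 2))
  cal0 <- calibrate_threshold(dataset_from_truth(tr0), c("Cd4", "Cd79a"), max_rate = 5)
  expect_equal(cal0$chosen_threshold, 1L)
  # unachievable rate -> flagged, never a silent success
  ds_bad <- dataset_from_counts(
    list(a = c(G = 50, H = 50), b = c(G = 50, H = 50)),
    genes_all = c("G", "H")
  )
  cal_bad <- calibrate_threshold(ds_bad, c("G", "H"), max_rate = 10, t_max = 4)
  expect_false(cal_bad$achieved)
  expect_equal(cal_bad$chosen_threshold, 4L)
})

test_that("thresholding rescues impossible double-positives under spillover", {
  # p = 0: perfect segmentation limit, zero impossible positives at any threshold
  tr0 <- simulate_tissue(tissue_config(n_cells = 100, spillover_p = 0, seed = 123))
  ds0 <- dataset_from_truth(tr0)
  for (t in 1:3) {
    expect_equal(nrow(classify_cells(ds0, c("Cd4", "Cd79a"), t)), 0)
  }
  # p > 0: t = 2 rate never exceeds the t = 1 rate (paired over seeds)
  deltas <- sapply(1:12, function(s) {
    tr <- simulate_tissue(tissue_config(n_cells = 120, spillover_p = 0.08, seed = 200 + s))
    ds <- dataset_from_truth(tr)
    n1 <- nrow(classify_cells(ds, c("Cd4", "Cd79a"), 1))
    n2 <- nrow(classify_cells(ds, c("Cd4", "Cd79a"), 2))
    n1 - n2
  })
  expect_true(all(deltas >= 0))
  expect_true(mean(deltas) > 0)
})
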