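grid_of <- function(vals, dims = c(10, 10, 10))
  voxel_grid(array(vals, dims), diag(4))
mask_of <- function(logicals, dims = c(10, 10, 10))
  label_map(voxel_grid(array(as.numeric(logicals), dims), diag(4)),
            c("1" = "foreground"))

test_that("normalization check uses robust percentiles of in-brain intensities", {
  set.seed(4)
  vals <- runif(1000, -3, 3)
  img <- grid_of(vals)
  brain <- mask_of(rep(TRUE, 1000))
  expect_false(normalization_check(img, brain)$flag)
  expect_true(normalization_check(grid_of(vals * 100), brain)$flag)

  # 10^4 in-range values plus 5 extreme outliers: 0.05% <= 0.5%, so no flag
  vals2 <- c(runif(10000 - 5, -2, 2), rep(50, 5))
  n2 <- normalization_check(grid_of(vals2, c(10, 10, 100)),
                            mask_of(rep(TRUE, 10000), c(10, 10, 100)))
  expect_false(n2$flag)
  q995 <- sort(vals2)[ceiling(0.995 * 10000)]   # sort-based oracle
  expect_equal(unname(n2$stats["high"]),
               stats::quantile(vals2, 0.995, names = FALSE))
  expect_lt(abs(n2$stats[["high"]] - q995), 0.01)

  expect_warning(res <- normalization_check(img, mask_of(rep(FALSE, 1000))),
                 "empty")
  expect_true(is.na(res$flag))
})

test_that("segmentation-outside-brain fraction counts escaped foreground voxels", {
  dims <- c(5, 5, 6)
  brain <- array(0, dims); brain[1:4, , ] <- 1       # brain: x in 1..4
  # 120 foreground voxels, 30 of them on the x = 5 background plane
  seg <- array(0, dims)
  inside <- which(brain == 1)
  seg[inside[seq_len(90)]] <- 1
  seg[which(brain == 0)] <- 1                        # all 30 outside voxels
  b <- label_map(voxel_grid(brain, diag(4)), c("1" = "foreground"))
  s <- label_map(voxel_grid(seg, diag(4)), c("1" = "foreground"))
  expect_equal(sum(seg != 0), 120)
  expect_equal(seg_outside_mask(s, b), 0.25)

  inside <- array(0, dims); inside[2, 2, 2] <- 1
  expect_equal(seg_outside_mask(label_map(voxel_grid(inside, diag(4)),
                                          c("1" = "x")), b), 0)
  outside <- array(0, dims); outside[5, 5, 5] <- 1
  expect_equal(seg_outside_mask(label_map(voxel_grid(outside, diag(4)),
                                          c("1" = "x")), b), 1)
  empty <- label_map(voxel_grid(array(0, dims), diag(4)), character())
  expect_equal(seg_outside_mask(empty, b), 0)
})

test_that("tumor volumes split total and enhancing compartments", {
  d <- array(0, c(20, 20, 20))
  d[seq_len(1000)] <- 1; d[1000 + seq_len(500)] <- 2; d[1500 + seq_len(500)] <- 3
  seg <- label_map(voxel_grid(d, diag(4)),
                   c("1" = "enhancing", "2" = "necrosis", "3" = "edema"))
  v <- tumor_volumes(seg)
  expect_equal(v[["total"]], 2.0)
  expect_equal(v[["enhancing"]], 1.0)
  # conservation: total equals the sum of per-label volumes
  expect_equal(v[["total"]], sum(vapply(1:3, function(l)
    label_volume_cm3(seg, l), 0)))

  empty <- label_map(voxel_grid(array(0, c(4, 4, 4)), diag(4)), character())
  ve <- tumor_volumes(empty)
  expect_equal(ve[["total"]], 0)
  expect_equal(ve[["enhancing"]], 0)
  # no enhancing role -> absent, not zero
  expect_true(is.na(tumor_volumes(seg, c(edema = 3L))[["enhancing"]]))
})

test_that("clean phantom QC matches generator ground truth with no flags", {
  rec <- clean_phantom()
  qc <- compute_study_qc(rec)
  truth <- jsonlite::read_json(rec$extras$truth_json)
  vox_cm3 <- truth$voxel_volume_mm3 / 1000
  expect_lt(abs(qc$tumor_total_cm3 - truth$true_total_cm3), vox_cm3)
  expect_lt(abs(qc$tumor_enhancing_cm3 - truth$true_enhancing_cm3), vox_cm3)
  expect_false(any(qc$normalization_flags %in% TRUE))
  expect_equal(qc$seg_outside_brain_fraction, 0)
  expect_length(qc$missing_inputs, 0)
})

test_that("each injected failure mode flips exactly its QC quantity (one-hot)", {
  # 20 seeded studies per mode, plus clean controls
  for (seed in 101:120) {
    base <- make_phantom_study(small_phantom_params(seed = seed),
                               fixture_dir(sprintf("onehot_clean_%d", seed)),
                               study_id = "C")
    qc0 <- compute_study_qc(base)
    signature <- function(qc) c(
      norm = any(qc$normalization_flags %in% TRUE),
      outside = isTRUE(qc$seg_outside_brain_fraction > 0),
      missing = length(qc$missing_inputs) > 0)
    expect_equal(unname(signature(qc0)), c(FALSE, FALSE, FALSE))

    for (mode in c("normalization_break", "cropped_fov", "missing_file")) {
      rec <- make_phantom_study(small_phantom_params(seed = seed),
                                fixture_dir(sprintf("onehot_%s_%d", mode, seed)),
                                study_id = "F")
      rec <- inject_failure(rec, mode, seed = seed)
      sig <- signature(compute_study_qc(rec))
      expected <- c(norm = mode == "normalization_break",
                    outside = mode == "cropped_fov",
                    missing = mode == "missing_file")
      expect_equal(sig, expected,
                   info = sprintf("mode %s seed %d", mode, seed))
    }
  }
})

test_that("normalization break flags only the degraded modality", {
  rec <- injected_phantom("normalization_break", seed = 55L)  # degrades T2
  qc <- compute_study_qc(rec)
  expect_true(qc$normalization_flags[["T2"]])
  expect_false(any(qc$normalization_flags[c("T1", "T1C", "FLAIR")] %in% TRUE))
})

test_that("missing panels are reported from the snapshot inventory", {
  rec <- injected_phantom("missing_file", seed = 77L)
  td <- withr::local_tempdir()
  snaps <- render_study(rec, td)
  qc <- compute_study_qc(rec, snaps)
  expect_gt(length(qc$missing_panels), 0)
  expect_true(all(grepl("FLAIR", basename(qc$missing_panels))))
})
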