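test_that("max-area slice selection follows the argmax/tie/fallback contract", {
  # per-slice axial areas [0, 5, 9, 9, 2] -> first maximal slice, 0-based
  d <- array(0, dim = c(3, 3, 5))
  areas <- c(0, 5, 9, 9, 2)
  for (k in seq_along(areas)) d[, , k][seq_len(areas[k])] <- 1
  expect_identical(max_area_slice(d, "axial"), 2L)

  expect_identical(max_area_slice(array(0, c(3, 3, 11)), "axial"), 5L)

  d2 <- array(0, dim = c(4, 4, 9)); d2[2, 2, 8] <- 1
  expect_identical(max_area_slice(d2, "axial"), 7L)
})

test_that("max-area slice agrees with a brute-force oracle on random masks", {
  set.seed(42)
  axes <- c(sagittal = 1L, coronal = 2L, axial = 3L)
  for (i in 1:100) {
    dims <- sample(4:9, 3, replace = TRUE)
    d <- array(rbinom(prod(dims), 1, 0.15), dims)
    ax <- sample(names(axes), 1)
    expect_identical(max_area_slice(d, ax),
                     as.integer(oracle_max_area_slice(d, axes[[ax]])))
  }
})

test_that("display windowing maps percentiles to [0, 1] linearly", {
  ramp <- matrix(0:100, nrow = 1)
  expect_equal(window_for_display(ramp, 0, 100), ramp / 100)

  expect_equal(window_for_display(matrix(7, 5, 5), 1, 99), matrix(0, 5, 5))

  vals <- c(0:100, 1e6)
  m <- matrix(vals, nrow = 2)
  q <- stats::quantile(vals, c(0.01, 0.99), names = FALSE)  # sort-based oracle
  w <- window_for_display(m, 1, 99)
  expect_equal(w[m == 1e6], 1)
  expect_equal(w[m == 50], (50 - q[1]) / (q[2] - q[1]))
  expect_error(window_for_display(m, 99, 1), class = "mriscreen_parameter_error")
})

test_that("overlay compositing blends, preserves background, and respects precedence", {
  gray <- matrix(seq(0, 1, length.out = 16), 4, 4)
  out <- composite_overlay(gray, list(), alpha = 0.4)
  expect_equal(out[, , 1], gray)
  expect_equal(out[, , 2], gray)
  expect_equal(out[, , 3], gray)

  full <- matrix(TRUE, 4, 4)
  solid <- composite_overlay(gray, list(list(mask = full, color = "red")), alpha = 1)
  expect_equal(solid[, , 1], matrix(1, 4, 4))
  expect_equal(solid[, , 2], matrix(0, 4, 4))

  # 2x2 overlap: later mask wins where both cover
  g2 <- matrix(0.5, 2, 2)
  m1 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # covers (1,1), (1,2)
  m2 <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)  # covers (1,2), (2,2)
  a <- 0.4
  out2 <- composite_overlay(g2, list(list(mask = m1, color = c(1, 0, 0)),
                                     list(mask = m2, color = c(0, 0, 1))), a)
  expect_equal(out2[1, 2, ], (1 - a) * 0.5 + a * c(0, 0, 1))  # overlap -> blue
  expect_equal(out2[1, 1, ], (1 - a) * 0.5 + a * c(1, 0, 0))
  expect_equal(out2[2, 1, ], rep(0.5, 3))                      # background

  expect_error(composite_overlay(gray, list(list(mask = matrix(TRUE, 2, 2),
                                                 color = "red"))),
               class = "mriscreen_geometry_error")
})

test_that("crosshair targeting finds the in-ROI maximum with deterministic ties", {
  img <- array(0, dim = c(6, 6, 7)); img[4, 5, 6] <- 9
  roi <- array(1, dim = c(6, 6, 7))
  expect_identical(crosshair_target(img, roi), c(3L, 4L, 5L))

  img2 <- array(0, dim = c(4, 4, 4))
  img2[4, 4, 4] <- 100                      # global max outside roi
  img2[2, 2, 2] <- 5
  roi2 <- array(0, dim = c(4, 4, 4)); roi2[1:3, 1:3, 1:3] <- 1
  expect_identical(crosshair_target(img2, roi2), c(1L, 1L, 1L))

  expect_identical(crosshair_target(array(0, c(10, 10, 10)),
                                    array(0, c(10, 10, 10))),
                   c(5L, 5L, 5L))
})

test_that("crosshair targeting agrees with brute-force masked argmax", {
  set.seed(9)
  for (i in 1:100) {
    dims <- sample(3:6, 3, replace = TRUE)
    img <- array(sample(1:20, prod(dims), replace = TRUE), dims)
    msk <- array(rbinom(prod(dims), 1, 0.3) == 1, dims)
    expect_identical(crosshair_target(img, msk),
                     as.integer(oracle_masked_argmax(img, msk)))
  }
})

test_that("density panels rescale each region to unit peak and skip empty input", {
  td <- withr::local_tempdir()
  cfg <- snapshot_config(scale = 1L)
  img <- voxel_grid(array(rnorm(1000), c(10, 10, 10)), diag(4))

  # disjoint-range regions draw in disjoint column ranges of the raster
  img$data[1:200] <- runif(200, -4, -2)
  img$data[201:400] <- runif(200, 2, 4)
  m1 <- array(FALSE, c(10, 10, 10)); m1[1:200] <- TRUE
  m2 <- array(FALSE, c(10, 10, 10)); m2[201:400] <- TRUE
  f <- file.path(td, "dens.png")
  res <- render_density_panel(img, list(
    list(mask = m1, name = "low", color = "red"),
    list(mask = m2, name = "high", color = "blue")), f, cfg)
  expect_equal(res$status, "rendered")
  px <- png::readPNG(f)
  is_red <- px[, , 1] > 0.9 & px[, , 2] < 0.1 & px[, , 3] < 0.1
  is_blue <- px[, , 3] > 0.9 & px[, , 1] < 0.1 & px[, , 2] < 0.1
  expect_true(any(is_red) && any(is_blue))
  expect_lt(max(which(colSums(is_red) > 0)), min(which(colSums(is_blue) > 0)))
  # each curve reaches the top of the drawing area (unit peak)
  expect_lte(min(which(rowSums(is_red) > 0)), 3)
  expect_lte(min(which(rowSums(is_blue) > 0)), 3)

  res2 <- render_density_panel(img, list(
    list(mask = array(FALSE, c(10, 10, 10)), name = "none", color = "red")),
    file.path(td, "skip.png"), cfg)
  expect_equal(res2$status, "skipped_missing_input")
})

test_that("a complete study renders every expected panel deterministically", {
  rec <- clean_phantom()
  td <- withr::local_tempdir()
  s1 <- render_study(rec, file.path(td, "a"))
  expect_s3_class(s1, "snapshot_set")
  expect_true(all(s1$panels$status == "rendered"))
  expect_true(all(file.exists(s1$panels$file)))
  # layout inventory: each expected panel appears exactly once
  key <- with(s1$panels, paste(kind, modality, plane))
  expect_false(anyDuplicated(key) > 0)
  expect_setequal(unique(s1$panels$kind),
                  c("annotation", "registration", "csf", "density"))
  expect_true(file.exists(file.path(td, "a", "P001_panels.json")))

  # byte-identical re-render
  s2 <- render_study(rec, file.path(td, "b"))
  for (i in seq_len(nrow(s1$panels))) {
    b1 <- readBin(s1$panels$file[i], "raw", file.size(s1$panels$file[i]))
    b2 <- readBin(s2$panels$file[i], "raw", file.size(s2$panels$file[i]))
    expect_identical(b1, b2)
  }
})

test_that("registration-check panels share slice indices across co-registered modalities", {
  rec <- clean_phantom()
  td <- withr::local_tempdir()
  s <- render_study(rec, td)
  reg <- s$panels[s$panels$kind == "registration", ]
  for (p in unique(reg$plane))
    expect_length(unique(reg$slice_index[reg$plane == p]), 1L)
})

test_that("a study missing one modality skips exactly that modality's panels", {
  rec <- injected_phantom("missing_file", seed = 21L)  # removes the FLAIR file
  td <- withr::local_tempdir()
  s <- render_study(rec, td)
  flair <- s$panels$modality == "FLAIR"
  expect_true(all(s$panels$status[flair] == "skipped_missing_input"))
  expect_true(all(s$panels$status[!flair] == "rendered"))
})

test_that("a rotated modality's brain-mask overlay disagrees with the image support", {
  clean <- clean_phantom()
  rot <- injected_phantom("misregistration", seed = 31L)
  bm <- read_label_map(clean$annotations[["brain_mask"]])$grid$data != 0
  support_overlap <- function(rec) {
    img <- read_volume(rec$anatomical[["FLAIR"]])$data
    mean(img[bm] != 0)   # thresholded support: nonzero (background is 0)
  }
  expect_lt(support_overlap(rot), support_overlap(clean))
  expect_gt(support_overlap(clean) - support_overlap(rot), 0.02)
})
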