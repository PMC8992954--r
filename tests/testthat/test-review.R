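entry <- function(id = "S1", ...) review_entry(id, "rev", timestamp = "2022-01-01T00:00:00Z", ...)

test_that("combined classification takes the maximum severity", {
  expect_equal(as.character(classify_combined(entry())), "acceptable")
  # a poor segmentation is a minor error, not a failure
  expect_equal(as.character(classify_combined(entry(q_tumor_seg = "poor"))),
               "minor_errors")
  expect_equal(as.character(classify_combined(
    entry(q_registration = "fail", q_brain_mask = "poor"))), "failure")
  expect_equal(as.character(classify_combined(entry(f_study_artifact = TRUE))),
               "failure")
  expect_equal(as.character(classify_combined(entry(f_bias_field = TRUE))),
               "minor_errors")
  # completeness flags never affect quality
  expect_equal(as.character(classify_combined(
    entry(f_no_pngs = TRUE, f_needs_review = TRUE))), "acceptable")
  # flag severities are configurable
  expect_equal(as.character(classify_combined(entry(f_bias_field = TRUE),
                                              minor_flags = character())),
               "acceptable")
})

test_that("combined classification is monotone: worsening never improves the class", {
  set.seed(12)
  worsen_q <- function(v) if (v == "acceptable") sample(c("poor", "fail"), 1) else "fail"
  for (i in 1:50) {
    base <- entry(q_brain_mask = sample(Q_LEVELS <- c("acceptable", "poor", "fail"), 1),
                  q_tumor_seg = sample(Q_LEVELS, 1),
                  q_csf_roi = sample(Q_LEVELS, 1),
                  q_registration = sample(Q_LEVELS, 1),
                  f_study_artifact = runif(1) < 0.2,
                  f_bias_field = runif(1) < 0.2,
                  f_normalization_failure = runif(1) < 0.2)
    c0 <- classify_combined(base)
    qcols <- c("q_brain_mask", "q_tumor_seg", "q_csf_roi", "q_registration")
    for (cl in qcols) {
      worse <- base
      worse[[cl]] <- worsen_q(base[[cl]])
      expect_gte(as.integer(classify_combined(worse)), as.integer(c0))
    }
    for (fl in c("f_study_artifact", "f_image_unusable", "f_bias_field",
                 "f_normalization_failure")) {
      worse <- base
      worse[[fl]] <- TRUE
      expect_gte(as.integer(classify_combined(worse)), as.integer(c0))
    }
  }
})

test_that("merging logs unions by study with later-timestamp precedence", {
  a <- do.call(rbind, lapply(1:3, function(i) entry(sprintf("A%d", i))))
  b <- do.call(rbind, lapply(1:4, function(i) entry(sprintf("B%d", i))))
  class(a) <- class(b) <- c("review_log", "data.frame")
  m <- merge_logs(a, b)
  expect_equal(nrow(m), 7)

  old <- review_entry("S9", "alice", timestamp = "2022-01-01T00:00:00Z",
                      q_tumor_seg = "fail")
  new <- review_entry("S9", "bob", timestamp = "2022-03-15T12:00:00Z")
  m2 <- merge_logs(old, new)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$reviewer, "bob")
  expect_equal(m2$q_tumor_seg, "acceptable")
  # order-independent
  expect_equal(merge_logs(new, old)$reviewer, "bob")

  # idempotence
  expect_equal(as.data.frame(merge_logs(a, a)), as.data.frame(a))
})

test_that("schema-invalid rows are rejected with a row-level report", {
  good <- entry("S1")
  bad <- good
  bad$study_id <- "S2"
  bad$q_tumor_seg <- "meh"
  expect_warning(m <- merge_logs(good, rbind(good, bad)), "invalid")
  rej <- attr(m, "rejected")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$study_id, "S2")
  expect_match(rej$reason, "q_tumor_seg")
  expect_equal(nrow(m), 1)
})

test_that("review CSV round-trips field-for-field including quoting edge cases", {
  td <- withr::local_tempdir()
  log <- rbind(entry("S1", comment = "plain"),
               entry("S2", q_brain_mask = "poor", f_bias_field = TRUE,
                     comment = "commas, and \"quotes\", and\nnewlines"),
               entry("S3", csf_location = "left,frontal"))
  class(log) <- c("review_log", "data.frame")
  f <- file.path(td, "log.csv")
  export_review_log(log, f)
  back <- import_review_log(f)
  expect_equal(as.data.frame(back), as.data.frame(log))

  # booleans serialized as 0/1
  raw <- readLines(f)
  expect_match(raw[1], '^"?study_id"?,"?reviewer"?,"?timestamp"?,"?q_brain_mask"?')
  expect_false(any(grepl("TRUE|FALSE", raw)))

  # unknown columns preserved as extras
  log2 <- log
  log2$site <- c("A", "B", "C")
  f2 <- file.path(td, "log2.csv")
  export_review_log(log2, f2)
  expect_equal(import_review_log(f2)$site, c("A", "B", "C"))

  # missing mandatory column is a schema error naming it
  df <- utils::read.csv(f)
  df$study_id <- NULL
  f3 <- file.path(td, "broken.csv")
  utils::write.csv(df, f3, row.names = FALSE)
  expect_error(import_review_log(f3), "study_id",
               class = "mriscreen_schema_error")
})

test_that("summaries tally categories, check totals, and report percentages", {
  log <- rbind(entry("S1"),
               entry("S2", q_tumor_seg = "poor"),
               entry("S3", q_tumor_seg = "fail", q_registration = "poor"),
               entry("S4", f_image_unusable = TRUE))
  class(log) <- c("review_log", "data.frame")
  s <- summary(log)
  expect_equal(s$n, 4)
  cats <- s$categories
  ts <- cats[cats$category == "tumor_segmentation", ]
  expect_equal(c(ts$acceptable, ts$minor_errors, ts$failure), c(2, 1, 1))
  iq <- cats[cats$category == "image_quality", ]
  expect_equal(iq$failure, 1)
  expect_true(is.na(iq$minor_errors))
  expect_equal(unname(s$combined), c(1L, 1L, 2L))
  expect_equal(s$acceptable_fraction_pct, 50)
  expect_equal(ts$failure_rate_pct, 25)

  one <- entry("S1")
  s1 <- summarize_reviews(one)
  expect_equal(s1$acceptable_fraction_pct_int, 100)

  expect_error(summary(review_log()), class = "mriscreen_empty_log")
})

test_that("RMSE stratification follows the closed form and the eligibility filter", {
  log <- rbind(entry("S1"), entry("S2"),
               entry("S3", q_tumor_seg = "fail"),
               entry("S4", q_registration = "poor"))  # ineligible
  class(log) <- c("review_log", "data.frame")
  measured <- c(S1 = 1, S2 = 2, S3 = 10, S4 = 3)
  reference <- c(S1 = 0, S2 = 0, S3 = 4, S4 = 0)

  r <- rmse_by_quality(log, measured, reference)
  acc <- r[r$class == "acceptable", ]
  expect_equal(acc$n, 2)
  expect_equal(acc$rmse, sqrt(mean(c(1, 4))))   # sqrt(2.5) ~ 1.581
  expect_equal(r[r$class == "failure", "rmse"], 6)
  # empty stratum reported with absent RMSE
  expect_true(is.na(r[r$class == "minor_errors", "rmse"]))
  expect_equal(r[r$class == "minor_errors", "n"], 0)
  # S4 excluded by the default eligibility filter
  expect_equal(sum(r$n), 3)

  # identical volumes give zero error
  r0 <- rmse_by_quality(log, reference, reference)
  expect_equal(r0[r0$class == "acceptable", "rmse"], 0)

  # custom filter admitting everything
  r_all <- rmse_by_quality(log, measured, reference,
                           eligibility = function(l) rep(TRUE, nrow(l)))
  expect_equal(sum(r_all$n), 4)
})

test_that("synthetic logs reproduce requested margins jointly", {
  log <- review_log_from_counts(
    100,
    fail_counts = c(tumor_segmentation = 10, registration = 6, image_quality = 3),
    minor_counts = c(brain_mask = 20, tumor_segmentation = 5),
    combined_failures = 12, combined_minor = 18)
  s <- summary(log)
  cats <- s$categories
  expect_equal(cats$failure[cats$category == "tumor_segmentation"], 10)
  expect_equal(cats$failure[cats$category == "registration"], 6)
  expect_equal(cats$failure[cats$category == "image_quality"], 3)
  expect_equal(cats$minor_errors[cats$category == "brain_mask"], 20)
  expect_equal(unname(s$combined), c(70L, 18L, 12L))

  expect_error(review_log_from_counts(10, fail_counts = c(brain_mask = 5),
                                      combined_failures = 8),
               class = "mriscreen_parameter_error")
})
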