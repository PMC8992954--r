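# Review-log schema: fixed column order of the CSV interchange format.
REVIEW_COLUMNS <- c("study_id", "reviewer", "timestamp",
                    "q_brain_mask", "q_tumor_seg", "q_csf_roi", "q_registration",
                    "f_study_artifact", "f_image_unusable", "f_bias_field",
                    "f_normalization_failure", "f_no_pngs", "f_needs_review",
                    "csf_location", "comment")
Q_COLUMNS <- c("q_brain_mask", "q_tumor_seg", "q_csf_roi", "q_registration")
F_COLUMNS <- c("f_study_artifact", "f_image_unusable", "f_bias_field",
               "f_normalization_failure", "f_no_pngs", "f_needs_review")
Q_LEVELS <- c("acceptable", "poor", "fail")
QUALITY_CLASSES <- c("acceptable", "minor_errors", "failure")

# Table-shaped review categories and the columns they are tallied from.
REVIEW_CATEGORIES <- list(
  image_quality = list(kind = "flag", cols = c("f_study_artifact", "f_image_unusable")),
  brain_mask = list(kind = "quality", cols = "q_brain_mask"),
  registration = list(kind = "quality", cols = "q_registration"),
  tumor_segmentation = list(kind = "quality", cols = "q_tumor_seg"),
  csf_localization = list(kind = "quality", cols = "q_csf_roi"),
  normalization = list(kind = "flag", cols = "f_normalization_failure"))

#' Create review-log entries
#'
#' A review log is a data.frame (class `review_log`) with one structured
#' human review per study: a three-level quality call
#' (`acceptable`/`poor`/`fail`) for the brain mask, tumor segmentation, CSF
#' ROI and registration — `poor` designates minor errors unlikely to affect
#' downstream processing, `fail` an unusable result — plus study-level
#' boolean flags (`study_artifact`, `image_unusable`, `bias_field`,
#' `normalization_failure`, `no_pngs`, `needs_review`), a project-specific
#' CSF-location string, and a free-text comment.
#'
#' @param study_id study identifier.
#' @param reviewer reviewer name.
#' @param timestamp ISO-8601 UTC timestamp (assigned at entry creation).
#' @param q_brain_mask,q_tumor_seg,q_csf_roi,q_registration one of
#'   `"acceptable"`, `"poor"`, `"fail"`.
#' @param f_study_artifact,f_image_unusable,f_bias_field,f_normalization_failure,f_no_pngs,f_needs_review
#'   logical flags.
#' @param csf_location free structured string (project-specific).
#' @param comment free text.
#' @return a one-row `review_log`.
#' @export
review_entry <- function(study_id, reviewer,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC"),
                         q_brain_mask = "acceptable", q_tumor_seg = "acceptable",
                         q_csf_roi = "acceptable", q_registration = "acceptable",
                         f_study_artifact = FALSE, f_image_unusable = FALSE,
                         f_bias_field = FALSE, f_normalization_failure = FALSE,
                         f_no_pngs = FALSE, f_needs_review = FALSE,
                         csf_location = "", comment = "") {
  df <- data.frame(study_id = as.character(study_id),
                   reviewer = as.character(reviewer),
                   timestamp = as.character(timestamp),
                   q_brain_mask = q_brain_mask, q_tumor_seg = q_tumor_seg,
                   q_csf_roi = q_csf_roi, q_registration = q_registration,
                   f_study_artifact = isTRUE(f_study_artifact),
                   f_image_unusable = isTRUE(f_image_unusable),
                   f_bias_field = isTRUE(f_bias_field),
                   f_normalization_failure = isTRUE(f_normalization_failure),
                   f_no_pngs = isTRUE(f_no_pngs),
                   f_needs_review = isTRUE(f_needs_review),
                   csf_location = as.character(csf_location),
                   comment = as.character(comment),
                   stringsAsFactors = FALSE)
  v <- validate_review_log(df)
  if (nrow(v$rejected)) stop_schema("invalid review entry: %s", v$rejected$reason[1])
  v$log
}

#' An empty review log
#' @return a zero-row `review_log`.
#' @export
review_log <- function() {
  df <- as.data.frame(stats::setNames(
    lapply(REVIEW_COLUMNS, function(cl)
      if (cl %in% F_COLUMNS) logical() else character()),
    REVIEW_COLUMNS), stringsAsFactors = FALSE)
  class(df) <- c("review_log", "data.frame")
  df
}

#' Validate review-log rows
#'
#' Splits a candidate data.frame into schema-valid rows and a row-level
#' rejection report (rows are never silently dropped: rejected rows are
#' reported with a reason).
#'
#' @param df data.frame with the review-log columns.
#' @return list with `log` (valid rows, class `review_log`) and `rejected`
#'   (data.frame with `row`, `study_id`, `reason`).
#' @export
validate_review_log <- function(df) {
  missing_cols <- setdiff(REVIEW_COLUMNS, names(df))
  if (length(missing_cols))
    stop_schema("review log lacks mandatory column(s): %s",
                paste(missing_cols, collapse = ", "))
  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reasons[bad & is.na(reasons)] <<- why
  flag(is.na(df$study_id) | !nzchar(as.character(df$study_id)), "empty study_id")
  for (qc in Q_COLUMNS)
    flag(!(as.character(df[[qc]]) %in% Q_LEVELS),
         sprintf("%s not in {%s}", qc, paste(Q_LEVELS, collapse = ", ")))
  for (fc in F_COLUMNS) {
    v <- df[[fc]]
    ok <- is.logical(v) | v %in% c(0, 1, "0", "1", "TRUE", "FALSE")
    flag(!ok, sprintf("%s not boolean", fc))
  }
  ts_ok <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}", as.character(df$timestamp))
  flag(!ts_ok, "timestamp not ISO-8601")
  bad <- !is.na(reasons)
  log <- df[!bad, , drop = FALSE]
  for (fc in F_COLUMNS) log[[fc]] <- as.logical(as.character(log[[fc]]) %in%
                                                  c("1", "TRUE")) | log[[fc]] %in% TRUE
  for (cl in setdiff(REVIEW_COLUMNS, F_COLUMNS)) log[[cl]] <- as.character(log[[cl]])
  log <- log[, c(REVIEW_COLUMNS, setdiff(names(df), REVIEW_COLUMNS)), drop = FALSE]
  rownames(log) <- NULL
  class(log) <- c("review_log", "data.frame")
  list(log = log,
       rejected = data.frame(row = which(bad),
                             study_id = as.character(df$study_id[bad]),
                             reason = reasons[bad], stringsAsFactors = FALSE))
}

#' Read / write review-log CSV
#'
#' The interchange format is RFC 4180 CSV (UTF-8, header row) with the
#' fixed column order `study_id, reviewer, timestamp, q_brain_mask,
#' q_tumor_seg, q_csf_roi, q_registration, f_study_artifact,
#' f_image_unusable, f_bias_field, f_normalization_failure, f_no_pngs,
#' f_needs_review, csf_location, comment`. Booleans are serialized as 0/1.
#' Unknown columns are preserved as extras; missing mandatory columns raise
#' a schema error naming them. `import_review_log(export_review_log(x))`
#' is the identity field-for-field.
#'
#' @param file CSV path.
#' @return `import_review_log()` returns a `review_log`;
#'   schema-invalid rows raise an error carrying the row-level report.
#' @export
import_review_log <- function(file) {
  if (!file.exists(file)) stop_absent_input("review log not found: %s", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", na.strings = character())
  v <- validate_review_log(df)
  if (nrow(v$rejected))
    stop_schema("review log '%s' has %d invalid row(s); first: row %d (%s)",
                file, nrow(v$rejected), v$rejected$row[1], v$rejected$reason[1])
  v$log
}

#' @param log a `review_log`.
#' @rdname import_review_log
#' @export
export_review_log <- function(log, file) {
  df <- as.data.frame(log)
  for (fc in F_COLUMNS) df[[fc]] <- as.integer(df[[fc]])
  extras <- setdiff(names(df), REVIEW_COLUMNS)
  df <- df[, c(REVIEW_COLUMNS, extras), drop = FALSE]
  # write.csv fixes qmethod = "double", i.e. RFC 4180 quote doubling
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Combined study quality classification
#'
#' Collapses one review entry to a single three-level class with a total
#' severity order `failure > minor_errors > acceptable` (max severity wins):
#' `failure` if any quality category is `fail` or any failure-severity flag
#' (`study_artifact`, `image_unusable`, `normalization_failure`) is set;
#' else `minor_errors` if any category is `poor` or any minor-severity flag
#' (`bias_field`) is set; else `acceptable`. `no_pngs` and `needs_review`
#' gate review completeness, not quality, and never affect the class. The
#' flag-to-severity mapping is configurable.
#'
#' @param log a `review_log` (any number of rows).
#' @param failure_flags,minor_flags flag names (without the `f_` prefix)
#'   mapped to failure / minor severity.
#' @return ordered factor over `acceptable < minor_errors < failure`.
#' @export
classify_combined <- function(log,
                              failure_flags = c("study_artifact", "image_unusable",
                                                "normalization_failure"),
                              minor_flags = "bias_field") {
  qm <- vapply(Q_COLUMNS, function(cl) as.character(log[[cl]]),
               character(nrow(log)))
  qm <- matrix(qm, nrow = nrow(log))
  flagged <- function(flags) {
    if (length(flags) == 0) return(rep(FALSE, nrow(log)))
    cols <- paste0("f_", flags)
    rowSums(matrix(vapply(cols, function(cl) log[[cl]] %in% TRUE,
                          logical(nrow(log))), nrow = nrow(log))) > 0
  }
  fail <- rowSums(qm == "fail") > 0 | flagged(failure_flags)
  minor <- rowSums(qm == "poor") > 0 | flagged(minor_flags)
  cls <- ifelse(fail, "failure", ifelse(minor, "minor_errors", "acceptable"))
  factor(cls, levels = QUALITY_CLASSES, ordered = TRUE)
}

#' Merge review logs
#'
#' Union by `study_id`; where both logs review the same study the entry
#' with the later timestamp wins, with a deterministic tie-break by
#' reviewer name and then by the lexicographic serialization of the row.
#' Schema-invalid rows are rejected with a row-level report (attached as
#' attribute `"rejected"` with a warning), never silently dropped.
#'
#' @param a,b `review_log`s (or data.frames with the schema columns).
#' @return merged `review_log`, sorted by `study_id`.
#' @export
merge_logs <- function(a, b) {
  va <- validate_review_log(as.data.frame(a))
  vb <- validate_review_log(as.data.frame(b))
  rejected <- rbind(
    if (nrow(va$rejected)) cbind(source = "a", va$rejected),
    if (nrow(vb$rejected)) cbind(source = "b", vb$rejected))
  if (is.null(rejected))
    rejected <- data.frame(source = character(), row = integer(),
                           study_id = character(), reason = character())
  both <- rbind(va$log, vb$log)
  if (nrow(both)) {
    ser <- apply(both, 1, function(r) paste(r, collapse = "\x1f"))
    ord <- order(both$study_id, both$timestamp, both$reviewer, ser)
    both <- both[ord, , drop = FALSE]
    both <- both[!duplicated(both$study_id, fromLast = TRUE), , drop = FALSE]
    rownames(both) <- NULL
  }
  class(both) <- c("review_log", "data.frame")
  if (nrow(rejected)) {
    warning(sprintf("%d schema-invalid row(s) rejected during merge", nrow(rejected)))
    attr(both, "rejected") <- rejected
  }
  both
}

pct1 <- function(x) round(100 * x, 1)
pct0 <- function(x) round(100 * x)

#' Aggregate a review log into a summary table
#'
#' Tallies per-category acceptable / minor-error / failure counts (image
#' quality and normalization are two-level: they are only evaluated as
#' acceptable or failure), the combined review result via
#' [classify_combined()], per-category failure rates, and the overall
#' acceptable fraction `(acceptable + minor_errors) / n`, reported at one
#' decimal and at the nearest integer. Each category's three counts are
#' checked to sum to the number of reviewed studies.
#'
#' @param object a nonempty `review_log`.
#' @param ... unused.
#' @return object of class `review_summary`: list with `n`, `categories`
#'   (data.frame `category`, `acceptable`, `minor_errors`, `failure`,
#'   `failure_rate_pct`), `combined` (named counts), `acceptable_fraction_pct`,
#'   `acceptable_fraction_pct_int`, `n_acceptable_or_minor`.
#' @export
summary.review_log <- function(object, ...) {
  log <- object
  n <- nrow(log)
  if (n == 0) stop_empty_log("cannot summarize an empty review log")
  rows <- lapply(names(REVIEW_CATEGORIES), function(cat) {
    def <- REVIEW_CATEGORIES[[cat]]
    if (def$kind == "flag") {
      failn <- sum(Reduce(`|`, lapply(def$cols, function(cl) log[[cl]] %in% TRUE)))
      data.frame(category = cat, acceptable = n - failn, minor_errors = NA_integer_,
                 failure = failn, stringsAsFactors = FALSE)
    } else {
      v <- as.character(log[[def$cols]])
      data.frame(category = cat, acceptable = sum(v == "acceptable"),
                 minor_errors = sum(v == "poor"), failure = sum(v == "fail"),
                 stringsAsFactors = FALSE)
    }
  })
  categories <- do.call(rbind, rows)
  sums <- rowSums(categories[, c("acceptable", "minor_errors", "failure")],
                  na.rm = TRUE)
  if (!all(sums == n))
    stop_schema("internal tally error: category counts do not sum to n")
  categories$failure_rate_pct <- pct1(categories$failure / n)
  comb <- table(classify_combined(log))
  if (sum(comb) != n) stop_schema("internal tally error in combined counts")
  acc_frac <- (comb[["acceptable"]] + comb[["minor_errors"]]) / n
  structure(list(n = n, categories = categories,
                 combined = stats::setNames(as.integer(comb), names(comb)),
                 acceptable_fraction_pct = pct1(acc_frac),
                 acceptable_fraction_pct_int = pct0(acc_frac),
                 n_acceptable_or_minor = as.integer(comb[["acceptable"]] +
                                                      comb[["minor_errors"]])),
            class = "review_summary")
}

#' @param log a nonempty `review_log`.
#' @rdname summary.review_log
#' @export
summarize_reviews <- function(log) summary.review_log(log)

#' @export
print.review_summary <- function(x, ...) {
  cat(sprintf("Review summary of %d studies\n", x$n))
  df <- x$categories
  df$minor_errors <- ifelse(is.na(df$minor_errors), "NA", df$minor_errors)
  print(df, row.names = FALSE)
  cat(sprintf("Review result: %d acceptable / %d minor errors / %d failure\n",
              x$combined[["acceptable"]], x$combined[["minor_errors"]],
              x$combined[["failure"]]))
  cat(sprintf("Acceptable quality: %d of %d (%g%%, %.1f%%)\n",
              x$n_acceptable_or_minor, x$n, x$acceptable_fraction_pct_int,
              x$acceptable_fraction_pct))
  invisible(x)
}

#' Volume RMSE stratified by tumor-segmentation quality
#'
#' Compares segmented and reference tumor volumes within strata of the
#' *tumor-segmentation* review category (not the combined class). Following
#' the review protocol, only studies whose image quality, registration and
#' brain mask are all clean (no `poor`, no `fail`, no image-quality flags)
#' are eligible, so that segmentation quality is the deciding factor; the
#' filter can be replaced.
#'
#' @param log a `review_log`.
#' @param measured,reference named numeric vectors of volumes (cm^3), names
#'   are study IDs.
#' @param eligibility `NULL` for the default filter, a logical vector along
#'   `log`, or a `function(log)` returning one.
#' @return data.frame with columns `class` (`acceptable`, `minor_errors`,
#'   `failure`), `n`, `rmse` (`NA` where `n` is 0).
#' @export
rmse_by_quality <- function(log, measured, reference, eligibility = NULL) {
  if (is.null(eligibility)) {
    eligible <- !(log$f_study_artifact %in% TRUE) &
      !(log$f_image_unusable %in% TRUE) &
      log$q_registration == "acceptable" & log$q_brain_mask == "acceptable"
  } else if (is.function(eligibility)) {
    eligible <- eligibility(log)
  } else eligible <- eligibility
  stopifnot(length(eligible) == nrow(log))
  strat <- c(acceptable = "acceptable", poor = "minor_errors", fail = "failure")
  ids <- intersect(log$study_id[eligible], intersect(names(measured), names(reference)))
  sub <- log[log$study_id %in% ids, , drop = FALSE]
  out <- lapply(QUALITY_CLASSES, function(cl) {
    sid <- sub$study_id[strat[as.character(sub$q_tumor_seg)] == cl]
    err <- measured[sid] - reference[sid]
    data.frame(class = cl, n = length(sid),
               rmse = if (length(sid)) sqrt(mean(err^2)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a synthetic review log matching requested count margins
#'
#' Constructs a deterministic review log of `n` studies whose per-category
#' failure and minor-error counts equal `fail_counts` / `minor_counts`, and
#' (optionally) whose combined classification has exactly
#' `combined_failures` failure studies and `combined_minor` minor-error
#' studies. Used to exercise the aggregation machinery against published
#' count tables, where per-study co-occurrence is unobserved: fail marks
#' are packed cyclically onto the failure pool, poor marks onto the minor
#' pool with spill onto failure studies, skipping same-category conflicts.
#' The result is revalidated against every requested margin.
#'
#' @param n number of studies.
#' @param fail_counts named integer vector over categories `image_quality`,
#'   `brain_mask`, `registration`, `tumor_segmentation`, `csf_localization`,
#'   `normalization`.
#' @param minor_counts named integer vector over the three-level categories
#'   (`brain_mask`, `registration`, `tumor_segmentation`, `csf_localization`).
#' @param combined_failures,combined_minor target combined counts; default
#'   places every mark on its own study (no co-occurrence).
#' @param reviewer,timestamp entry metadata.
#' @return a `review_log` of `n` rows.
#' @export
review_log_from_counts <- function(n, fail_counts = c(), minor_counts = c(),
                                   combined_failures = NULL,
                                   combined_minor = NULL,
                                   reviewer = "synthetic-oracle",
                                   timestamp = "2022-01-01T00:00:00Z") {
  qcat <- c(brain_mask = "q_brain_mask", registration = "q_registration",
            tumor_segmentation = "q_tumor_seg", csf_localization = "q_csf_roi")
  fcat <- c(image_quality = "f_image_unusable",
            normalization = "f_normalization_failure")
  if (!all(names(fail_counts) %in% c(names(qcat), names(fcat))))
    stop_parameter("unknown category in fail_counts")
  if (!all(names(minor_counts) %in% names(qcat)))
    stop_parameter("minor_counts only apply to three-level categories")
  totF <- sum(fail_counts); totM <- sum(minor_counts)
  FF <- if (is.null(combined_failures)) totF else combined_failures
  MM <- if (is.null(combined_minor)) totM else combined_minor
  if (FF > totF || (totF > 0 && FF == 0))
    stop_parameter("combined_failures incompatible with fail_counts")
  if (length(fail_counts) && any(fail_counts > FF))
    stop_parameter("a category fail count exceeds combined_failures")
  if (MM > totM) stop_parameter("combined_minor exceeds available poor marks")
  if (FF + MM > n) stop_parameter("combined counts exceed n")

  qv <- matrix("acceptable", nrow = n, ncol = length(qcat),
               dimnames = list(NULL, names(qcat)))
  fl <- matrix(FALSE, nrow = n, ncol = length(fcat),
               dimnames = list(NULL, names(fcat)))
  place <- function(cat, value, pool, p) {
    tries <- 0L
    repeat {
      s <- pool[p]
      taken <- if (cat %in% names(qcat)) qv[s, cat] != "acceptable" else fl[s, cat]
      if (!taken) break
      p <- p %% length(pool) + 1L
      tries <- tries + 1L
      if (tries > length(pool))
        stop_parameter("requested counts are not jointly satisfiable")
    }
    if (cat %in% names(qcat)) qv[s, cat] <<- value else fl[s, cat] <<- TRUE
    p %% length(pool) + 1L
  }
  if (FF > 0) {
    pool <- seq_len(FF); p <- 1L
    for (cat in names(fail_counts))
      for (i in seq_len(fail_counts[[cat]])) p <- place(cat, "fail", pool, p)
  }
  if (totM > 0) {
    pool <- c(FF + seq_len(MM), seq_len(FF)); p <- 1L
    for (cat in names(minor_counts))
      for (i in seq_len(minor_counts[[cat]])) p <- place(cat, "poor", pool, p)
  }

  log <- data.frame(study_id = sprintf("S%05d", seq_len(n)),
                    reviewer = reviewer, timestamp = timestamp,
                    q_brain_mask = qv[, "brain_mask"],
                    q_tumor_seg = qv[, "tumor_segmentation"],
                    q_csf_roi = qv[, "csf_localization"],
                    q_registration = qv[, "registration"],
                    f_study_artifact = FALSE,
                    f_image_unusable = fl[, "image_quality"],
                    f_bias_field = FALSE,
                    f_normalization_failure = fl[, "normalization"],
                    f_no_pngs = FALSE, f_needs_review = FALSE,
                    csf_location = "", comment = "",
                    stringsAsFactors = FALSE)
  class(log) <- c("review_log", "data.frame")
  comb <- table(classify_combined(log))
  ok <- comb[["failure"]] == FF && comb[["minor_errors"]] == MM
  for (cat in names(fail_counts)) {
    got <- if (cat %in% names(qcat)) sum(qv[, cat] == "fail") else sum(fl[, cat])
    ok <- ok && got == fail_counts[[cat]]
  }
  for (cat in names(minor_counts))
    ok <- ok && sum(qv[, cat] == "poor") == minor_counts[[cat]]
  if (!ok) stop_parameter("requested counts are not jointly satisfiable")
  log
}
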