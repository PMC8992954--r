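#' Study manifests and study records
#'
#' A study manifest is a CSV (RFC 4180, UTF-8, header row) with one row per
#' imaging study. Recognized columns: `study_id`, the four anatomical path
#' columns `path_T1`, `path_T1C`, `path_T2`, `path_FLAIR`, annotation paths
#' `path_brain_mask`, `path_tumor_seg`, `path_csf_roi`, optional reference
#' tumor volumes `ref_total_cm3`, `ref_enhancing_cm3`, optional functional
#' maps as `path_func_<name>` columns, plus any free extra columns (carried
#' through to reports). Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest CSV path.
#' @return a data.frame of class `study_manifest` (one row per study, paths
#'   resolved absolute where the file column is non-missing).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_absent_input("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"study_id" %in% names(df))
    stop_schema("manifest lacks mandatory column: study_id")
  df$study_id <- as.character(df$study_id)
  if (any(!nzchar(df$study_id)) || anyNA(df$study_id))
    stop_schema("manifest has empty study_id values")
  if (anyDuplicated(df$study_id))
    stop_schema("duplicate study_id in manifest: %s",
                paste(unique(df$study_id[duplicated(df$study_id)]), collapse = ", "))
  pc <- grep("^path_", names(df), value = TRUE)
  base <- dirname(normalizePath(path, mustWork = TRUE))
  for (col in pc) {
    v <- as.character(df[[col]])
    v[!is.na(v) & !nzchar(v)] <- NA
    rel <- !is.na(v) & !grepl("^(/|[A-Za-z]:)", v)
    v[rel] <- file.path(base, v[rel])
    df[[col]] <- v
  }
  anat <- intersect(paste0("path_", c("T1", "T1C", "T2", "FLAIR")), names(df))
  if (length(anat) == 0)
    stop_schema("manifest has no anatomical path columns (path_T1 ... path_FLAIR)")
  has_anat <- rowSums(!is.na(as.matrix(df[anat]))) > 0
  if (any(!has_anat))
    stop_schema("studies with no anatomical image: %s",
                paste(df$study_id[!has_anat], collapse = ", "))
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' @param manifest a `study_manifest` data.frame.
#' @param file output CSV path.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(as.data.frame(manifest), file, row.names = FALSE, na = "")
  invisible(file)
}

#' Build a study record from one manifest row
#'
#' A `study_record` is the per-case file set: anatomical modalities,
#' optional functional maps, annotations, optional reference tumor volumes
#' and free extra fields. Missing annotation paths are recorded as absent,
#' not errors.
#'
#' @param manifest a `study_manifest`.
#' @param study_id which study to extract.
#' @return object of class `study_record` with elements `study_id`,
#'   `anatomical`, `functional`, `annotations` (named character vectors of
#'   existing columns, `NA`s dropped), `reference_volumes` (named numeric or
#'   NULL) and `extras` (named list).
#' @export
study_record <- function(manifest, study_id) {
  i <- match(study_id, manifest$study_id)
  if (is.na(i)) stop_absent_input("study '%s' not in manifest", study_id)
  row <- manifest[i, , drop = FALSE]
  grab <- function(cols) {
    cols <- intersect(cols, names(row))
    v <- vapply(cols, function(cl) as.character(row[[cl]]), "")
    names(v) <- sub("^path_(func_)?", "", cols)
    v[!is.na(v) & nzchar(v)]
  }
  anat <- grab(paste0("path_", c("T1", "T1C", "T2", "FLAIR")))
  func <- grab(grep("^path_func_", names(row), value = TRUE))
  ann <- grab(paste0("path_", c("brain_mask", "tumor_seg", "csf_roi")))
  refv <- NULL
  if (all(c("ref_total_cm3", "ref_enhancing_cm3") %in% names(row)) &&
      !is.na(row$ref_total_cm3)) {
    refv <- c(total = as.numeric(row$ref_total_cm3),
              enhancing = as.numeric(row$ref_enhancing_cm3))
  }
  known <- c("study_id", grep("^(path_|ref_)", names(row), value = TRUE))
  extras <- as.list(row[setdiff(names(row), known)])
  structure(list(study_id = row$study_id, anatomical = anat,
                 functional = func, annotations = ann,
                 reference_volumes = refv, extras = extras),
            class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s\n  anatomical: %s\n  annotations: %s\n",
              x$study_id,
              paste(names(x$anatomical), collapse = ", "),
              if (length(x$annotations)) paste(names(x$annotations), collapse = ", ")
              else "(none)"))
  if (length(x$functional))
    cat("  functional:", paste(names(x$functional), collapse = ", "), "\n")
  invisible(x)
}

#' All study records of a manifest
#' @inheritParams study_record
#' @return named list of [study_record]s.
#' @export
study_records <- function(manifest) {
  out <- lapply(manifest$study_id, function(id) study_record(manifest, id))
  stats::setNames(out, manifest$study_id)
}
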