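#' Normalized-intensity range check
#'
#' For z-score-normalized images, in-brain intensities should fall in an
#' expected range such as `[-5, 5]`; ranges far outside it indicate a
#' normalization failure. To tolerate isolated hot voxels the check uses
#' robust percentiles (default 0.5th / 99.5th) of the within-brain
#' intensities rather than the min/max.
#'
#' @param image a [voxel_grid].
#' @param brain a [label_map] (brain mask) of the same shape.
#' @param expected length-2 expected interval, `expected[1] < expected[2]`.
#' @param robust_pct length-2 percentile pair for the robust low/high.
#' @return list with `flag` (TRUE if robust low < expected low or robust
#'   high > expected high; `NA` for an empty mask), `stats` (named `low`,
#'   `high`) and `status` (`"ok"` or `"empty_mask"`).
#' @export
normalization_check <- function(image, brain, expected = c(-5, 5),
                                robust_pct = c(0.5, 99.5)) {
  img <- slice_source(image)
  msk <- slice_source(brain) != 0
  if (!identical(dim(img), dim(msk)))
    stop_geometry("image and brain mask shapes differ")
  if (!(expected[1] < expected[2]))
    stop_parameter("expected interval must have low < high")
  if (!any(msk)) {
    warning("empty brain mask: normalization check indeterminate")
    return(list(flag = NA, stats = c(low = NA_real_, high = NA_real_),
                status = "empty_mask"))
  }
  q <- stats::quantile(img[msk], robust_pct / 100, names = FALSE)
  list(flag = unname(q[1] < expected[1] || q[2] > expected[2]),
       stats = c(low = q[1], high = q[2]), status = "ok")
}

#' Fraction of a segmentation outside the brain mask
#'
#' Fraction of segmentation-foreground voxels falling on brain-mask
#' background; a positive value signals a truncated field of view or a
#' segmentation escaping the brain. 0 for an empty segmentation.
#'
#' @param seg,brain [label_map]s of the same shape.
#' @return fraction in `[0, 1]`.
#' @export
seg_outside_mask <- function(seg, brain) {
  s <- slice_source(seg) != 0
  b <- slice_source(brain) != 0
  if (!identical(dim(s), dim(b)))
    stop_geometry("segmentation and brain mask shapes differ")
  n <- sum(s)
  if (n == 0) return(0)
  sum(s & !b) / n
}

#' Tumor volumes from a multi-label segmentation
#'
#' `total` is the volume of all nonzero labels (the total T2-FLAIR
#' hyperintensity under the default three-label convention); `enhancing` is
#' the volume of the label with role `"enhancing"` in `label_roles`, or
#' `NA` (absent, not zero) when no label has that role.
#'
#' @param seg a [label_map].
#' @param label_roles named integer vector role -> label value.
#' @return named numeric `c(total = , enhancing = )` in cm^3.
#' @export
tumor_volumes <- function(seg, label_roles = c(enhancing = 1L, necrosis = 2L,
                                               edema = 3L)) {
  stopifnot(inherits(seg, "label_map"))
  all_labels <- unique(as.vector(seg$grid$data))
  all_labels <- all_labels[all_labels != 0]
  total <- if (length(all_labels)) label_volume_cm3(seg, all_labels) else 0
  enh <- if ("enhancing" %in% names(label_roles))
    label_volume_cm3(seg, label_roles[["enhancing"]]) else NA_real_
  c(total = total, enhancing = enh)
}

#' QC configuration
#' @param expected_range expected normalized-intensity interval.
#' @param robust_pct robust percentile pair for [normalization_check()].
#' @param label_roles tumor label role map for [tumor_volumes()].
#' @return list of class `qc_config`.
#' @export
qc_config <- function(expected_range = c(-5, 5), robust_pct = c(0.5, 99.5),
                      label_roles = c(enhancing = 1L, necrosis = 2L, edema = 3L)) {
  structure(list(expected_range = expected_range, robust_pct = robust_pct,
                 label_roles = label_roles), class = "qc_config")
}

#' Automatic screening metrics for one study
#'
#' Computes the advisory pre-flags surfaced next to the snapshot panels:
#' per-modality normalization checks, the fraction of the tumor segmentation
#' outside the brain mask, tumor volumes, missing input files, and (when a
#' [render_study()] result is supplied) the expected-but-absent panel files
#' that feed the reviewer's "No PNGs" flag. These metrics never
#' auto-populate the human review fields.
#'
#' @param study a [study_record].
#' @param snapshots optional `snapshot_set` from [render_study()].
#' @param config a [qc_config()].
#' @return object of class `study_qc`: list with `study_id`, `norm` (data
#'   frame modality/low/high/flag), `normalization_flags` (named logical),
#'   `tumor_total_cm3`, `tumor_enhancing_cm3`, `seg_outside_brain_fraction`,
#'   `missing_inputs`, `missing_panels`.
#' @export
compute_study_qc <- function(study, snapshots = NULL, config = qc_config()) {
  stopifnot(inherits(study, "study_record"))
  paths <- c(study$anatomical, study$functional, study$annotations)
  missing_inputs <- paths[!file.exists(paths)]

  load_ok <- function(p, loader, ...) {
    if (is.null(p) || is.na(p) || !file.exists(p)) return(NULL)
    tryCatch(loader(p, ...), error = function(e) NULL)
  }
  brain <- load_ok(study$annotations["brain_mask"][[1]],
                   function(p) reorient_canonical(read_label_map(p)))
  seg <- load_ok(study$annotations["tumor_seg"][[1]],
                 function(p) reorient_canonical(read_label_map(
                   p, stats::setNames(names(config$label_roles),
                                      as.character(config$label_roles)))))

  norm_rows <- list()
  for (m in names(study$anatomical)) {
    g <- load_ok(study$anatomical[[m]], function(p) reorient_canonical(read_volume(p)))
    if (is.null(g) || is.null(brain)) {
      norm_rows[[m]] <- data.frame(modality = m, low = NA_real_, high = NA_real_,
                                   flag = NA, stringsAsFactors = FALSE)
      next
    }
    nc <- suppressWarnings(
      normalization_check(g, brain, expected = config$expected_range,
                          robust_pct = config$robust_pct))
    norm_rows[[m]] <- data.frame(modality = m, low = nc$stats[["low"]],
                                 high = nc$stats[["high"]], flag = nc$flag,
                                 stringsAsFactors = FALSE)
  }
  norm <- if (length(norm_rows)) do.call(rbind, c(norm_rows, make.row.names = FALSE))
          else data.frame(modality = character(), low = numeric(),
                          high = numeric(), flag = logical())

  vols <- c(total = NA_real_, enhancing = NA_real_)
  outside <- NA_real_
  if (!is.null(seg)) {
    vols <- tumor_volumes(seg, config$label_roles)
    if (!is.null(brain)) outside <- seg_outside_mask(seg, brain)
  }

  missing_panels <- character()
  if (!is.null(snapshots)) {
    p <- snapshots$panels
    missing_panels <- p$file[p$status != "rendered" | !file.exists(p$file)]
  }

  structure(list(
    study_id = study$study_id,
    norm = norm,
    normalization_flags = stats::setNames(norm$flag, norm$modality),
    tumor_total_cm3 = unname(vols["total"]),
    tumor_enhancing_cm3 = unname(vols["enhancing"]),
    seg_outside_brain_fraction = outside,
    missing_inputs = unname(missing_inputs),
    missing_panels = missing_panels), class = "study_qc")
}

#' @export
print.study_qc <- function(x, ...) {
  cat(sprintf("<study_qc> %s: total %.2f cm^3, enhancing %.2f cm^3, outside-brain %.3f\n",
              x$study_id, x$tumor_total_cm3, x$tumor_enhancing_cm3,
              x$seg_outside_brain_fraction))
  fl <- x$normalization_flags
  cat("  normalization flags:",
      if (length(fl)) paste(sprintf("%s=%s", names(fl), fl), collapse = " ")
      else "(none)", "\n")
  if (length(x$missing_inputs))
    cat("  missing inputs:", length(x$missing_inputs), "\n")
  invisible(x)
}

#' Write a per-study QC JSON sidecar
#' @param qc a `study_qc`.
#' @param file output JSON path.
#' @export
write_qc_json <- function(qc, file) {
  jsonlite::write_json(unclass(qc), file, auto_unbox = TRUE, dataframe = "rows",
                       digits = NA, na = "null")
  invisible(file)
}

#' Tabulate QC results for a cohort
#' @param qcs list of `study_qc` objects.
#' @return data.frame with one row per study (QC columns ready to merge into
#'   the manifest for the report builder).
#' @export
qc_table <- function(qcs) {
  do.call(rbind, lapply(qcs, function(q) data.frame(
    study_id = q$study_id,
    tumor_total_cm3 = q$tumor_total_cm3,
    tumor_enhancing_cm3 = q$tumor_enhancing_cm3,
    seg_outside_brain_fraction = q$seg_outside_brain_fraction,
    normalization_flagged = any(q$normalization_flags %in% TRUE),
    n_missing_inputs = length(q$missing_inputs),
    n_missing_panels = length(q$missing_panels),
    stringsAsFactors = FALSE)))
}
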