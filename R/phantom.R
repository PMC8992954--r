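# Geometric brain phantom: ellipsoidal brain, concentric-sphere three-label
# tumor (necrotic core / enhancing rim / edema), spherical ventricle with a
# CSF ROI. Emulates processed study inputs: four co-registered anatomical
# modalities with tissue-dependent contrast, Gaussian noise, and intensities
# z-score-normalized within the brain mask.

PHANTOM_MODALITIES <- c("T1", "T1C", "T2", "FLAIR")
FAILURE_MODES <- c("misregistration", "bias_field", "normalization_break",
                   "cropped_fov", "corrupt_seg", "missing_file")

# Tissue intensity means (arbitrary raw units, before z-normalization).
# Contrast-to-noise is chosen so that, after z-scoring within the brain
# mask, clean in-brain intensities stay inside the expected [-5, 5] range
# (robust 99.5th percentile around 3) as they do for real normalized MRI.
PHANTOM_TISSUE_MEANS <- matrix(
  c(0, 100, 60, 85, 95, 75,      # T1: CSF dark
    0, 100, 60, 85, 140, 75,     # T1C: enhancing rim bright
    0, 100, 145, 135, 115, 120,  # T2: CSF bright, edema bright
    0, 100, 65, 140, 115, 95),   # FLAIR: CSF suppressed, edema bright
  nrow = 4, byrow = TRUE,
  dimnames = list(PHANTOM_MODALITIES,
                  c("background", "brain", "csf", "edema", "enhancing",
                    "necrosis")))

#' Phantom study parameters
#'
#' Geometry is specified in mm in the scanner frame so the same anatomy can
#' be generated at any grid resolution; the default field of view is 192 mm
#' (64^3 voxels at 3 mm isotropic spacing). All stochastic draws are fixed
#' by `seed`.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing_mm voxel spacing; default `192 / shape` mm.
#' @param brain_semiaxes_mm ellipsoid semi-axes of the brain.
#' @param tumor_center_mm tumor center relative to the brain center.
#' @param tumor_radii_mm named radii `necrosis < enhancing < edema` of the
#'   concentric tumor compartments.
#' @param ventricle_center_mm,ventricle_radius_mm CSF-bright ventricle sphere.
#' @param csf_roi_radius_mm radius of the CSF ROI (concentric with the
#'   ventricle).
#' @param tissue_means modality x tissue raw intensity means.
#' @param noise_sd Gaussian noise standard deviation (raw units).
#' @param seed RNG seed fixing every stochastic draw.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(64L, 64L, 64L),
                           spacing_mm = 192 / shape,
                           brain_semiaxes_mm = c(78, 90, 66),
                           tumor_center_mm = c(24, 10, 26),
                           tumor_radii_mm = c(necrosis = 8, enhancing = 15,
                                              edema = 24),
                           ventricle_center_mm = c(-6, 6, 0),
                           ventricle_radius_mm = 9,
                           csf_roi_radius_mm = 6.5,
                           tissue_means = PHANTOM_TISSUE_MEANS,
                           noise_sd = 12,
                           seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 8),
            all(tumor_radii_mm > 0), diff(tumor_radii_mm) > 0,
            ventricle_radius_mm > 0, csf_roi_radius_mm > 0, noise_sd >= 0)
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 brain_semiaxes_mm = brain_semiaxes_mm,
                 tumor_center_mm = tumor_center_mm,
                 tumor_radii_mm = tumor_radii_mm,
                 ventricle_center_mm = ventricle_center_mm,
                 ventricle_radius_mm = ventricle_radius_mm,
                 csf_roi_radius_mm = csf_roi_radius_mm,
                 tissue_means = tissue_means, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

new_study_record <- function(study_id, anatomical = character(),
                             functional = character(),
                             annotations = character(),
                             reference_volumes = NULL, extras = list()) {
  structure(list(study_id = study_id, anatomical = anatomical,
                 functional = functional, annotations = annotations,
                 reference_volumes = reference_volumes, extras = extras),
            class = "study_record")
}

phantom_affine <- function(shape, spacing) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(spacing, 3)
  A[1:3, 4] <- -(shape - 1) / 2 * spacing   # brain center at world origin
  A
}

# world-mm coordinate arrays of every voxel center
phantom_coords <- function(p) {
  ax <- lapply(1:3, function(d)
    (seq_len(p$shape[d]) - 1 - (p$shape[d] - 1) / 2) * p$spacing_mm[d])
  list(x = array(rep(ax[[1]], times = prod(p$shape[2:3])), p$shape),
       y = array(rep(rep(ax[[2]], each = p$shape[1]), times = p$shape[3]), p$shape),
       z = array(rep(ax[[3]], each = prod(p$shape[1:2])), p$shape))
}

#' Generate one synthetic phantom study
#'
#' Writes four co-registered anatomical NIfTI volumes with tissue-dependent
#' contrast and Gaussian noise, z-score-normalized within the brain mask,
#' plus the brain mask, a three-label tumor segmentation (1 = enhancing,
#' 2 = necrosis, 3 = edema) and a binary CSF ROI, and a ground-truth JSON
#' recording label voxel counts, true volumes and the applied parameters.
#' Regeneration with the same parameters is byte-identical.
#'
#' @param p a [phantom_params()].
#' @param dir output directory (created).
#' @param study_id study identifier used in file names.
#' @return a [study_record()] with an extra `truth_json` entry in `extras`.
#' @export
make_phantom_study <- function(p, dir, study_id = "phantom001") {
  stopifnot(inherits(p, "phantom_params"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_mriscreen("mriscreen_io_error", "cannot create output dir '%s'", dir)
  co <- phantom_coords(p)
  ell <- (co$x / p$brain_semiaxes_mm[1])^2 + (co$y / p$brain_semiaxes_mm[2])^2 +
    (co$z / p$brain_semiaxes_mm[3])^2
  brain <- ell <= 1
  dv <- sqrt((co$x - p$ventricle_center_mm[1])^2 +
             (co$y - p$ventricle_center_mm[2])^2 +
             (co$z - p$ventricle_center_mm[3])^2)
  ventricle <- brain & dv <= p$ventricle_radius_mm
  csf_roi <- brain & dv <= p$csf_roi_radius_mm
  dt <- sqrt((co$x - p$tumor_center_mm[1])^2 + (co$y - p$tumor_center_mm[2])^2 +
             (co$z - p$tumor_center_mm[3])^2)
  r <- p$tumor_radii_mm
  tumor <- array(0L, p$shape)
  tumor[brain & dt <= r[["edema"]]] <- 3L
  tumor[brain & dt <= r[["enhancing"]]] <- 1L
  tumor[brain & dt <= r[["necrosis"]]] <- 2L

  tissue <- array(1L, p$shape)             # 1 = background
  tissue[brain] <- 2L                      # brain
  tissue[ventricle] <- 3L                  # csf
  tissue[tumor == 3L] <- 4L                # edema
  tissue[tumor == 1L] <- 5L                # enhancing
  tissue[tumor == 2L] <- 6L                # necrosis

  aff <- phantom_affine(p$shape, p$spacing_mm)
  files <- character()
  with_seed(p$seed, {
    for (m in PHANTOM_MODALITIES) {
      raw <- p$tissue_means[m, ][tissue] +
        stats::rnorm(prod(p$shape), 0, p$noise_sd)
      dim(raw) <- p$shape
      z <- (raw - mean(raw[brain])) / stats::sd(raw[brain])
      z[!brain] <- 0      # skull-stripped convention: background exactly 0
      f <- file.path(dir, sprintf("%s_%s.nii.gz", study_id, m))
      write_volume(voxel_grid(z, aff), f, datatype = "float")
      files[m] <- f
    }
  })
  ann <- character()
  for (nm in c("brain_mask", "tumor_seg", "csf_roi")) {
    arr <- switch(nm, brain_mask = array(as.numeric(brain), p$shape),
                  tumor_seg = array(as.numeric(tumor), p$shape),
                  csf_roi = array(as.numeric(csf_roi), p$shape))
    f <- file.path(dir, sprintf("%s_%s.nii.gz", study_id, nm))
    write_volume(voxel_grid(arr, aff), f, datatype = "uint8")
    ann[nm] <- f
  }
  vox_mm3 <- prod(p$spacing_mm)
  counts <- c(brain = sum(brain), csf_roi = sum(csf_roi),
              enhancing = sum(tumor == 1L), necrosis = sum(tumor == 2L),
              edema = sum(tumor == 3L))
  truth <- list(study_id = study_id, seed = p$seed,
                shape = p$shape, spacing_mm = p$spacing_mm,
                voxel_volume_mm3 = vox_mm3,
                voxel_counts = as.list(counts),
                true_total_cm3 = sum(counts[c("enhancing", "necrosis", "edema")]) *
                  vox_mm3 / 1000,
                true_enhancing_cm3 = counts[["enhancing"]] * vox_mm3 / 1000,
                failure_mode = "clean", failure_params = list())
  truth_file <- file.path(dir, sprintf("%s_truth.json", study_id))
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)
  new_study_record(study_id, anatomical = files, annotations = ann,
                   extras = list(truth_json = truth_file))
}

# ---- failure-mode machinery -------------------------------------------------

# in-plane rotation about the axial (S) axis, bilinear resampling, same grid;
# fill = 0 matches the skull-stripped background convention
rotate_axial <- function(arr, degrees, fill = 0) {
  d <- dim(arr)
  th <- degrees * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  gi <- rep(seq_len(d[1]), times = d[2]) - cx
  gj <- rep(seq_len(d[2]), each = d[1]) - cy
  # inverse mapping: source coordinates of each target pixel
  si <- cos(th) * gi + sin(th) * gj + cx
  sj <- -sin(th) * gi + cos(th) * gj + cy
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  ok <- i0 >= 1 & i0 < d[1] & j0 >= 1 & j0 < d[2]
  out <- array(fill, d)
  w00 <- (1 - fi) * (1 - fj); w10 <- fi * (1 - fj)
  w01 <- (1 - fi) * fj; w11 <- fi * fj
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    v <- rep(fill, d[1] * d[2])
    idx <- cbind(i0[ok], j0[ok])
    v[ok] <- w00[ok] * sl[idx] +
      w10[ok] * sl[cbind(i0[ok] + 1L, j0[ok])] +
      w01[ok] * sl[cbind(i0[ok], j0[ok] + 1L)] +
      w11[ok] * sl[cbind(i0[ok] + 1L, j0[ok] + 1L)]
    out[, , k] <- v
  }
  out
}

shift3 <- function(arr, by, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- by[ax]
    dst[[ax]] <- seq_len(d[ax])[(1 + max(s, 0)):(d[ax] + min(s, 0))]
    src[[ax]] <- dst[[ax]] - s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

dilate3 <- function(mask, r) {
  out <- mask
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shift3(mask, c(dx, dy, dz), fill = FALSE)
  }
  out
}

#' Inject a failure mode into a phantom study
#'
#' Degrades exactly one input artifact of a written study, emulating the
#' failure modes a data review is meant to catch:
#' \describe{
#'   \item{misregistration}{a rigid in-plane misalignment of one modality:
#'     rotation about the axial axis by `degrees` (bilinear resampling on
#'     the same grid) plus a `translation_mm` offset.}
#'   \item{bias_field}{multiplies one modality by a smooth low-frequency
#'     field `1 + amplitude * gradient`.}
#'   \item{normalization_break}{multiplies one modality's intensities by
#'     `factor`.}
#'   \item{cropped_fov}{zeroes the top `fraction` of axial slices of all
#'     anatomical images and the brain mask, leaving the tumor map intact,
#'     so the segmentation exits the brain volume.}
#'   \item{corrupt_seg}{shifts the tumor map by `shift_vox` voxels and
#'     dilates it by `dilate_vox`, inflating the measured volume; the truth
#'     file keeps the pre-corruption volumes.}
#'   \item{missing_file}{removes one modality's file.}
#' }
#' The study's truth JSON is updated with the injected mode and parameters.
#'
#' @param study a [study_record] as returned by [make_phantom_study()].
#' @param mode one of `misregistration`, `bias_field`,
#'   `normalization_break`, `cropped_fov`, `corrupt_seg`, `missing_file`.
#' @param magnitude named list overriding the mode's magnitude defaults
#'   (`degrees = 10`, `amplitude = 0.3`, `factor = 100`, `fraction = 0.35`,
#'   `dilate_vox = 2`, `shift_vox = c(4, 0, 0)`, `modality` per mode).
#' @param seed RNG seed (reserved for stochastic magnitudes; the default
#'   degradations are deterministic).
#' @return the modified [study_record] (files degraded in place).
#' @export
inject_failure <- function(study, mode, magnitude = list(), seed = 1L) {
  if (!mode %in% FAILURE_MODES)
    stop_parameter("unknown failure mode '%s'", mode)
  mag <- utils::modifyList(switch(mode,
    misregistration = list(degrees = 10, translation_mm = c(10, 5, 0),
                           modality = "FLAIR"),
    bias_field = list(amplitude = 0.3, modality = "T1"),
    normalization_break = list(factor = 100, modality = "T2"),
    cropped_fov = list(fraction = 0.35),
    corrupt_seg = list(dilate_vox = 2L, shift_vox = c(4L, 0L, 0L)),
    missing_file = list(modality = "FLAIR")), magnitude)

  rewrite <- function(path, fun, datatype = "float") {
    g <- read_volume(path)
    g$data <- fun(g$data)
    write_volume(g, path, datatype = datatype)
  }
  if (mode == "misregistration") {
    g <- read_volume(study$anatomical[[mag$modality]])
    spacing <- sqrt(colSums(g$affine[1:3, 1:3]^2))
    shift_vox <- round(mag$translation_mm / spacing)
    g$data <- shift3(rotate_axial(g$data, mag$degrees), shift_vox, fill = 0)
    write_volume(g, study$anatomical[[mag$modality]], datatype = "float")
  } else if (mode == "bias_field") {
    rewrite(study$anatomical[[mag$modality]], function(d) {
      u <- seq(-1, 1, length.out = dim(d)[1])
      field <- array(rep(1 + mag$amplitude * u, times = prod(dim(d)[2:3])), dim(d))
      d * field
    })
  } else if (mode == "normalization_break") {
    rewrite(study$anatomical[[mag$modality]], function(d) d * mag$factor)
  } else if (mode == "cropped_fov") {
    crop <- function(d) {
      nz <- dim(d)[3]
      keep <- floor(nz * (1 - mag$fraction))
      if (keep < nz) d[, , (keep + 1):nz] <- 0
      d
    }
    for (m in names(study$anatomical)) rewrite(study$anatomical[[m]], crop)
    rewrite(study$annotations[["brain_mask"]], crop, datatype = "uint8")
  } else if (mode == "corrupt_seg") {
    brain <- read_label_map(study$annotations[["brain_mask"]])$grid$data != 0
    rewrite(study$annotations[["tumor_seg"]], function(d) {
      s <- shift3(d, mag$shift_vox)
      grown <- dilate3(s != 0, mag$dilate_vox)
      s[grown & s == 0] <- 3
      s[!brain] <- 0     # a plausible failed segmentation stays in-brain
      s
    }, datatype = "uint8")
  } else if (mode == "missing_file") {
    file.remove(study$anatomical[[mag$modality]])
    # path stays in the record: the file is expected but absent
  }

  tf <- study$extras$truth_json
  if (!is.null(tf) && file.exists(tf)) {
    truth <- jsonlite::read_json(tf)
    truth$failure_mode <- mode
    truth$failure_params <- mag
    jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  }
  study
}

#' Generate a synthetic review cohort
#'
#' Writes `n` phantom studies under `dir` (one subdirectory each); each
#' study is independently clean or degraded by exactly one failure mode
#' drawn with the given rates. Produces `manifest.csv` (study manifest with
#' reference tumor volumes = true volume + Gaussian error) and `truth.csv`
#' (per-study injected mode and true volumes). Tumor size and position vary
#' across studies; every draw is fixed by `seed`.
#'
#' @param n number of studies.
#' @param mode_rates named probabilities over [FAILURE_MODES]; must sum to
#'   at most 1 (remainder = clean).
#' @param dir cohort output directory.
#' @param seed master seed.
#' @param shape phantom grid dimensions.
#' @param ref_noise_sd sd (cm^3) of the reference-volume measurement error.
#' @return list with `manifest` (a `study_manifest`), `truth` (data.frame
#'   `study_id`, `failure_mode`, `true_total_cm3`, `true_enhancing_cm3`),
#'   `manifest_file`, `truth_file`, `dir`.
#' @export
make_cohort <- function(n, mode_rates = c(), dir, seed = 1L,
                        shape = c(64L, 64L, 64L), ref_noise_sd = 2) {
  if (length(mode_rates)) {
    if (!all(names(mode_rates) %in% FAILURE_MODES))
      stop_parameter("unknown failure mode in mode_rates")
    if (any(mode_rates < 0) || sum(mode_rates) > 1 + 1e-12)
      stop_parameter("mode_rates must be probabilities summing to at most 1")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draws <- with_seed(seed, list(
    study_seed = sample.int(.Machine$integer.max - 1L, n),
    mode = sample(c(names(mode_rates), "clean"), n, replace = TRUE,
                  prob = c(mode_rates, 1 - sum(mode_rates))),
    scale = stats::runif(n, 0.90, 1.05),
    jitter = matrix(stats::runif(3 * n, -3, 5), ncol = 3),
    ref_err_total = stats::rnorm(n, 0, ref_noise_sd),
    ref_err_enh = stats::rnorm(n, 0, ref_noise_sd)))

  man_rows <- list(); truth_rows <- list()
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    base <- phantom_params(shape = shape)
    p <- phantom_params(shape = shape,
                        tumor_center_mm = base$tumor_center_mm + draws$jitter[i, ],
                        tumor_radii_mm = base$tumor_radii_mm * draws$scale[i],
                        seed = draws$study_seed[i])
    rec <- make_phantom_study(p, file.path(dir, id), study_id = id)
    if (draws$mode[i] != "clean")
      rec <- inject_failure(rec, draws$mode[i], seed = draws$study_seed[i])
    truth <- jsonlite::read_json(rec$extras$truth_json)
    rel <- function(path) {
      if (is.null(path) || is.na(path)) return(NA_character_)
      file.path(id, basename(path))
    }
    man_rows[[i]] <- data.frame(
      study_id = id,
      path_T1 = rel(rec$anatomical["T1"][[1]]),
      path_T1C = rel(rec$anatomical["T1C"][[1]]),
      path_T2 = rel(rec$anatomical["T2"][[1]]),
      path_FLAIR = rel(rec$anatomical["FLAIR"][[1]]),
      path_brain_mask = rel(rec$annotations["brain_mask"][[1]]),
      path_tumor_seg = rel(rec$annotations["tumor_seg"][[1]]),
      path_csf_roi = rel(rec$annotations["csf_roi"][[1]]),
      ref_total_cm3 = truth$true_total_cm3 + draws$ref_err_total[i],
      ref_enhancing_cm3 = truth$true_enhancing_cm3 + draws$ref_err_enh[i],
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      study_id = id, failure_mode = truth$failure_mode,
      true_total_cm3 = truth$true_total_cm3,
      true_enhancing_cm3 = truth$true_enhancing_cm3,
      seed = draws$study_seed[i], stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, man_rows)
  truth <- do.call(rbind, truth_rows)
  manifest_file <- file.path(dir, "manifest.csv")
  truth_file <- file.path(dir, "truth.csv")
  utils::write.csv(man, manifest_file, row.names = FALSE, na = "")
  utils::write.csv(truth, truth_file, row.names = FALSE)
  list(manifest = read_manifest(manifest_file), truth = truth,
       manifest_file = manifest_file, truth_file = truth_file, dir = dir)
}

#' Oracle review of a synthetic cohort
#'
#' Converts the generator's truth table into the review entries a perfect
#' reviewer would record: each injected failure mode maps to exactly one
#' review category (`misregistration` -> registration fail, `bias_field` ->
#' bias-field flag, `normalization_break` -> normalization-failure flag,
#' `cropped_fov` -> image-unusable flag, `corrupt_seg` -> tumor-segmentation
#' fail, `missing_file` -> no-PNGs flag); clean studies are fully
#' acceptable.
#'
#' @param truth the `truth` data.frame from [make_cohort()].
#' @param reviewer reviewer name recorded on the entries.
#' @return a `review_log` with one entry per study.
#' @export
oracle_review <- function(truth, reviewer = "oracle") {
  entries <- lapply(seq_len(nrow(truth)), function(i) {
    mode <- truth$failure_mode[i]
    args <- list(study_id = truth$study_id[i], reviewer = reviewer,
                 timestamp = "2022-01-01T00:00:00Z")
    args <- switch(mode,
      clean = args,
      misregistration = c(args, list(q_registration = "fail")),
      bias_field = c(args, list(f_bias_field = TRUE)),
      normalization_break = c(args, list(f_normalization_failure = TRUE)),
      cropped_fov = c(args, list(f_image_unusable = TRUE)),
      corrupt_seg = c(args, list(q_tumor_seg = "fail")),
      missing_file = c(args, list(f_no_pngs = TRUE)),
      stop_parameter("unknown failure mode '%s' in truth table", mode))
    do.call(review_entry, args)
  })
  out <- do.call(rbind, entries)
  class(out) <- c("review_log", "data.frame")
  out
}
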