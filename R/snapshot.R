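#' Snapshot rendering configuration
#'
#' Controls the pre-rendered panel layout: which planes the registration
#' check uses, the robust display window, overlay opacity and palette, the
#' expected normalized-intensity range annotated on density panels, the
#' integer upscale factor of the written PNGs, and the density histogram
#' resolution.
#'
#' The fixed default palette is color-blind aware: brain mask = yellow
#' 1-pixel contour (so underlying anatomy stays visible), tumor labels =
#' red/green/blue by ascending label value, CSF ROI = cyan, overlay alpha
#' 0.4. Slices are displayed in radiological-style 2D orientation: the
#' patient's left appears on the viewer's right, anterior at the top of
#' axial slices, superior at the top of sagittal/coronal slices.
#'
#' @param registration_planes planes rendered for the per-modality
#'   brain-mask registration check.
#' @param window_pct length-2 display window percentiles (within-brain when
#'   a brain mask exists, else whole-slice).
#' @param alpha overlay opacity in `[0, 1]`.
#' @param palette named list of colors (see Details).
#' @param expected_range expected normalized-intensity interval annotated on
#'   density panels (z-scored images; default `c(-5, 5)`).
#' @param scale integer pixel upscale factor for written panels.
#' @param density_bins histogram bin count for density panels.
#' @param modalities anatomical modalities expected per study.
#' @param tumor_label_names label->role map for the tumor segmentation.
#' @return a list of class `snapshot_config`.
#' @export
snapshot_config <- function(registration_planes = c("axial", "sagittal"),
                            window_pct = c(1, 99),
                            alpha = 0.4,
                            palette = list(brain_mask = "yellow",
                                           tumor = c("red", "green3", "blue"),
                                           csf_roi = "cyan",
                                           crosshair = "red"),
                            expected_range = c(-5, 5),
                            scale = 2L,
                            density_bins = 100L,
                            modalities = c("T1", "T1C", "T2", "FLAIR"),
                            tumor_label_names = c("1" = "enhancing",
                                                  "2" = "necrosis",
                                                  "3" = "edema")) {
  stopifnot(length(window_pct) == 2, window_pct[1] < window_pct[2],
            alpha >= 0, alpha <= 1, scale >= 1)
  structure(list(registration_planes = match.arg(registration_planes,
                                                 c("axial", "sagittal", "coronal"),
                                                 several.ok = TRUE),
                 window_pct = window_pct, alpha = alpha, palette = palette,
                 expected_range = expected_range, scale = as.integer(scale),
                 density_bins = as.integer(density_bins),
                 modalities = modalities,
                 tumor_label_names = tumor_label_names),
            class = "snapshot_config")
}

plane_axis <- function(plane) {
  switch(match.arg(plane, c("axial", "sagittal", "coronal")),
         sagittal = 1L, coronal = 2L, axial = 3L)
}

#' Maximum-area slice of a segmentation
#'
#' The slice index (0-based) along the given anatomical plane with the
#' greatest count of nonzero voxels — the key slice displayed on snapshot
#' panels. Ties break to the lowest index; an empty map falls back to the
#' middle slice, `floor(dim / 2)`.
#'
#' @param m a [label_map], [voxel_grid], or 3D array; assumed in canonical
#'   RAS orientation (see [reorient_canonical()]).
#' @param plane `"axial"` (third axis), `"sagittal"` (first) or
#'   `"coronal"` (second).
#' @return integer 0-based slice index.
#' @export
max_area_slice <- function(m, plane = "axial") {
  arr <- slice_source(m)
  ax <- plane_axis(plane)
  areas <- apply(arr != 0, ax, sum)
  if (all(areas == 0)) return(as.integer(dim(arr)[ax] %/% 2L))
  as.integer(which.max(areas) - 1L)
}

slice_source <- function(m) {
  if (inherits(m, "label_map")) m$grid$data
  else if (inherits(m, "voxel_grid")) m$data
  else if (is.array(m) && length(dim(m)) == 3L) m
  else stop_format("expected a label_map, voxel_grid or 3D array")
}

# Extract a 2D slice in display orientation (radiological-style; see
# snapshot_config docs). idx0 is the 0-based slice index.
display_slice <- function(arr, plane, idx0) {
  arr <- slice_source(arr)
  ax <- plane_axis(plane)
  i <- as.integer(idx0) + 1L
  if (i < 1L || i > dim(arr)[ax])
    stop_geometry("slice index %d out of range on %s axis", idx0, plane)
  s <- switch(as.character(ax),
              "1" = arr[i, , ], "2" = arr[, i, ], "3" = arr[, , i])
  m <- t(s)
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

# Displayed (row, col) of a 0-based voxel index on a display_slice image.
display_rowcol <- function(dims, plane, ijk0) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  i <- ijk0[1]; j <- ijk0[2]; k <- ijk0[3]
  switch(as.character(plane_axis(plane)),
         "3" = c(ny - j, nx - i),
         "1" = c(nz - k, ny - j),
         "2" = c(nz - k, nx - i))
}

#' Percentile windowing for display
#'
#' Maps a 2D scalar slice to gray values in `[0, 1]`: values at or below the
#' low percentile map to 0, at or above the high percentile to 1, linear in
#' between. A constant input maps to all zeros. Percentiles may be computed
#' on a separate reference sample (e.g. within-brain voxels) via `ref`.
#'
#' @param slice2d numeric matrix.
#' @param lo_pct,hi_pct percentiles, `0 <= lo_pct < hi_pct <= 100`.
#' @param ref optional numeric vector from which the percentiles are taken
#'   (defaults to the slice itself).
#' @return numeric matrix in `[0, 1]`.
#' @export
window_for_display <- function(slice2d, lo_pct = 1, hi_pct = 99, ref = NULL) {
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100))
    stop_parameter("need 0 <= lo_pct < hi_pct <= 100")
  if (is.null(ref) || length(ref) == 0) ref <- as.vector(slice2d)
  q <- stats::quantile(ref, c(lo_pct, hi_pct) / 100, names = FALSE, na.rm = TRUE)
  if (q[2] <= q[1]) return(array(0, dim = dim(slice2d)))
  out <- (slice2d - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

col_unit <- function(color) {
  if (is.numeric(color)) return(as.numeric(color[1:3]))
  as.numeric(grDevices::col2rgb(color)) / 255
}

#' Blend colored masks over a grayscale slice
#'
#' Background pixels keep their gray value; pixels under a mask are blended
#' as `(1 - alpha) * gray + alpha * color`. Later overlays draw over earlier
#' ones where masks overlap.
#'
#' @param gray numeric matrix in `[0, 1]`.
#' @param overlays list of `list(mask = <logical matrix>, color = <color>)`.
#' @param alpha opacity in `[0, 1]`.
#' @return numeric array `nrow x ncol x 3` (RGB in `[0, 1]`).
#' @export
composite_overlay <- function(gray, overlays = list(), alpha = 0.4) {
  rgb <- array(rep(as.numeric(gray), 3), dim = c(dim(gray), 3L))
  for (ov in overlays) {
    msk <- ov$mask != 0
    if (!identical(dim(msk), dim(gray)))
      stop_geometry("overlay mask shape [%s] != image shape [%s]",
                    paste(dim(msk), collapse = ","),
                    paste(dim(gray), collapse = ","))
    if (!any(msk)) next
    cu <- col_unit(ov$color)
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      pl[msk] <- (1 - alpha) * gray[msk] + alpha * cu[ch]
      rgb[, , ch] <- pl
    }
  }
  rgb
}

# 1-pixel contour of a binary 2D mask (4-neighborhood boundary).
mask_contour <- function(mask2d) {
  m <- mask2d != 0
  if (!any(m)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  m & !interior
}

#' Maximum-intensity voxel inside an ROI
#'
#' The crosshair target: the 0-based voxel index of the maximum image
#' intensity among ROI-foreground voxels. Ties break to the
#' lexicographically smallest index; an empty ROI falls back to the image
#' center `floor(dim / 2)`.
#'
#' @param image a [voxel_grid] (or 3D array).
#' @param roi a [label_map] (or 3D array) of the same shape; nonzero =
#'   foreground.
#' @return integer length-3 vector of 0-based indices.
#' @export
crosshair_target <- function(image, roi) {
  img <- slice_source(image)
  msk <- slice_source(roi) != 0
  if (!identical(dim(img), dim(msk)))
    stop_geometry("image shape [%s] != roi shape [%s]",
                  paste(dim(img), collapse = ","), paste(dim(msk), collapse = ","))
  if (!any(msk)) return(as.integer(dim(img) %/% 2L))
  v <- img[msk]
  best <- max(v)
  cand <- which(msk & img == best)
  idx <- arrayInd(cand, dim(img))
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  as.integer(idx[1, ] - 1L)
}

# ---- raster helpers ---------------------------------------------------------

upscale_nn <- function(rgb, f) {
  if (f <= 1L) return(rgb)
  rgb[rep(seq_len(dim(rgb)[1]), each = f),
      rep(seq_len(dim(rgb)[2]), each = f), , drop = FALSE]
}

# Horizontal concatenation of RGB arrays, padded to equal height with white.
hcat_rgb <- function(panels, gap = 2L) {
  h <- max(vapply(panels, function(p) dim(p)[1], 0L))
  pad <- function(p) {
    if (dim(p)[1] == h) return(p)
    out <- array(1, dim = c(h, dim(p)[2], 3L))
    out[seq_len(dim(p)[1]), , ] <- p
    out
  }
  sep <- array(1, dim = c(h, gap, 3L))
  pieces <- list()
  for (i in seq_along(panels)) {
    pieces[[length(pieces) + 1L]] <- pad(panels[[i]])
    if (i < length(panels)) pieces[[length(pieces) + 1L]] <- sep
  }
  w <- sum(vapply(pieces, function(p) dim(p)[2], 0L))
  out <- array(0, dim = c(h, w, 3L))
  at <- 1L
  for (p in pieces) {
    out[, at:(at + dim(p)[2] - 1L), ] <- p
    at <- at + dim(p)[2]
  }
  out
}

draw_hv_line <- function(rgb, row = NULL, col = NULL, color) {
  cu <- col_unit(color)
  for (ch in 1:3) {
    if (!is.null(row) && row >= 1 && row <= dim(rgb)[1]) rgb[row, , ch] <- cu[ch]
    if (!is.null(col) && col >= 1 && col <= dim(rgb)[2]) rgb[, col, ch] <- cu[ch]
  }
  rgb
}

# Rasterize a polyline through (row, col) vertices.
draw_polyline <- function(rgb, rows, cols, color) {
  cu <- col_unit(color)
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  for (i in seq_len(length(rows) - 1L)) {
    n <- max(abs(rows[i + 1] - rows[i]), abs(cols[i + 1] - cols[i]), 1L)
    rr <- round(seq(rows[i], rows[i + 1], length.out = n + 1L))
    cc <- round(seq(cols[i], cols[i + 1], length.out = n + 1L))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    for (ch in 1:3) rgb[cbind(rr[ok], cc[ok], ch)] <- cu[ch]
  }
  rgb
}

write_panel_png <- function(rgb, file, scale = 1L) {
  png::writePNG(upscale_nn(rgb, scale), file)
  invisible(file)
}

# One displayed slice with overlays; window reference = within-brain voxels
# of the slice if a brain mask is given, else the whole slice.
render_overlay_slice <- function(image, plane, idx0, overlays3d = list(),
                                 config, brain = NULL, contour_roles = "brain_mask") {
  sl <- display_slice(image, plane, idx0)
  ref <- NULL
  if (!is.null(brain)) {
    bm <- display_slice(brain, plane, idx0) != 0
    if (any(bm)) ref <- sl[bm]
  }
  gray <- window_for_display(sl, config$window_pct[1], config$window_pct[2], ref = ref)
  ovs <- list()
  for (ov in overlays3d) {
    m2 <- display_slice(ov$mask, plane, idx0) != 0
    if (!is.null(ov$role) && ov$role %in% contour_roles) m2 <- mask_contour(m2)
    ovs[[length(ovs) + 1L]] <- list(mask = m2, color = ov$color)
  }
  composite_overlay(gray, ovs, alpha = config$alpha)
}

# Overlay descriptors (3D masks + colors) for one annotation role.
annotation_overlays <- function(role, ann, config) {
  if (role == "tumor_seg") {
    labs <- sort(as.integer(names(config$tumor_label_names)))
    cols <- rep_len(config$palette$tumor, length(labs))
    lapply(seq_along(labs), function(i)
      list(mask = ann$tumor_seg$grid$data == labs[i], color = cols[i], role = "tumor_seg"))
  } else {
    list(list(mask = ann[[role]]$grid$data != 0,
              color = config$palette[[role]], role = role))
  }
}

#' Scaled intensity density panel
#'
#' Renders per-region intensity density curves from the in-mask voxels of an
#' image, each curve rescaled to unit peak so shapes are comparable
#' (a 100-bin histogram profile; no kernel smoothing). Vertical gray lines
#' mark the expected normalized-range endpoints. Empty regions are dropped;
#' if no region has voxels the panel is skipped.
#'
#' @param image a [voxel_grid].
#' @param regions list of `list(mask = <label_map/array>, name, color)`.
#' @param file output PNG path.
#' @param config a [snapshot_config()].
#' @return list with `status` (`"rendered"` or `"skipped_missing_input"`)
#'   and `file`.
#' @export
render_density_panel <- function(image, regions, file,
                                 config = snapshot_config()) {
  img <- slice_source(image)
  vals <- lapply(regions, function(r) {
    m <- slice_source(r$mask) != 0
    if (!identical(dim(m), dim(img)))
      stop_geometry("density region '%s' shape mismatch", r$name)
    img[m]
  })
  keep <- vapply(vals, length, 0L) > 0
  if (!any(keep)) return(list(status = "skipped_missing_input", file = file))
  vals <- vals[keep]; regions <- regions[keep]
  bins <- config$density_bins
  rng <- range(c(unlist(vals), config$expected_range))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  H <- 120L; W <- 3L * bins
  rgb <- array(1, dim = c(H, W, 3L))
  bin_col <- function(x) {
    # column of the bin-center pixel for value x
    b <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), bins)
    3L * b - 1L
  }
  for (ep in config$expected_range)
    rgb <- draw_hv_line(rgb, col = bin_col(ep), color = "gray60")
  for (i in seq_along(vals)) {
    b <- pmin(pmax(findInterval(vals[[i]], breaks, rightmost.closed = TRUE), 1L), bins)
    cnt <- tabulate(b, nbins = bins)
    h <- cnt / max(cnt)                      # unit-peak scaling
    nz <- range(which(cnt > 0))              # draw over the region's support only
    span <- nz[1]:nz[2]
    rows <- round((1 - h[span]) * (H - 2L)) + 1L
    cols <- 3L * span - 1L
    rgb <- draw_polyline(rgb, rows, cols, regions[[i]]$color)
  }
  write_panel_png(rgb, file, config$scale)
  list(status = "rendered", file = file)
}

# Three-plane composite at per-plane slice indices (named list plane->idx0).
three_plane_rgb <- function(image, idxs, overlays3d, config, brain = NULL,
                            crosshair = NULL) {
  panels <- lapply(names(idxs), function(pl) {
    p <- render_overlay_slice(image, pl, idxs[[pl]], overlays3d, config, brain = brain)
    if (!is.null(crosshair)) {
      rc <- display_rowcol(dim(slice_source(image)), pl, crosshair)
      p <- draw_hv_line(p, row = rc[1], col = rc[2],
                        color = config$palette$crosshair)
    }
    p
  })
  hcat_rgb(panels)
}

#' Render all snapshot panels for one study
#'
#' Pre-renders the static review panels for a study so that browsing the
#' gallery never touches the NIfTI volumes: (a) a three-plane overlay of
#' each annotation on a reference anatomical image at the annotation's own
#' maximum-area slices; (b) per-modality registration-check views with the
#' brain mask overlaid as a contour at the *brain mask's* maximum-area
#' slices — the same slice indices on every co-registered modality, so
#' misregistration is visible; (c) a CSF-ROI confirmation view on every
#' modality at the CSF ROI's maximum-area axial slice; (d) a scaled
#' intensity-density panel per modality; (e) a three-plane crosshair view of
#' each functional map at the maximum-intensity voxel within the tumor ROI.
#'
#' Missing inputs produce panels with status `skipped_missing_input` and
#' never abort the study; unexpected per-panel errors are recorded as
#' `failed`. Panels are written as PNG named
#' `{study_id}_{kind}_{modality}_{plane}.png`, plus a JSON sidecar
#' `{study_id}_panels.json` listing every panel and its status.
#'
#' @param study a [study_record].
#' @param out_dir output directory (created if needed).
#' @param config a [snapshot_config()].
#' @return an object of class `snapshot_set`: list with `study_id` and
#'   `panels`, a data.frame with columns `kind`, `modality`, `plane`,
#'   `slice_index` (0-based; comma-separated for three-plane panels, `NA`
#'   when unrendered), `file`, `status`.
#' @export
render_study <- function(study, out_dir, config = snapshot_config()) {
  stopifnot(inherits(study, "study_record"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- study$study_id

  load_grid <- function(path) reorient_canonical(read_volume(path))
  load_map <- function(path, label_names = NULL)
    reorient_canonical(read_label_map(path, label_names))
  try_load <- function(path, loader, ...) {
    if (is.null(path) || is.na(path) || !file.exists(path)) return(NULL)
    tryCatch(loader(path, ...), error = function(e) NULL)
  }

  anat <- list()
  for (m in config$modalities)
    anat[[m]] <- try_load(study$anatomical[m][[1]], load_grid)
  anat <- Filter(Negate(is.null), anat)
  ann <- list(
    brain_mask = try_load(study$annotations["brain_mask"][[1]], load_map),
    tumor_seg = try_load(study$annotations["tumor_seg"][[1]], load_map,
                         label_names = config$tumor_label_names),
    csf_roi = try_load(study$annotations["csf_roi"][[1]], load_map))
  func <- list()
  for (fn in names(study$functional))
    func[[fn]] <- try_load(study$functional[[fn]], load_grid)

  ref_anat <- if (length(anat)) anat[[1]] else NULL
  brain <- ann$brain_mask
  planes3 <- c("axial", "sagittal", "coronal")

  rows <- list()
  add <- function(kind, modality, plane, slice_index, file, status) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, modality = modality, plane = plane,
      slice_index = slice_index, file = file, status = status,
      stringsAsFactors = FALSE)
  }
  panel_file <- function(kind, modality, plane)
    file.path(out_dir, sprintf("%s_%s_%s_%s.png", id, kind, modality, plane))

  attempt <- function(kind, modality, plane, slice_index, fun) {
    file <- panel_file(kind, modality, plane)
    st <- tryCatch({ fun(file); "rendered" },
                   error = function(e) "failed")
    add(kind, modality, plane, slice_index, file, st)
  }
  skip <- function(kind, modality, plane)
    add(kind, modality, plane, NA_character_, panel_file(kind, modality, plane),
        "skipped_missing_input")

  # (a) three-plane annotation overlays on the reference anatomical
  for (role in c("brain_mask", "tumor_seg", "csf_roi")) {
    if (is.null(ann[[role]]) || is.null(ref_anat)) { skip("annotation", role, "all"); next }
    idxs <- stats::setNames(lapply(planes3, function(p)
      max_area_slice(ann[[role]], p)), planes3)
    attempt("annotation", role, "all",
            paste(unlist(idxs), collapse = ","), function(file) {
      ovs <- annotation_overlays(role, ann, config)
      write_panel_png(three_plane_rgb(ref_anat, idxs, ovs, config, brain = brain),
                      file, config$scale)
    })
  }

  # (b) registration check: brain-mask overlay at shared slice indices
  reg_idx <- lapply(stats::setNames(nm = config$registration_planes), function(p) {
    src <- if (!is.null(brain)) brain else ref_anat
    if (is.null(src)) 0L
    else if (!is.null(brain)) max_area_slice(brain, p)
    else as.integer(dim(src$data)[plane_axis(p)] %/% 2L)
  })
  bm_ov <- if (!is.null(brain)) annotation_overlays("brain_mask", ann, config) else list()
  for (m in config$modalities) {
    for (p in config$registration_planes) {
      if (is.null(anat[[m]])) { skip("registration", m, p); next }
      attempt("registration", m, p, as.character(reg_idx[[p]]), function(file) {
        write_panel_png(render_overlay_slice(anat[[m]], p, reg_idx[[p]], bm_ov,
                                             config, brain = brain),
                        file, config$scale)
      })
    }
  }

  # (c) CSF-ROI confirmation on every modality
  csf_idx <- if (!is.null(ann$csf_roi)) max_area_slice(ann$csf_roi, "axial") else NA
  for (m in config$modalities) {
    if (is.null(anat[[m]]) || is.null(ann$csf_roi)) { skip("csf", m, "axial"); next }
    attempt("csf", m, "axial", as.character(csf_idx), function(file) {
      ovs <- annotation_overlays("csf_roi", ann, config)
      write_panel_png(render_overlay_slice(anat[[m]], "axial", csf_idx, ovs,
                                           config, brain = brain),
                      file, config$scale)
    })
  }

  # (d) density panel per modality
  dens_regions <- function() {
    out <- list()
    if (!is.null(brain))
      out[[length(out) + 1L]] <- list(mask = brain, name = "brain",
                                      color = config$palette$brain_mask)
    if (!is.null(ann$tumor_seg)) {
      labs <- sort(as.integer(names(config$tumor_label_names)))
      cols <- rep_len(config$palette$tumor, length(labs))
      for (i in seq_along(labs))
        out[[length(out) + 1L]] <- list(
          mask = ann$tumor_seg$grid$data == labs[i],
          name = config$tumor_label_names[as.character(labs[i])],
          color = cols[i])
    }
    if (!is.null(ann$csf_roi))
      out[[length(out) + 1L]] <- list(mask = ann$csf_roi, name = "csf",
                                      color = config$palette$csf_roi)
    out
  }
  for (m in config$modalities) {
    regions <- if (is.null(anat[[m]])) list() else dens_regions()
    if (length(regions) == 0) { skip("density", m, "all"); next }
    file <- panel_file("density", m, "all")
    st <- tryCatch(render_density_panel(anat[[m]], regions, file, config)$status,
                   error = function(e) "failed")
    add("density", m, "all", NA_character_, file, st)
  }

  # (e) crosshair three-plane panels for functional maps
  for (fn in names(study$functional)) {
    if (is.null(func[[fn]])) { skip("crosshair", fn, "all"); next }
    roi <- if (!is.null(ann$tumor_seg)) ann$tumor_seg
           else array(0, dim(func[[fn]]$data))
    tgt <- crosshair_target(func[[fn]], roi)
    idxs <- list(axial = tgt[3], sagittal = tgt[1], coronal = tgt[2])
    attempt("crosshair", fn, "all", paste(tgt, collapse = ","), function(file) {
      write_panel_png(three_plane_rgb(func[[fn]], idxs, list(), config,
                                      crosshair = tgt),
                      file, config$scale)
    })
  }

  panels <- do.call(rbind, rows)
  out <- structure(list(study_id = id, panels = panels), class = "snapshot_set")
  jsonlite::write_json(
    list(study_id = id,
         panels = panels[, c("kind", "modality", "plane", "slice_index",
                             "file", "status")]),
    file.path(out_dir, sprintf("%s_panels.json", id)),
    auto_unbox = TRUE, dataframe = "rows")
  out
}

#' @export
print.snapshot_set <- function(x, ...) {
  st <- table(x$panels$status)
  cat(sprintf("<snapshot_set> %s: %d panels (%s)\n", x$study_id,
              nrow(x$panels),
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  invisible(x)
}
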