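#' 3D voxel grids and label maps
#'
#' `voxel_grid()` wraps a 3D scalar array together with its 4x4 voxel-to-world
#' affine (NIfTI convention: the affine maps *0-based* voxel indices to world
#' coordinates in mm, RAS+ axes). `label_map()` wraps a `voxel_grid` whose
#' values are non-negative integer labels, plus a label->role dictionary.
#'
#' All public slice/voxel indices in this package are 0-based, matching the
#' NIfTI convention; conversion to R's 1-based subscripts happens internally.
#'
#' @param data numeric 3D array; must contain no NaN.
#' @param affine numeric 4x4 matrix; upper-left 3x3 must be invertible.
#' @param path optional source file identifier, kept for provenance.
#' @return `voxel_grid()` returns an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), diag(4))
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(data, affine, path = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_format("voxel_grid data must be a 3D array, got dims [%s]",
                paste(dim(data), collapse = ", "))
  if (any(dim(data) < 1L)) stop_format("all grid dimensions must be >= 1")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop_format("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop_format("upper-left 3x3 of affine is singular")
  if (anyNA(data) && any(is.nan(data)))
    stop_format("voxel data contains NaN; replace before constructing")
  structure(list(data = data, affine = affine, path = path),
            class = "voxel_grid")
}

#' @param grid a `voxel_grid` with non-negative integer values.
#' @param label_names named character vector mapping label value to role,
#'   e.g. `c("1" = "enhancing", "2" = "necrosis", "3" = "edema")`. Every
#'   nonzero value present in the grid must be named; 0 is background.
#' @rdname voxel_grid
#' @export
label_map <- function(grid, label_names) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- unique(as.vector(grid$data))
  vals <- vals[vals != 0]
  if (any(vals < 0) || any(vals != round(vals)))
    stop_format("label map values must be non-negative integers")
  if (length(vals) && !all(as.character(vals) %in% names(label_names)))
    stop_format("labels present but unnamed: %s",
                paste(setdiff(as.character(vals), names(label_names)),
                      collapse = ", "))
  structure(list(grid = grid, label_names = label_names),
            class = "label_map")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d, voxel %.3f mm^3%s\n",
              d[1], d[2], d[3], voxel_volume_mm3(x),
              if (is.null(x$path)) "" else paste0(", from ", x$path)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$grid$data[x$grid$data != 0]))
  cat(sprintf("<label_map> %s; labels: %s\n",
              paste(dim(x$grid$data), collapse = " x "),
              if (length(tab) == 0) "(empty)"
              else paste(sprintf("%s=%s (%d vox)", names(tab),
                                 x$label_names[names(tab)], tab),
                         collapse = ", ")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into a [voxel_grid].
#' Header scaling (scl_slope/scl_inter) is applied. NaN voxels are replaced
#' by the finite image minimum with a warning, so that degraded data can
#' still be rendered and reviewed rather than aborting a study.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param nan_replace replace NaN voxels by the finite minimum (default TRUE);
#'   if FALSE, NaN input is an error.
#' @return a [voxel_grid].
#' @seealso [read_label_map()], [write_volume()]
#' @export
read_volume <- function(path, nan_replace = TRUE) {
  if (length(path) != 1L || is.na(path) || !file.exists(path))
    stop_absent_input("input volume not found: %s", as.character(path)[1])
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format("failed to parse NIfTI '%s': %s",
                                                  path, conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  dat <- as.array(img)
  dat <- array(as.vector(dat), dim = dim(dat))   # strip RNifti attributes
  nd <- dim(dat)
  if (length(nd) == 4L && nd[4] == 1L) dim(dat) <- nd[1:3]
  if (length(dim(dat)) != 3L)
    stop_format("'%s' is not a 3D volume (dims [%s])", path,
                paste(nd, collapse = ", "))
  if (any(is.nan(dat))) {
    if (!nan_replace) stop_format("'%s' contains NaN voxels", path)
    repl <- suppressWarnings(min(dat[is.finite(dat)]))
    if (!is.finite(repl)) repl <- 0
    n <- sum(is.nan(dat))
    dat[is.nan(dat)] <- repl
    warning(sprintf("%d NaN voxel(s) in '%s' replaced by image minimum %.4g",
                    n, path, repl))
  }
  storage.mode(dat) <- "double"
  voxel_grid(dat, aff, path = path)
}

#' Read a NIfTI label map
#'
#' Reads an integer-labeled volume (brain mask, tumor segmentation, ROI).
#' Non-integer stored values are rounded to the nearest integer with a
#' warning (real-world masks sometimes store floats).
#'
#' @inheritParams read_volume
#' @param label_names named character vector mapping label to role; defaults
#'   to naming every nonzero value found "foreground" (binary-mask reading).
#' @return a [label_map].
#' @export
read_label_map <- function(path, label_names = NULL) {
  g <- read_volume(path)
  if (any(g$data != round(g$data))) {
    warning(sprintf("non-integer values in label map '%s' rounded to nearest integer", path))
    g$data <- round(g$data)
  }
  if (is.null(label_names)) {
    vals <- sort(unique(as.vector(g$data)))
    vals <- vals[vals != 0]
    label_names <- stats::setNames(rep("foreground", length(vals)),
                                   as.character(vals))
  }
  label_map(g, label_names)
}

#' Write a voxel grid to NIfTI
#'
#' @param g a [voxel_grid] or [label_map].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"double"` (default) round-trips data
#'   bit-exactly, `"float"` halves file size, `"uint8"` suits label maps.
#' @return `path`, invisibly.
#' @export
write_volume <- function(g, path, datatype = "double") {
  if (inherits(g, "label_map")) g <- g$grid
  stopifnot(inherits(g, "voxel_grid"))
  img <- RNifti::asNifti(g$data)
  # RNifti's qform<- does not refresh pixdim; set it from the affine columns.
  RNifti::pixdim(img) <- sqrt(colSums(g$affine[1:3, 1:3]^2))
  RNifti::`sform<-`(img, structure(g$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(g$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Physical voxel volume
#'
#' Absolute determinant of the upper-left 3x3 of the affine: the volume of
#' one voxel in mm^3, invariant to rotations of the grid.
#'
#' @param g a [voxel_grid] or [label_map].
#' @return scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(g) {
  if (inherits(g, "label_map")) g <- g$grid
  stopifnot(inherits(g, "voxel_grid"))
  abs(det(g$affine[1:3, 1:3]))
}

#' Labeled volume in cm^3
#'
#' Counts voxels whose value falls in `labels` and multiplies by the voxel
#' volume. Labels absent from the map simply contribute zero.
#'
#' @param m a [label_map].
#' @param labels integer vector of label values to include (nonempty).
#' @return scalar, cm^3.
#' @export
label_volume_cm3 <- function(m, labels) {
  stopifnot(inherits(m, "label_map"))
  if (length(labels) == 0) stop_parameter("labels must be nonempty")
  n <- sum(m$grid$data %in% labels)
  n * voxel_volume_mm3(m$grid) / 1000
}

#' Reorient a grid to canonical RAS
#'
#' Permutes and flips the storage axes so they run Right, Anterior, Superior
#' with positive steps, updating the affine so the world coordinate of every
#' voxel is unchanged. Anatomical planes are defined on this orientation:
#' axial = slices along the third (S) axis, sagittal = first (R),
#' coronal = second (A). Idempotent.
#'
#' @param x a [voxel_grid] or [label_map].
#' @return the reoriented object (same class).
#' @export
reorient_canonical <- function(x) UseMethod("reorient_canonical")

#' @export
reorient_canonical.label_map <- function(x) {
  x$grid <- reorient_canonical(x$grid)
  x
}

#' @export
reorient_canonical.voxel_grid <- function(x) {
  A <- x$affine
  R <- A[1:3, 1:3]
  perm <- integer(3)
  sgn <- numeric(3)
  for (j in 1:3) {
    col <- R[, j]
    nrm <- sqrt(sum(col^2))
    k <- which.max(abs(col))
    # reject oblique axes: nearest cardinal direction must be within 45 deg
    if (abs(col[k]) / nrm < cos(pi / 4) - 1e-9)
      stop_orientation("affine axis %d is more than 45 degrees from any cardinal direction", j)
    perm[j] <- k
    sgn[j] <- sign(col[k])
  }
  if (anyDuplicated(perm))
    stop_orientation("affine axes do not map to three distinct world axes")
  ord <- match(1:3, perm)        # ord[w]: storage axis feeding world axis w
  d <- aperm(x$data, ord)
  newA <- diag(4)
  tr <- A[1:3, 4]
  for (w in 1:3) {
    jold <- ord[w]
    colv <- A[1:3, jold]
    if (sgn[jold] < 0) {
      n <- dim(x$data)[jold]
      idx <- rep(list(quote(expr = )), 3)
      idx[[w]] <- seq_len(dim(d)[w])[dim(d)[w]:1]
      d <- do.call(`[`, c(list(d), idx, drop = FALSE))
      tr <- tr + colv * (n - 1)
      colv <- -colv
    }
    newA[1:3, w] <- colv
  }
  newA[1:3, 4] <- tr
  voxel_grid(d, newA, path = x$path)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param g a [voxel_grid].
#' @param ijk numeric length-3 vector or n x 3 matrix of 0-based indices.
#' @return world coordinates in mm (same shape).
#' @export
voxel_to_world <- function(g, ijk) {
  if (inherits(g, "label_map")) g <- g$grid
  m <- rbind(t(matrix(ijk, ncol = 3)), 1)
  out <- t(g$affine %*% m)[, 1:3, drop = FALSE]
  if (is.null(dim(ijk))) drop(out) else out
}
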