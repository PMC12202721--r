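#' Construct a 3D scalar volume
#'
#' The basic spatial container of the package: a 3D numeric array together
#' with its voxel spacing (mm) and a 4x4 voxel-to-world affine. Voxel indices
#' are 0-based in the affine convention (NIfTI standard, RAS+ world axes);
#' continuous index `i` refers to the centre of voxel `i`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   zero origin.
#' @param units optional unit tag (e.g. `"mM"`, `"a.u."`).
#' @param valid optional logical array of the same shape flagging voxels that
#'   carry meaningful values (used by resampling fill and aTSC thresholding).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                          units = NULL, valid = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("scalar_volume requires a 3D array, got ", length(dim(data)),
         " dimension(s)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (!is.null(valid)) {
    valid <- as.array(valid)
    stopifnot(identical(dim(valid), dim(data)))
    storage.mode(valid) <- "logical"
  }
  structure(list(data = data, spacing = spacing, affine = affine,
                 units = units, valid = valid),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              if (is.null(x$units)) "" else paste0(", units ", x$units)))
  cat(sprintf("  range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Construct a binary mask on a volume or slice grid
#'
#' @param data logical (or 0/1) array, 2D or 3D.
#' @param spacing voxel size in mm, one value per array axis.
#' @param affine optional 4x4 voxel-to-world matrix (3D masks).
#' @param label free-text role of the mask, e.g. `"parenchyma"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = rep(1, length(dim(data))),
                        affine = NULL, label = "") {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("binary_mask must be 2D or 3D")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("spacing must have one positive value per mask axis")
  structure(list(data = data, spacing = spacing, affine = affine,
                 label = label),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> '%s' %s, %d voxel(s) set\n", x$label,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

# grids agree: shape, spacing and affine (within fp tolerance)
same_grid <- function(a, b, tol = 1e-8) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    (is.null(a$affine) || is.null(b$affine) ||
       max(abs(a$affine - b$affine)) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (shape/spacing/affine differ)")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file (optionally gzip-compressed) into a
#' [scalar_volume()], taking spacing and affine from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units optional unit tag to attach.
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, but '", path, "' has ", length(d),
         " dimensions (", paste(d, collapse = "x"), ")")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  # strip the niftiImage attributes so the array is a plain R array
  arr <- array(as.vector(img), dim = d)
  scalar_volume(arr, spacing = RNifti::pixdim(img),
                affine = aff, units = units)
}

#' Write a volume to NIfTI
#'
#' @param vol a `scalar_volume` (or `binary_mask`, written as 0/1 integers).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    if (length(dim(vol$data)) != 3L)
      stop("only 3D masks can be written as NIfTI")
    dat <- array(as.integer(vol$data), dim = dim(vol$data))
    vol <- scalar_volume(dat, vol$spacing, vol$affine)
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::pixdim(img) <- vol$spacing
  if (!is.null(vol$units))
    img <- RNifti::asNifti(img, list(descrip = vol$units))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask
#'
#' @param path path to a 0/1 NIfTI volume.
#' @param label role of the mask.
#' @return A 3D `binary_mask`.
#' @export
read_mask <- function(path, label = "") {
  v <- read_volume(path)
  binary_mask(v$data != 0, v$spacing, v$affine, label = label)
}

# nearest integer with the halfway case rounded toward the lower index
round_half_down <- function(x) ceiling(x - 0.5)

#' Nearest-neighbour resampling to a new matrix size
#'
#' Resamples a volume onto a grid of `target_shape` voxels spanning the same
#' physical extent, assigning each output voxel the value of the source voxel
#' nearest in continuous index space (voxel-centre convention; halfway ties
#' round toward the lower index). Spacing and affine are rescaled so that the
#' physical geometry is preserved. No new values are invented: the output
#' value set is a subset of the input value set.
#'
#' @param vol a `scalar_volume`.
#' @param target_shape integer length-3, the output matrix size.
#' @return A `scalar_volume` on the new grid.
#' @export
resample_nearest <- function(vol, target_shape) {
  stopifnot(inherits(vol, "scalar_volume"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(is.na(target_shape)) ||
      any(target_shape < 1L))
    stop("target_shape must be 3 positive integers")
  src <- dim(vol$data)
  ratio <- src / target_shape
  # 0-based target index t maps to source index ratio*(t + 0.5) - 0.5
  idx <- lapply(1:3, function(ax) {
    t0 <- seq_len(target_shape[ax]) - 1
    s <- ratio[ax] * (t0 + 0.5) - 0.5
    pmin(pmax(round_half_down(s), 0L), src[ax] - 1L) + 1L  # back to 1-based
  })
  out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- target_shape
  scale_aff <- diag(c(ratio, 1))
  scale_aff[1:3, 4] <- (ratio - 1) / 2
  scalar_volume(out, spacing = vol$spacing * ratio,
                affine = vol$affine %*% scale_aff, units = vol$units)
}

#' Resample a volume through an affine registration transform
#'
#' Pulls a source volume onto a target grid through a world-coordinate affine
#' (source world -> target world), with nearest-neighbour lookup. Voxels whose
#' pull-back falls outside the source field of view receive `fill` and are
#' flagged in the output's `valid` array. The transform is typically a manual
#' registration exported from an external tool as a 4x4 matrix.
#'
#' @param vol source `scalar_volume`.
#' @param transform 4x4 affine mapping source world coordinates to target
#'   world coordinates.
#' @param target a `scalar_volume` supplying the output grid (its data values
#'   are ignored).
#' @param fill value assigned to out-of-field voxels (default 0).
#' @return A `scalar_volume` on the target grid, with a `valid` mask.
#' @export
apply_affine_nearest <- function(vol, transform, target, fill = 0) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(target, "scalar_volume"))
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L))) stop("transform must be 4x4")
  dt <- determinant(transform, logarithm = FALSE)
  if (abs(dt$modulus) < 1e-12) stop("transform is singular")
  tgt_dim <- dim(target$data)
  n <- prod(tgt_dim)
  g <- as.matrix(expand.grid(i = seq_len(tgt_dim[1]) - 1,
                             j = seq_len(tgt_dim[2]) - 1,
                             k = seq_len(tgt_dim[3]) - 1))
  hom <- rbind(t(g), 1)
  # target voxel -> target world -> source world -> source voxel
  m <- solve(vol$affine) %*% solve(transform) %*% target$affine
  sv <- m %*% hom
  si <- round_half_down(sv[1:3, , drop = FALSE])
  src_dim <- dim(vol$data)
  inside <- si[1, ] >= 0 & si[1, ] < src_dim[1] &
    si[2, ] >= 0 & si[2, ] < src_dim[2] &
    si[3, ] >= 0 & si[3, ] < src_dim[3]
  out <- rep(fill, n)
  if (any(inside)) {
    lin <- si[1, inside] + src_dim[1] * (si[2, inside] +
                                           src_dim[2] * si[3, inside]) + 1
    out[inside] <- vol$data[lin]
  }
  scalar_volume(array(out, tgt_dim), spacing = target$spacing,
                affine = target$affine, units = vol$units,
                valid = array(inside, tgt_dim))
}

#' Select an evaluation slice
#'
#' @param axis array axis perpendicular to the slice (1, 2 or 3).
#' @param index 1-based slice index along that axis.
#' @return An object of class `slice_selection`.
#' @export
slice_selection <- function(axis, index) {
  axis <- as.integer(axis); index <- as.integer(index)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  structure(list(axis = axis, index = index), class = "slice_selection")
}

#' Extract a 2D slice from a volume
#'
#' Used to pull the coronal evaluation plane (in this workflow, the slice
#' posterior to the renal pelvis on which all segmentation is done).
#'
#' @param vol a `scalar_volume` or 3D `binary_mask`.
#' @param sel a [slice_selection()].
#' @return A list of class `mri_slice` with fields `data` (2D), `spacing`
#'   (in-plane mm), `axis`, `index`, and `valid` when the volume carries one.
#' @export
extract_slice <- function(vol, sel) {
  stopifnot(inherits(sel, "slice_selection"))
  d <- dim(vol$data)
  if (sel$index < 1L || sel$index > d[sel$axis])
    stop("slice index ", sel$index, " out of bounds [1, ", d[sel$axis],
         "] on axis ", sel$axis)
  take <- function(arr) {
    switch(sel$axis,
           arr[sel$index, , ],
           arr[, sel$index, ],
           arr[, , sel$index])
  }
  inplane <- setdiff(1:3, sel$axis)
  structure(list(data = take(vol$data), spacing = vol$spacing[inplane],
                 axis = sel$axis, index = sel$index,
                 valid = if (!is.null(vol$valid)) take(vol$valid) else NULL),
            class = "mri_slice")
}

#' Read an affine transform from a JSON sidecar
#'
#' The file must hold a 4x4 row-major matrix under the key `"matrix"` (or be
#' a bare 4x4 array).
#'
#' @param path JSON file path.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::fromJSON(path)
  m <- if (is.list(x) && !is.null(x$matrix)) x$matrix else x
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(4L, 4L)))
    stop("affine file ", path, " does not hold a 4x4 matrix")
  if (any(!is.finite(m))) stop("non-finite entries in affine file ", path)
  m
}
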