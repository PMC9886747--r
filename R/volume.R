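#' Construct a CT volume
#'
#' A `ctha_volume` couples a 3D array of attenuation values in Hounsfield
#' units (HU) with its scanner geometry: per-axis voxel size in mm, the world
#' position of the first voxel, and an orthonormal direction matrix. World
#' coordinates follow an LPS-style convention throughout the package:
#' `world = origin + axes %*% (spacing * (index - 1))` for 1-based array
#' indices.
#'
#' @param values 3D numeric array of attenuation in HU.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, world coordinate of voxel `[1,1,1]` in mm.
#' @param axes 3x3 orthonormal direction matrix (columns are the world
#'   directions of the array axes).
#' @return A `ctha_volume` object.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   axes = diag(3)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  v <- structure(
    list(values = values, spacing = spacing, origin = origin, axes = axes),
    class = "ctha_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("voxel spacing must be strictly positive and finite", call. = FALSE)
  if (any(!is.finite(v$origin)) || any(!is.finite(v$axes)))
    stop("volume geometry must be finite", call. = FALSE)
  if (abs(abs(det(v$axes)) - 1) > 1e-6 ||
      max(abs(crossprod(v$axes) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (|det| = 1)", call. = FALSE)
  if (any(dim(v$values) < 1L))
    stop("all volume dimensions must be >= 1", call. = FALSE)
  invisible(v)
}

#' Construct a binary mask on a volume grid
#'
#' Masks share the grid of their parent volume and carry a role tag.
#'
#' @param values 3D logical (or 0/1) array.
#' @param geometry a `ctha_volume` (or another mask) providing the grid, or a
#'   list with `spacing`, `origin`, `axes`.
#' @param label role tag: `"tumor"`, `"liver"`, `"vessel"` or `"residual"`.
#' @return A `ctha_mask` object (also a `ctha_volume`).
#' @export
mask <- function(values, geometry, label = c("tumor", "liver", "vessel", "residual")) {
  label <- match.arg(label)
  if (!is.logical(values)) {
    bad <- !(values %in% c(0, 1, NA))
    if (any(bad)) stop("mask values must be 0/1 or logical", call. = FALSE)
    values <- array(values > 0, dim(values))
  }
  if (inherits(geometry, "ctha_volume") &&
      !identical(dim(values), dim(geometry$values)))
    stop("mask grid must match its parent volume", call. = FALSE)
  m <- structure(
    list(values = values, spacing = as.numeric(geometry$spacing),
         origin = as.numeric(geometry$origin),
         axes = matrix(as.numeric(geometry$axes), 3, 3), label = label),
    class = c("ctha_mask", "ctha_volume"))
  m
}

is_mask <- function(x) inherits(x, "ctha_mask")

#' @export
print.ctha_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              if (is_mask(x)) paste0("ctha_mask:", x$label) else "ctha_volume",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm", x$origin[1], x$origin[2], x$origin[3]))
  if (is_mask(x)) cat(sprintf("; %d voxels set", sum(x$values)))
  else cat(sprintf("; HU range [%.1f, %.1f]",
                   suppressWarnings(min(x$values, na.rm = TRUE)),
                   suppressWarnings(max(x$values, na.rm = TRUE))))
  cat("\n")
  invisible(x)
}

# index (1-based, N x 3) -> world mm (N x 3)
index_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  t(vol$origin + vol$axes %*% (vol$spacing * t(idx - 1)))
}

# world mm (N x 3) -> continuous 1-based index (N x 3)
world_to_index <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  t((t(vol$axes) %*% (t(pts) - vol$origin)) / vol$spacing + 1)
}

# 0-based affine (4x4) of a volume, NIfTI-style
vol_affine <- function(vol) {
  A <- diag(4)
  A[1:3, 1:3] <- vol$axes %*% diag(vol$spacing)
  A[1:3, 4] <- vol$origin
  A
}

#' Read a CT volume from disk
#'
#' Supports NIfTI-1 files (`.nii`/`.nii.gz`) and directories holding an
#' uncompressed explicit-VR little-endian DICOM series. DICOM pixel values
#' are rescaled to HU using the stored rescale slope and intercept, and the
#' slice stack is checked for uniform spacing.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"auto"` (default), `"nifti"` or `"dicom_series"`.
#' @return A [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    A <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    A <- matrix(as.numeric(A), 4, 4)
    spacing <- sqrt(colSums(A[1:3, 1:3]^2))
    axes <- sweep(A[1:3, 1:3], 2, spacing, "/")
    vals <- as.array(img)
    if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
    volume(vals, spacing = spacing, origin = A[1:3, 4], axes = axes)
  } else {
    read_dicom_series(path)
  }
}

#' Write a volume (or mask) as NIfTI-1
#'
#' Masks are written as unsigned 8-bit images with values 0/1; volumes keep
#' their numeric type. Geometry is stored in the qform/sform.
#'
#' @param vol a [volume()] or [mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  dt <- "double"
  if (is_mask(vol)) { vals <- array(as.integer(vals), dim(vals)); dt <- "uint8" }
  else if (is.integer(vals)) dt <- "int16"
  img <- RNifti::asNifti(vals)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  A <- vol_affine(vol)
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Values are interpolated at the reference voxel centers; voxels falling
#' outside the moving volume's field of view are set to `fill`
#' (default -1000 HU, air). Masks are resampled with nearest-neighbour
#' interpolation and stay binary.
#'
#' @param moving volume or mask to resample.
#' @param reference volume supplying the target grid.
#' @param interpolation `"linear"` or `"nearest"`; defaults to nearest for
#'   masks, linear otherwise.
#' @param fill out-of-field value (ignored for masks, which use `FALSE`).
#' @return A volume (or mask) on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  interpolation = NULL, fill = -1000) {
  validate_volume(moving); validate_volume(reference)
  if (is.null(interpolation))
    interpolation <- if (is_mask(moving)) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  # 0-based output index -> 0-based moving index
  M4 <- solve(vol_affine(moving)) %*% vol_affine(reference)
  M <- M4[1:3, , drop = FALSE]
  src <- moving$values
  ismask <- is_mask(moving)
  storage.mode(src) <- "double"
  out <- cpp_resample_affine(src, dim(src), dim(reference$values), M,
                             interpolation == "linear", FALSE,
                             if (ismask) 0 else fill)
  if (ismask)
    mask(array(out > 0.5, dim(out)), reference, label = moving$label)
  else
    volume(out, reference$spacing, reference$origin, reference$axes)
}

plane_axis <- function(plane) {
  switch(match.arg(plane, c("axial", "coronal", "sagittal")),
         axial = 3L, coronal = 2L, sagittal = 1L)
}

check_axis_aligned <- function(vol) {
  if (max(abs(abs(vol$axes) - diag(3))) > 1e-6)
    stop("operation requires an axis-aligned volume", call. = FALSE)
}

#' Thin-slab maximum intensity projection
#'
#' Projects the per-pixel maximum over all slices whose centers fall within a
#' closed slab `[center - t/2, center + t/2]` along the projection axis.
#' Thin slabs (5-10 mm) are the conventional rendering for identifying
#' feeding arteries on enhancement maps; the default thickness is 7 mm, the
#' midpoint of that range. A slab thinner than one voxel projects the single
#' nearest slice.
#'
#' @param vol a [volume()] (axis-aligned).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param center_mm world coordinate of the slab center along the projection
#'   axis.
#' @param thickness_mm slab thickness in mm (> 0).
#' @return A `ctha_mip` with the 2D projection and slab metadata.
#' @export
mip_slab <- function(vol, plane = "axial", center_mm, thickness_mm = 7) {
  validate_volume(vol); check_axis_aligned(vol)
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    stop("slab thickness must be > 0", call. = FALSE)
  ax <- plane_axis(plane)
  d <- dim(vol$values)
  coords <- vol$origin[ax] + vol$axes[ax, ax] * vol$spacing[ax] * (seq_len(d[ax]) - 1)
  lo <- min(coords) - vol$spacing[ax] / 2
  hi <- max(coords) + vol$spacing[ax] / 2
  if (center_mm < lo || center_mm > hi)
    stop("slab does not intersect the volume", call. = FALSE)
  sel <- which(abs(coords - center_mm) <= thickness_mm / 2)
  if (length(sel) == 0L) sel <- which.min(abs(coords - center_mm))
  sub <- switch(ax,
                vol$values[sel, , , drop = FALSE],
                vol$values[, sel, , drop = FALSE],
                vol$values[, , sel, drop = FALSE])
  img <- apply(sub, setdiff(1:3, ax), max)
  structure(list(values = img,
                 plane = match.arg(plane, c("axial", "coronal", "sagittal")),
                 slab_center_mm = center_mm, slab_thickness_mm = thickness_mm,
                 slices = sel,
                 in_plane_spacing = vol$spacing[setdiff(1:3, ax)]),
            class = "ctha_mip")
}

#' @export
print.ctha_mip <- function(x, ...) {
  cat(sprintf("<ctha_mip> %s slab, %.1f mm thick at %.1f mm (%d slices), %d x %d px\n",
              x$plane, x$slab_thickness_mm, x$slab_center_mm,
              length(x$slices), nrow(x$values), ncol(x$values)))
  invisible(x)
}
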