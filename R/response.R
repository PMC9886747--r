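# ROI handling and the relative-enhancement statistic.
#
# A planar ROI is a set of voxel-center sample points on one axial or
# coronal slice, together with an outline polygon kept for serialization and
# display. Statistics are always computed over the sample points (snapped to
# the nearest voxel of the map they are evaluated on), so transferring an
# ROI rigidly between acquisitions is exact.

new_planar_roi <- function(plane, slice_mm, points, outline, role) {
  structure(list(plane = plane, axis = plane_axis(plane),
                 slice_mm = slice_mm, points = points, outline = outline,
                 role = role),
            class = "ctha_roi")
}

#' @export
print.ctha_roi <- function(x, ...) {
  cat(sprintf("<ctha_roi> %s ROI, %s slice at %.2f mm, %d sample points, area %.1f mm^2\n",
              x$role, x$plane, x$slice_mm, nrow(x$points), roi_area(x)))
  invisible(x)
}

#' ROI area (mm^2) from its outline polygon
#' @param roi a planar ROI.
#' @export
roi_area <- function(roi) {
  v <- roi$outline
  ax <- roi$axis
  ij <- setdiff(1:3, ax)
  p <- v[, ij, drop = FALSE]
  n <- nrow(p)
  idx <- c(seq_len(n)[-1], 1L)
  abs(sum(p[, 1] * p[idx, 2] - p[idx, 1] * p[, 2])) / 2
}

#' Define the tumor ROI on the pre-treatment enhancement map
#'
#' Selects, over all axial and all coronal slices, the slice with the
#' largest in-plane tumor cross-sectional area and takes that slice's tumor
#' cross-section as the ROI. Ties between the best axial and best coronal
#' area are broken toward axial; ties between slices toward the lower slice.
#'
#' @param pre_em `ctha_em` on whose grid the mask lives.
#' @param tumor_mask a [mask()] on the same grid (nonempty).
#' @return A planar ROI with role `"tumor"`.
#' @export
define_tumor_roi <- function(pre_em, tumor_mask) {
  if (!same_geometry(pre_em, tumor_mask))
    stop("tumor mask must lie on the map grid", call. = FALSE)
  tm <- tumor_mask$values
  if (!any(tm)) stop("tumor mask is empty", call. = FALSE)
  sp <- tumor_mask$spacing
  ax_counts <- apply(tm, 3, sum)
  co_counts <- apply(tm, 2, sum)
  ax_area <- max(ax_counts) * sp[1] * sp[2]
  co_area <- max(co_counts) * sp[1] * sp[3]
  if (ax_area >= co_area) { plane <- "axial"; k <- which.max(ax_counts)
  } else { plane <- "coronal"; k <- which.max(co_counts) }
  ax <- plane_axis(plane)
  sel <- which(if (ax == 3L) tm[, , k] else tm[, k, ], arr.ind = TRUE)
  idx <- matrix(0L, nrow(sel), 3)
  idx[, setdiff(1:3, ax)] <- sel
  idx[, ax] <- k
  pts <- index_to_world(tumor_mask, idx)
  slice_mm <- pts[1, ax]
  outline <- roi_outline_from_points(pts, ax, tumor_mask$spacing)
  new_planar_roi(plane, slice_mm, pts, outline, "tumor")
}

# rectangular-union outline is overkill for display; a convex hull of the
# half-voxel-expanded points is adequate and rigid-invariant in area terms
roi_outline_from_points <- function(pts, ax, spacing) {
  ij <- setdiff(1:3, ax)
  p2 <- pts[, ij, drop = FALSE]
  h <- spacing[ij] / 2
  ex <- rbind(cbind(p2[, 1] - h[1], p2[, 2] - h[2]),
              cbind(p2[, 1] - h[1], p2[, 2] + h[2]),
              cbind(p2[, 1] + h[1], p2[, 2] - h[2]),
              cbind(p2[, 1] + h[1], p2[, 2] + h[2]))
  hull <- grDevices::chull(ex)
  out <- matrix(pts[1, ], nrow = length(hull), ncol = 3, byrow = TRUE)
  out[, ij] <- ex[hull, , drop = FALSE]
  out
}

#' Define the normal-parenchyma reference ROI
#'
#' Places a circular ROI of the requested area in the hepatic lobe
#' contralateral to the tumor, on the same plane type as the tumor ROI,
#' excluding blood vessels. Among all candidate slices the center is chosen
#' as the vessel-free parenchyma point with the largest 2D distance to
#' vessels and to the liver boundary, so the disk is guaranteed to contain
#' only vessel-free parenchyma.
#'
#' Laterality follows the LPS convention (+x is the patient's left): the
#' contralateral lobe is the liver region on the opposite side of the
#' lobe-split plane `x = lobe_split_x` from the tumor.
#'
#' @param pre_em `ctha_em` providing the grid.
#' @param liver_mask,vessel_mask [mask()]s on the map grid (`vessel_mask`
#'   may be `NULL`).
#' @param tumor_lobe `"left"` or `"right"`.
#' @param lobe_split_x world x-coordinate of the lobe-split plane, mm.
#' @param area_mm2 ROI area (default 300 mm^2).
#' @param plane plane type, normally the tumor ROI's.
#' @param vessel_margin_mm 3D safety margin around the vessel mask; keeps the
#'   disk clear of partial-volume vessel signal on neighbouring slices.
#' @return A planar ROI with role `"normal"`.
#' @export
define_normal_roi <- function(pre_em, liver_mask, tumor_lobe = c("left", "right"),
                              vessel_mask = NULL, lobe_split_x,
                              area_mm2 = 300, plane = "axial",
                              vessel_margin_mm = 2) {
  tumor_lobe <- match.arg(tumor_lobe)
  if (!same_geometry(pre_em, liver_mask))
    stop("liver mask must lie on the map grid", call. = FALSE)
  ax <- plane_axis(plane)
  if (ax == 1L) stop("normal ROI plane must be axial or coronal", call. = FALSE)
  allowed <- liver_mask$values
  if (!is.null(vessel_mask) && any(vessel_mask$values)) {
    vdil <- cpp_dilate_mm(as.vector(vessel_mask$values), dim(allowed),
                          liver_mask$spacing, vessel_margin_mm)
    allowed <- allowed & !array(vdil, dim(allowed))
  }
  # contralateral half-space (LPS: +x = left)
  d <- dim(allowed)
  xw <- liver_mask$origin[1] + liver_mask$spacing[1] * (seq_len(d[1]) - 1)
  contra <- if (tumor_lobe == "left") xw < lobe_split_x else xw > lobe_split_x
  allowed <- allowed & array(contra, d)
  radius <- sqrt(area_mm2 / pi)
  ij <- setdiff(1:3, ax)
  sp2 <- liver_mask$spacing[ij]
  px <- min(sp2)
  best <- list(dist = -Inf)
  for (k in seq_len(d[ax])) {
    sl <- if (ax == 3L) allowed[, , k] else allowed[, k, ]
    if (!any(sl)) next
    dm <- EBImage::distmap(EBImage::Image(sl * 1), metric = "euclidean") * px
    m <- max(dm)
    if (m > best$dist) {
      w <- which(dm == m, arr.ind = TRUE)[1, ]
      best <- list(dist = m, k = k, center2 = w)
    }
  }
  if (!is.finite(best$dist) || best$dist < radius)
    stop(sprintf(paste0("no vessel-free contralateral parenchyma can host a ",
                        "%.0f mm^2 ROI; reduce area_mm2"), area_mm2),
         call. = FALSE)
  k <- best$k
  # world center of the disk
  cidx <- matrix(0L, 1, 3); cidx[, ij] <- best$center2; cidx[, ax] <- k
  cw <- index_to_world(liver_mask, cidx)
  # sample points: voxel centers of the slice within the disk
  sl_dim <- d[ij]
  gi <- as.matrix(expand.grid(seq_len(sl_dim[1]), seq_len(sl_dim[2])))
  idx <- matrix(0L, nrow(gi), 3)
  idx[, ij] <- gi; idx[, ax] <- k
  pts <- index_to_world(liver_mask, idx)
  keep <- (pts[, ij[1]] - cw[ij[1]])^2 + (pts[, ij[2]] - cw[ij[2]])^2 <= radius^2
  pts <- pts[keep, , drop = FALSE]
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  outline <- matrix(cw, nrow = length(theta), ncol = 3, byrow = TRUE)
  outline[, ij[1]] <- cw[ij[1]] + radius * cos(theta)
  outline[, ij[2]] <- cw[ij[2]] + radius * sin(theta)
  new_planar_roi(plane, cw[ax], pts, outline, "normal")
}

#' Transfer a planar ROI through a rigid transform
#'
#' Maps the ROI's sample points and outline through the pre-to-post rigid
#' transform and re-snaps the slice coordinate to the nearest slice of the
#' target grid, emulating the transfer of a hand-drawn ROI to the
#' corresponding anatomical location on the post-treatment map.
#'
#' @param roi a planar ROI.
#' @param transform a `ctha_rigid` (from [align_em_pair()]).
#' @param target optional volume/map supplying the slice grid to snap to.
#' @return The transferred ROI.
#' @export
transfer_roi <- function(roi, transform, target = NULL) {
  pts <- rigid_apply(transform, roi$points)
  outline <- rigid_apply(transform, roi$outline)
  ax <- roi$axis
  slice_mm <- mean(pts[, ax])
  if (!is.null(target)) {
    d <- dim(target$values)
    coords <- target$origin[ax] + target$spacing[ax] * (seq_len(d[ax]) - 1)
    k <- which.min(abs(coords - slice_mm))
    if (abs(coords[k] - slice_mm) > target$spacing[ax])
      stop("transferred ROI falls outside the target volume", call. = FALSE)
    snapped <- coords[k]
    pts[, ax] <- snapped
    slice_mm <- snapped
  }
  new_planar_roi(roi$plane, slice_mm, pts, outline, roi$role)
}

# values of a map at the ROI sample points (nearest voxel, deduplicated);
# NA (out-of-field) voxels are dropped
roi_values <- function(em, roi) {
  ci <- world_to_index(em, roi$points)
  idx <- round(ci)
  d <- dim(em$values)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  idx <- idx[ok, , drop = FALSE]
  lin <- unique((idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1])
  v <- em$values[lin]
  v[!is.na(v)]
}

#' Tumor relative enhancement for one phase
#'
#' The relative-enhancement statistic is the ratio of the mean
#' enhancement-map value over the tumor ROI to the mean over the
#' normal-parenchyma ROI. For post-treatment maps with suspected residual
#' enhancement, `high_attenuation_mode` restricts the tumor mean to voxels
#' above `tau_hu` (default 0 delta-HU), so that subtraction voids from
#' contrast stasis — voxels near zero — do not dilute the estimate. If no
#' tumor voxel exceeds the threshold the whole ROI is used and the mode is
#' recorded as inapplicable.
#'
#' @param em a `ctha_em`.
#' @param roi_tumor,roi_normal planar ROIs on this map.
#' @param high_attenuation_mode restrict the tumor mean to voxels `> tau_hu`.
#' @param tau_hu high-attenuation cutoff in delta-HU.
#' @return A one-row tibble: `T`, `mean_tumor`, `mean_normal`,
#'   `n_voxels_tumor_used`, `high_attenuation_mode`,
#'   `high_attenuation_applied`, `tau_hu`.
#' @export
relative_enhancement <- function(em, roi_tumor, roi_normal,
                                 high_attenuation_mode = FALSE, tau_hu = 0) {
  tv <- roi_values(em, roi_tumor)
  nv <- roi_values(em, roi_normal)
  if (length(tv) == 0L || length(nv) == 0L)
    stop("ROI contains no usable voxels on this map", call. = FALSE)
  mn <- mean(nv)
  if (mn <= 0)
    stop(sprintf(paste0("normal-parenchyma mean enhancement is %.2f HU (<= 0); ",
                        "cannot normalize - check parenchymal enhancement and ",
                        "ROI placement"), mn), call. = FALSE)
  applied <- FALSE
  used <- tv
  if (high_attenuation_mode) {
    sub <- tv[tv > tau_hu]
    if (length(sub) > 0L) { used <- sub; applied <- TRUE }
  }
  tibble::tibble(T = mean(used) / mn,
                 mean_tumor = mean(used), mean_normal = mn,
                 n_voxels_tumor_used = length(used),
                 high_attenuation_mode = high_attenuation_mode,
                 high_attenuation_applied = applied,
                 tau_hu = tau_hu)
}

#' Classify treatment response from post-treatment relative enhancement
#'
#' Residual tumor enhancement is called when the post-treatment relative
#' enhancement strictly exceeds 1; a ratio of exactly 1 is non-residual.
#'
#' @param T_post_RE finite scalar.
#' @return A `ctha_response`: `call` (`"residual"`/`"non_residual"`) and the
#'   deciding value.
#' @export
classify_response <- function(T_post_RE) {
  if (!is.numeric(T_post_RE) || length(T_post_RE) != 1L || !is.finite(T_post_RE))
    stop("T_post_RE must be a finite scalar", call. = FALSE)
  structure(list(call = if (T_post_RE > 1) "residual" else "non_residual",
                 T_post_RE = T_post_RE),
            class = "ctha_response")
}

#' @export
print.ctha_response <- function(x, ...) {
  cat(sprintf("<ctha_response> %s (T_post-RE = %.3f)\n", x$call, x$T_post_RE))
  invisible(x)
}
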