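#' Compute an enhancement map by registered subtraction
#'
#' Warps the native (non-contrast) phase into the arterial phase through the
#' deformable registration field and subtracts it voxel-wise:
#' `EM = arterial - warp(native)`. The map lives on the arterial grid — the
#' geometry on which enhancement is defined — and is never smoothed or
#' clipped: negative values (subtraction voids from contrast stasis) are
#' diagnostic and must be retained. Voxels that fall outside the native
#' field of view after warping are `NA` and excluded from all downstream
#' statistics.
#'
#' @param native native-phase [volume()] (the moving image).
#' @param arterial arterial-phase [volume()] (the fixed image).
#' @param field [deformation_field()] on the arterial grid (as returned by
#'   `register_deformable(arterial, native)`).
#' @param registration_id provenance string recorded on the map.
#' @return A `ctha_em` enhancement map.
#' @export
compute_em <- function(native, arterial, field, registration_id = "unspecified") {
  validate_volume(native); validate_volume(arterial)
  if (!all(field$geometry$dim == dim(arterial$values)) ||
      max(abs(field$geometry$spacing - arterial$spacing)) > 1e-6)
    stop("deformation field must live on the arterial grid", call. = FALSE)
  warped <- warp(native, field, "linear")
  structure(list(values = arterial$values - warped$values,
                 spacing = arterial$spacing, origin = arterial$origin,
                 axes = arterial$axes,
                 phase_pair = NA_character_,
                 registration_id = registration_id,
                 smoothing_applied = FALSE),
            class = c("ctha_em", "ctha_volume"))
}

em_set_phase <- function(em, phase) { em$phase_pair <- phase; em }

#' @export
print.ctha_em <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ctha_em> %s, %d x %d x %d, delta-HU range [%.1f, %.1f], %d NA voxels\n",
              x$phase_pair, d[1], d[2], d[3],
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Co-register a pre/post enhancement-map pair
#'
#' Estimates the rigid transform between the pre- and post-treatment
#' acquisitions and resamples the post-treatment map onto the pre-treatment
#' grid for voxel-based comparison. By default the transform is estimated
#' from reference volumes (typically the native phases, which are free of
#' enhancement differences); set `on = "maps"` to register the maps
#' themselves.
#'
#' @param pre_em,post_em `ctha_em` maps.
#' @param pre_ref,post_ref reference [volume()]s for the rigid registration
#'   (required when `on = "reference"`).
#' @param on `"reference"` or `"maps"`.
#' @param exclude_mask optional mask of voxels excluded from the rigid
#'   metric (see [register_rigid()]).
#' @return `list(post_on_pre = <ctha_em on the pre grid>, transform =
#'   <ctha_rigid mapping pre-world points to post-world points>)`.
#' @export
align_em_pair <- function(pre_em, post_em, pre_ref = NULL, post_ref = NULL,
                          on = c("reference", "maps"), exclude_mask = NULL) {
  on <- match.arg(on)
  if (on == "reference") {
    if (is.null(pre_ref) || is.null(post_ref))
      stop("pre_ref/post_ref volumes are required with on = \"reference\"",
           call. = FALSE)
    transform <- register_rigid(pre_ref, post_ref, exclude_mask = exclude_mask)
  } else {
    as_vol <- function(em) {
      v <- em$values; v[is.na(v)] <- 0
      volume(v, em$spacing, em$origin, em$axes)
    }
    transform <- register_rigid(as_vol(pre_em), as_vol(post_em))
  }
  post_on_pre <- resample_em_rigid(post_em, pre_em, transform)
  list(post_on_pre = post_on_pre, transform = transform)
}

# resample a map onto `target` geometry through a pre->post rigid transform
resample_em_rigid <- function(em, target, transform) {
  Tm <- diag(4)
  Tm[1:3, 1:3] <- transform$R
  Tm[1:3, 4] <- transform$center - transform$R %*% transform$center + transform$t
  M4 <- solve(vol_affine(em)) %*% Tm %*% vol_affine(target)
  vals <- em$values
  nas <- is.na(vals)
  vals[nas] <- -1e30
  out <- cpp_resample_affine(vals, dim(vals), dim(target$values),
                             M4[1:3, , drop = FALSE], TRUE, FALSE, NA_real_)
  out[out < -1e29] <- NA_real_   # interpolation touched an out-of-field voxel
  structure(list(values = array(out, dim(target$values)),
                 spacing = target$spacing, origin = target$origin,
                 axes = target$axes,
                 phase_pair = em$phase_pair,
                 registration_id = em$registration_id,
                 smoothing_applied = FALSE),
            class = c("ctha_em", "ctha_volume"))
}

#' Render an enhancement map slice or thin-slab MIP for display
#'
#' Linear windowing of map values to `[0, 1]` gray levels, optionally in
#' inverted gray scale (low values white), as enhancement maps are usually
#' read. Rendering is strictly for visualization and QC; quantitation always
#' uses the raw map.
#'
#' @param em a `ctha_em`.
#' @param window length-2 `(lo, hi)` display window in delta-HU.
#' @param inverted render low values white.
#' @param plane,slice_mm slice to render (nearest slice to `slice_mm`).
#' @param mip if `TRUE` render a thin-slab MIP centered at `slice_mm`.
#' @param thickness_mm MIP slab thickness.
#' @return A 2D matrix of gray values in `[0, 1]`.
#' @export
render_em <- function(em, window = c(0, 100), inverted = FALSE,
                      plane = "axial", slice_mm = NULL, mip = FALSE,
                      thickness_mm = 7) {
  if (window[1] >= window[2]) stop("window must satisfy lo < hi", call. = FALSE)
  ax <- plane_axis(plane)
  d <- dim(em$values)
  if (is.null(slice_mm))
    slice_mm <- em$origin[ax] + em$spacing[ax] * (d[ax] - 1) / 2
  if (mip) {
    vol <- volume(ifelse(is.na(em$values), window[1], em$values),
                  em$spacing, em$origin, em$axes)
    img <- mip_slab(vol, plane, slice_mm, thickness_mm)$values
  } else {
    k <- round((slice_mm - em$origin[ax]) / em$spacing[ax]) + 1
    k <- min(max(k, 1), d[ax])
    img <- switch(ax, em$values[k, , ], em$values[, k, ], em$values[, , k])
    img[is.na(img)] <- window[1]
  }
  g <- (pmin(pmax(img, window[1]), window[2]) - window[1]) / diff(window)
  if (inverted) g <- 1 - g
  g
}
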