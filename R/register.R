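#' Construct a dense deformation field
#'
#' Displacements are stored in mm on the fixed-image grid: the field maps
#' each fixed-grid point `x` to the point `x + u(x)` in the moving image's
#' world space.
#'
#' @param displacements 4D array `dim x 3` of displacement vectors in mm.
#' @param geometry a [volume()] or geometry list of the fixed grid.
#' @return A `ctha_field`.
#' @export
deformation_field <- function(displacements, geometry) {
  geom <- as_geometry(geometry)
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L || !all(d[1:3] == geom$dim))
    stop("displacements must be a dim x 3 array on the fixed grid", call. = FALSE)
  if (any(!is.finite(displacements)))
    stop("deformation field must be finite everywhere", call. = FALSE)
  structure(list(displacements = displacements, geometry = geom),
            class = "ctha_field")
}

as_geometry <- function(x) {
  if (inherits(x, "ctha_volume"))
    list(dim = dim(x$values), spacing = x$spacing, origin = x$origin, axes = x$axes)
  else if (inherits(x, "ctha_field")) x$geometry
  else if (is.list(x) && all(c("dim", "spacing") %in% names(x)))
    list(dim = as.integer(x$dim), spacing = as.numeric(x$spacing),
         origin = as.numeric(x$origin %||% c(0, 0, 0)),
         axes = x$axes %||% diag(3))
  else stop("cannot interpret geometry", call. = FALSE)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- as_geometry(a); gb <- as_geometry(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$axes - gb$axes)) < tol
}

#' @export
print.ctha_field <- function(x, ...) {
  nrm <- sqrt(rowSums(matrix(x$displacements, ncol = 3)^2))
  cat(sprintf("<ctha_field> %s grid, |u| mean %.3f mm, max %.3f mm\n",
              paste(x$geometry$dim, collapse = " x "), mean(nrm), max(nrm)))
  invisible(x)
}

# Jacobian determinant of x -> x + u(x) evaluated on the grid
field_jacobian <- function(field) {
  g <- field$geometry
  u <- field$displacements
  cpp_jacobian_det(u[, , , 1] / g$spacing[1], u[, , , 2] / g$spacing[2],
                   u[, , , 3] / g$spacing[3], g$dim)
}

#' Registration settings
#'
#' Defaults for the multiresolution demons-style deformable registration:
#' three pyramid levels (downsampling 4x, 2x, 1x), Gaussian regularization of
#' both the per-iteration update ("fluid", sigma 1 voxel) and the accumulated
#' field ("elastic", sigma 2 voxels), intensities clipped to `[-100, 200]` HU
#' before the similarity metric so that vessels present only in the arterial
#' phase cannot bias the match, and a relative metric-improvement stopping
#' tolerance. Iteration counts are per level, coarse to fine.
#'
#' @param levels number of pyramid levels.
#' @param iterations integer vector (length `levels`) of maximum iterations
#'   per level, coarse to fine.
#' @param sigma_fluid,sigma_field Gaussian sigmas in voxels.
#' @param clip_hu length-2 HU clipping window applied before the metric.
#' @param tol relative metric improvement below which a level stops.
#' @param step demons force scaling.
#' @return A list of settings.
#' @export
reg_params <- function(levels = 3, iterations = c(150, 80, 40),
                       sigma_fluid = 1.0, sigma_field = 2.0,
                       clip_hu = c(-100, 200), tol = 1e-5, step = 1.0) {
  list(levels = levels,
       iterations = rep_len(iterations, levels),
       sigma_fluid = sigma_fluid, sigma_field = sigma_field,
       clip_hu = clip_hu, tol = tol, step = step)
}

check_overlap <- function(fixed, moving) {
  corners <- function(v) {
    d <- dim(v$values)
    idx <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
    index_to_world(v, idx)
  }
  cf <- corners(fixed); cm <- corners(moving)
  ok <- all(apply(cf, 2, min) <= apply(cm, 2, max) + 1e-9) &&
    all(apply(cm, 2, min) <= apply(cf, 2, max) + 1e-9)
  if (!ok) stop("volumes do not overlap in world space", call. = FALSE)
}

#' Deformable registration of two same-modality CT volumes
#'
#' Estimates a dense displacement field mapping the fixed grid into the
#' moving image with a multiresolution, intensity-difference-driven
#' (demons-style) algorithm with symmetric forces. Updates that would
#' increase the mean-squared-difference metric are rejected with step
#' halving, so the recorded metric trace is non-increasing within each
#' level. If a level cannot improve the metric at all the result is flagged
#' as non-converged but the best field found is still returned.
#'
#' @param fixed,moving [volume()]s; `moving` is resampled onto the fixed
#'   grid first when the grids differ.
#' @param params see [reg_params()].
#' @return `list(field = <ctha_field>, report = <ctha_reg_report>)`; the
#'   report holds the per-level metric traces and convergence flags.
#' @export
register_deformable <- function(fixed, moving, params = reg_params()) {
  validate_volume(fixed); validate_volume(moving)
  check_overlap(fixed, moving)
  if (!same_geometry(fixed, moving))
    moving <- resample_to_reference(moving, fixed, "linear")
  clip <- function(v) pmin(pmax(v, params$clip_hu[1]), params$clip_hu[2])
  f <- clip(as.vector(fixed$values)); m <- clip(as.vector(moving$values))
  d0 <- dim(fixed$values)
  nlev <- params$levels
  # image pyramids, fine to coarse
  pyr_f <- list(array(f, d0)); pyr_m <- list(array(m, d0))
  for (l in seq_len(nlev - 1)) {
    pyr_f[[l + 1]] <- cpp_downsample2(pyr_f[[l]], dim(pyr_f[[l]]))
    pyr_m[[l + 1]] <- cpp_downsample2(pyr_m[[l]], dim(pyr_m[[l]]))
  }
  u <- NULL
  traces <- vector("list", nlev)
  conv <- logical(nlev)
  for (l in nlev:1) {
    fl <- pyr_f[[l]]; ml <- pyr_m[[l]]
    dl <- dim(fl)
    if (!is.null(u)) {
      # upsample previous (coarser) field to this level; displacements are in
      # voxel units, so each component scales by the axis refinement factor
      dprev <- dim(u[[1]])
      s <- dprev / dl
      M <- cbind(diag(s), (s - 1) / 2)
      u <- lapply(1:3, function(cc)
        cpp_resample_affine(u[[cc]], dprev, dl, M, TRUE, TRUE, 0) *
          (dl[cc] / dprev[cc]))
    }
    res <- cpp_demons_level(fl, ml, dl, u,
                            params$iterations[nlev - l + 1],
                            params$sigma_fluid, params$sigma_field,
                            params$tol, params$step)
    u <- list(res$ux, res$uy, res$uz)
    traces[[nlev - l + 1]] <- res$trace
    conv[nlev - l + 1] <- res$converged
  }
  disp <- array(0, c(d0, 3L))
  for (c in 1:3) disp[, , , c] <- u[[c]] * fixed$spacing[c]
  field <- deformation_field(disp, fixed)
  report <- structure(list(metric_trace = traces,
                           levels = nlev,
                           converged = conv[nlev],
                           level_converged = conv,
                           mean_error_mm = NA_real_, std_error_mm = NA_real_),
                      class = "ctha_reg_report")
  list(field = field, report = report)
}

#' @export
print.ctha_reg_report <- function(x, ...) {
  cat(sprintf("<ctha_reg_report> %d levels, converged: %s\n", x$levels,
              x$converged))
  for (l in seq_along(x$metric_trace)) {
    tr <- x$metric_trace[[l]]
    cat(sprintf("  level %d: %d accepted iterations, metric %.4g -> %.4g\n",
                l, length(tr), tr[1], tr[length(tr)]))
  }
  if (is.finite(x$mean_error_mm))
    cat(sprintf("  error vs truth: %.3f +/- %.3f mm\n",
                x$mean_error_mm, x$std_error_mm))
  invisible(x)
}

#' Warp a volume or mask through a deformation field
#'
#' Samples the input at `x + u(x)` for every point `x` of the fixed grid the
#' field lives on. Masks are warped with nearest-neighbour interpolation and
#' remain binary; volumes default to linear interpolation with out-of-field
#' voxels set to `NA`.
#'
#' @param x a [volume()] or [mask()].
#' @param field a [deformation_field()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @return The warped volume/mask on the fixed grid.
#' @export
warp <- function(x, field, interpolation = NULL) {
  validate_volume(x)
  if (is.null(interpolation))
    interpolation <- if (is_mask(x)) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  g <- field$geometry
  ismask <- is_mask(x)
  vals <- x$values
  storage.mode(vals) <- "double"
  if (same_geometry(x, g) && max(abs(g$axes - diag(3))) < 1e-9) {
    u <- field$displacements
    out <- cpp_warp_same_grid(vals, g$dim,
                              u[, , , 1] / g$spacing[1],
                              u[, , , 2] / g$spacing[2],
                              u[, , , 3] / g$spacing[3],
                              interpolation == "linear", FALSE,
                              if (ismask) 0 else NA_real_)
  } else {
    gref <- volume(array(0, g$dim), g$spacing, g$origin, g$axes)
    idx <- as.matrix(expand.grid(seq_len(g$dim[1]), seq_len(g$dim[2]),
                                 seq_len(g$dim[3])))
    w <- index_to_world(gref, idx) + matrix(field$displacements, ncol = 3)
    ci <- world_to_index(x, w) - 1
    out <- cpp_sample_at(vals, dim(vals), ci, interpolation == "linear",
                         FALSE, if (ismask) 0 else NA_real_)
    out <- array(out, g$dim)
  }
  if (ismask)
    mask(array(out > 0.5, g$dim), list(values = array(0, g$dim),
                                       spacing = g$spacing, origin = g$origin,
                                       axes = g$axes), label = x$label)
  else volume(out, g$spacing, g$origin, g$axes)
}

#' Numerically invert a deformation field
#'
#' Computes the displacement field `v` of the inverse of the mapping
#' `x -> x + u(x)` by fixed-point iteration `v(x) <- -u(x + v(x))`, which
#' converges quickly for the smooth, fold-free fields this package works
#' with. The residual composition error is reported as an attribute.
#'
#' @param field a [deformation_field()].
#' @param iterations fixed-point iterations.
#' @return The inverse [deformation_field()] on the same grid, with
#'   attribute `max_residual_mm` (max |u(x + v(x)) + v(x)|).
#' @export
invert_field <- function(field, iterations = 20) {
  g <- field$geometry
  u <- field$displacements
  uv <- lapply(1:3, function(c) u[, , , c] / g$spacing[c])  # voxel units
  vv <- lapply(uv, function(a) -a)
  for (it in seq_len(iterations)) {
    uw <- lapply(uv, function(a)
      cpp_warp_same_grid(a, g$dim, vv[[1]], vv[[2]], vv[[3]], TRUE, TRUE, 0))
    vv <- lapply(uw, function(a) -a)
  }
  uw <- lapply(uv, function(a)
    cpp_warp_same_grid(a, g$dim, vv[[1]], vv[[2]], vv[[3]], TRUE, TRUE, 0))
  res <- sqrt(Reduce(`+`, lapply(1:3, function(c)
    ((uw[[c]] + vv[[c]]) * g$spacing[c])^2)))
  disp <- array(0, c(g$dim, 3L))
  for (c in 1:3) disp[, , , c] <- vv[[c]] * g$spacing[c]
  out <- deformation_field(disp, g)
  attr(out, "max_residual_mm") <- max(res)
  out
}

#' Rigid co-registration of two volumes
#'
#' Finds the rigid transform (rotation about the fixed volume's center plus
#' translation) mapping fixed-image world points to the corresponding
#' moving-image world points, by multiresolution Nelder-Mead minimization of
#' the mean-squared HU difference (after clipping).
#'
#' @param fixed,moving [volume()]s.
#' @param clip_hu HU clipping window for the metric.
#' @param maxit iterations per resolution level.
#' @param exclude_mask optional [mask()] on the fixed grid of voxels to
#'   exclude from the metric (e.g. a treated tumor whose appearance changed
#'   between the acquisitions being co-registered).
#' @return A `ctha_rigid`: rotation matrix `R`, translation `t`, center `c`;
#'   points map as `R %*% (x - c) + c + t`.
#' @export
register_rigid <- function(fixed, moving, clip_hu = c(-100, 200), maxit = 300,
                           exclude_mask = NULL) {
  validate_volume(fixed); validate_volume(moving)
  check_overlap(fixed, moving)
  clip <- function(v) pmin(pmax(v, clip_hu[1]), clip_hu[2])
  fv <- array(clip(fixed$values), dim(fixed$values))
  mv <- array(clip(moving$values), dim(moving$values))
  ev <- if (!is.null(exclude_mask)) {
    m <- exclude_mask$values
    storage.mode(m) <- "double"
    m
  } else NULL
  center <- as.vector(index_to_world(fixed, matrix((dim(fixed$values) + 1) / 2, 1)))
  Am_inv <- solve(vol_affine(moving))
  cost_at_level <- function(fl, keep, Af_l) {
    dl <- dim(fl)
    function(par) {
      Tm <- rigid_matrix(par, center)
      M4 <- Am_inv %*% Tm %*% Af_l
      w <- cpp_resample_affine(mv, dim(mv), dl, M4[1:3, , drop = FALSE],
                               TRUE, TRUE, 0)
      d2 <- (w - fl)^2
      if (is.null(keep)) mean(d2) else mean(d2[keep])
    }
  }
  par <- rep(0, 6)
  for (fac in c(4L, 2L, 2L)) {   # repeated half-resolution pass as a restart
    fl <- fv; el <- ev
    steps <- as.integer(log2(fac))
    for (s in seq_len(steps)) {
      fl <- cpp_downsample2(fl, dim(fl))
      if (!is.null(el)) el <- cpp_downsample2(el, dim(el))
    }
    keep <- if (!is.null(el)) el < 0.25 else NULL
    Af_l <- vol_affine(fixed)
    Af_l[1:3, 1:3] <- Af_l[1:3, 1:3] * fac
    Af_l[1:3, 4] <- Af_l[1:3, 4] + fixed$axes %*% (fixed$spacing * (fac - 1) / 2)
    o <- stats::optim(par, cost_at_level(fl, keep, Af_l), method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(1, 1, 1, 0.02, 0.02, 0.02),
                                     reltol = 1e-12))
    par <- o$par
  }
  structure(list(R = rigid_rotation(par[4:6]), t = par[1:3], center = center,
                 par = par),
            class = "ctha_rigid")
}

rigid_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rigid_matrix <- function(par, center) {
  R <- rigid_rotation(par[4:6])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center + par[1:3]
  M
}

#' Identity rigid transform
#' @param center rotation center (mm); cosmetic for the identity.
#' @export
rigid_identity <- function(center = c(0, 0, 0)) {
  structure(list(R = diag(3), t = c(0, 0, 0), center = center,
                 par = rep(0, 6)), class = "ctha_rigid")
}

#' Apply a rigid transform to world points
#' @param transform a `ctha_rigid`.
#' @param pts `n x 3` matrix of points in mm.
#' @return Transformed `n x 3` matrix.
#' @export
rigid_apply <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3)
  t(transform$R %*% (t(pts) - transform$center) + transform$center + transform$t)
}

#' @export
print.ctha_rigid <- function(x, ...) {
  ang <- x$par[4:6] * 180 / pi
  cat(sprintf("<ctha_rigid> t = (%.2f, %.2f, %.2f) mm, angles = (%.2f, %.2f, %.2f) deg\n",
              x$t[1], x$t[2], x$t[3], ang[1], ang[2], ang[3]))
  invisible(x)
}

#' Displacement-recovery error between two deformation fields
#'
#' Mean and standard deviation of the per-voxel Euclidean magnitude of the
#' difference between an estimated and a true displacement field, within a
#' region of interest.
#'
#' @param estimated,truth [deformation_field()]s on a common grid.
#' @param roi a [mask()] on the same grid.
#' @return `c(mean_mm, std_mm)`.
#' @export
registration_error <- function(estimated, truth, roi) {
  if (!all(estimated$geometry$dim == truth$geometry$dim))
    stop("fields must share a grid", call. = FALSE)
  sel <- as.vector(roi$values)
  if (!any(sel)) stop("ROI is empty", call. = FALSE)
  du <- matrix(estimated$displacements - truth$displacements, ncol = 3)[sel, , drop = FALSE]
  nrm <- sqrt(rowSums(du^2))
  c(mean_mm = mean(nrm), std_mm = stats::sd(nrm) * sqrt((length(nrm) - 1) / length(nrm)))
}
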