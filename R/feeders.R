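# Feeding-artery analysis on post-treatment enhancement maps.
#
# Residual-enhancement regions are 26-connected components of tumor voxels
# above a map threshold. Feeders are found by an explicit algorithmic
# surrogate for the visual thin-slab-MIP reading: a Hessian-based tubular
# vesselness filter followed by a minimal-cost path from the hepatic artery
# root to the region; the path is then compared against the pre-treatment
# vessel mask to distinguish persistent feeders from newly developed
# collaterals. All parameters of the surrogate (threshold, epsilon,
# dilation, overlap cutoff) are recorded in the outputs.

#' Detect residual-enhancement regions
#'
#' 26-connected components of tumor voxels whose post-treatment map value
#' exceeds `threshold_hu` (default 20 delta-HU, roughly the parenchymal
#' uplift). Components smaller than `min_voxels` are discarded as noise;
#' regions are returned sorted by volume, largest first.
#'
#' @param post_em post-treatment `ctha_em`.
#' @param tumor_mask [mask()] on the same grid.
#' @param threshold_hu residual threshold in delta-HU.
#' @param min_voxels minimum component size.
#' @return A list of `ctha_region` objects (possibly empty), each holding a
#'   residual [mask()], `centroid_mm`, `mean_delta_hu` and `n_voxels`.
#' @export
detect_residual_regions <- function(post_em, tumor_mask, threshold_hu = 20,
                                    min_voxels = 5) {
  if (!same_geometry(post_em, tumor_mask))
    stop("tumor mask must lie on the map grid", call. = FALSE)
  v <- post_em$values
  sel <- tumor_mask$values & !is.na(v) & v > threshold_hu
  if (!any(sel)) return(list())
  lab <- cpp_cc26(as.vector(sel), dim(v))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(keep, function(l) {
    m <- array(lab == l, dim(v))
    idx <- which(m, arr.ind = TRUE)
    ctr <- colMeans(index_to_world(tumor_mask, idx))
    structure(list(mask = mask(m, tumor_mask, "residual"),
                   centroid_mm = ctr,
                   mean_delta_hu = mean(v[m]),
                   n_voxels = sum(m),
                   threshold_hu = threshold_hu),
              class = "ctha_region")
  })
}

#' @export
print.ctha_region <- function(x, ...) {
  cat(sprintf("<ctha_region> %d voxels, mean %.1f delta-HU, centroid (%.1f, %.1f, %.1f) mm\n",
              x$n_voxels, x$mean_delta_hu,
              x$centroid_mm[1], x$centroid_mm[2], x$centroid_mm[3]))
  invisible(x)
}

#' Multiscale tubular vesselness
#'
#' Hessian-eigenvalue (Frangi-type) filter for bright tubular structures,
#' evaluated at each scale (Gaussian sigma in mm) and combined by the
#' per-voxel maximum. Scores lie in `[0, 1]`; plates and blobs are
#' suppressed.
#'
#' @param x a [volume()] or `ctha_em` (NA voxels treated as 0).
#' @param scales_mm vector of scales (all > 0).
#' @param alpha,beta,cfrac Frangi sensitivity parameters; the structureness
#'   cutoff is `cfrac` times the maximum Hessian norm at each scale.
#' @return A [volume()] of vesselness scores.
#' @export
vesselness <- function(x, scales_mm = c(1, 1.5, 2), alpha = 0.5, beta = 0.5,
                       cfrac = 0.5) {
  if (length(scales_mm) < 1L || any(scales_mm <= 0))
    stop("at least one positive scale is required", call. = FALSE)
  v <- x$values
  v[is.na(v)] <- 0
  storage.mode(v) <- "double"
  out <- array(0, dim(v))
  for (s in scales_mm)
    out <- pmax(out, cpp_frangi_scale(v, dim(v), x$spacing, s, alpha, beta, cfrac))
  volume(array(out, dim(v)), x$spacing, x$origin, x$axes)
}

#' Trace a feeding artery from the artery root to a residual region
#'
#' Minimal-cost path on the 26-connected voxel graph with per-voxel cost
#' `1 / (vesselness + epsilon)`, from the root point to the dilated residual
#' region. Returns `NULL` when the best path's minimum vesselness (outside
#' the region itself) falls below `min_vesselness` — i.e., no artery leads
#' to the region.
#'
#' @param post_em post-treatment `ctha_em` (for path intensity statistics).
#' @param region a `ctha_region`.
#' @param root_mm world coordinates of the hepatic artery root.
#' @param vesselness_map [vesselness()] output on the same grid.
#' @param epsilon cost regularizer.
#' @param min_vesselness no-artery cutoff.
#' @param target_dilation_mm dilation of the region mask that terminates the
#'   search.
#' @return A `ctha_trace` (path in mm, mean intensity, minimum vesselness,
#'   length) or `NULL`.
#' @export
trace_feeder <- function(post_em, region, root_mm, vesselness_map,
                         epsilon = 1e-3, min_vesselness = 0.1,
                         target_dilation_mm = NULL) {
  d <- dim(post_em$values)
  ci <- round(world_to_index(post_em, matrix(root_mm, 1)))
  if (any(ci < 1) || any(ci > d))
    stop("root point lies outside the volume", call. = FALSE)
  if (is.null(target_dilation_mm))
    target_dilation_mm <- 1.5 * max(post_em$spacing)
  target <- cpp_dilate_mm(as.vector(region$mask$values), d, post_em$spacing,
                          target_dilation_mm)
  vv <- as.vector(vesselness_map$values)
  # tracing uses relative vesselness (normalized to unit maximum), making the
  # path and the no-artery decision invariant to uniform rescaling of the map
  if (max(vv) > 0) vv <- vv / max(vv)
  cost <- 1 / (vv + epsilon)
  start <- as.integer((ci[1] - 1) + d[1] * ((ci[2] - 1) + d[2] * (ci[3] - 1)))
  res <- cpp_dijkstra(cost, d, post_em$spacing, start, target)
  if (!isTRUE(res$reached)) return(NULL)
  idx0 <- res$path
  lin <- idx0[, 1] + d[1] * (idx0[, 2] + d[2] * idx0[, 3]) + 1
  inside <- target[lin]
  vpath <- vv[lin]
  v_en_route <- vpath[!inside]
  if (length(v_en_route) == 0L || min(v_en_route) < min_vesselness)
    return(NULL)
  ref <- volume(array(0, d), post_em$spacing, post_em$origin, post_em$axes)
  pts <- index_to_world(ref, idx0 + 1)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  emv <- post_em$values[lin]
  structure(list(path = pts, path_lin = lin,
                 mean_intensity = mean(emv, na.rm = TRUE),
                 vesselness_min = min(v_en_route),
                 length_mm = sum(seg),
                 epsilon = epsilon, min_vesselness = min_vesselness),
            class = "ctha_trace")
}

#' @export
print.ctha_trace <- function(x, ...) {
  cat(sprintf("<ctha_trace> %d points, %.1f mm, mean %.1f delta-HU, min vesselness %.3f\n",
              nrow(x$path), x$length_mm, x$mean_intensity, x$vesselness_min))
  invisible(x)
}

#' Classify a traced feeder as persistent or newly developed
#'
#' A feeder is a persistent (previously treated) artery when at least
#' `overlap_threshold` of its path points lie inside the pre-treatment
#' vessel mask dilated by `dilation_mm`; otherwise it is a new collateral
#' that developed after embolization. The trace must already be expressed in
#' the pre-treatment (common) frame.
#'
#' @param trace a `ctha_trace`.
#' @param pre_vessel_mask pre-treatment vessel [mask()].
#' @param dilation_mm mask dilation in mm.
#' @param overlap_threshold persistent-feeder cutoff on the overlap
#'   fraction (`>=` rule).
#' @return A one-row tibble: `status`, `overlap_fraction`, `path_length_mm`
#'   and the parameters used.
#' @export
classify_feeder <- function(trace, pre_vessel_mask, dilation_mm = 1.2,
                            overlap_threshold = 0.5) {
  if (is.null(trace) || nrow(trace$path) == 0L)
    stop("empty trace", call. = FALSE)
  d <- dim(pre_vessel_mask$values)
  dil <- cpp_dilate_mm(as.vector(pre_vessel_mask$values), d,
                       pre_vessel_mask$spacing, dilation_mm)
  ci <- round(world_to_index(pre_vessel_mask, trace$path))
  ok <- ci[, 1] >= 1 & ci[, 1] <= d[1] & ci[, 2] >= 1 & ci[, 2] <= d[2] &
    ci[, 3] >= 1 & ci[, 3] <= d[3]
  inmask <- logical(nrow(ci))
  lin <- (ci[ok, 3] - 1) * d[1] * d[2] + (ci[ok, 2] - 1) * d[1] + ci[ok, 1]
  inmask[ok] <- dil[lin]
  frac <- mean(inmask)
  tibble::tibble(
    status = if (frac >= overlap_threshold) "persistent_feeder" else "new_collateral",
    overlap_fraction = frac,
    path_length_mm = trace$length_mm,
    dilation_mm = dilation_mm,
    overlap_threshold = overlap_threshold)
}
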