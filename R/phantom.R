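#' Specify a synthetic dual-phase CTHA case
#'
#' The phantom emulates intraprocedural CT hepatic arteriography of a liver
#' bearing one hypervascular tumor, acquired as a native (non-contrast) and
#' an arterial phase both before and after embolization. The construction
#' mirrors the physics the subtraction method exploits:
#'
#' * the arterial phase adds a parenchymal uplift over the liver, a tumor
#'   uplift over the (still viable) tumor tissue, and bright tubular vessels;
#' * after treatment, only a residual fraction `residual_fraction` of the
#'   tumor keeps its arterial uplift — placed as a spherical cap at the
#'   lateral tumor margin, where under-treated tumor is typically found;
#' * the treated (non-residual) tumor retains contrast ("stasis"): a large
#'   `stasis_delta` is added to the post-treatment native AND arterial phases
#'   equally, so it cancels under subtraction and appears as a void;
#' * the native phase of each pair is deformed by a smooth random field
#'   emulating inter-acquisition motion, and independent Gaussian noise is
#'   added to every phase.
#'
#' All HU defaults are plausible values for contrast-enhanced liver CT, not
#' estimates of any particular patient cohort.
#'
#' @param grid_shape voxels per axis (default 96^3).
#' @param spacing_mm isotropic voxel size in mm (default 0.6, quasi-isotropic
#'   high-resolution reconstruction).
#' @param liver_center_mm,liver_semiaxes_mm liver ellipsoid, mm.
#' @param tumor_center_mm,tumor_radius_mm tumor sphere, mm.
#' @param hu_background,hu_liver_native,hu_tumor_native native-phase HU.
#' @param parenchymal_enhancement arterial uplift of liver parenchyma, HU.
#' @param tumor_enhancement arterial uplift of viable tumor, HU.
#' @param residual_fraction fraction of tumor volume still enhancing after
#'   treatment, in `[0, 1]`.
#' @param stasis_delta HU added to the treated tumor subregion in both
#'   post-treatment phases (retained contrast).
#' @param vessel_tree list of vessels, each
#'   `list(points = <n x 3 matrix, mm>, radius_mm, phase)` with phase one of
#'   `"pre_only"`, `"post_only"`, `"both"`. `NULL` uses a default tree with
#'   one feeding artery reaching the residual cap and one uninvolved vessel
#'   in the contralateral lobe.
#' @param deformation_amplitude_mm maximum native-phase displacement, mm.
#' @param noise_sigma_hu additive Gaussian noise standard deviation, HU.
#' @param seed integer seed; everything derived from it is deterministic.
#' @return A `ctha_phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing_mm = 0.6,
                         liver_center_mm = c(28.5, 28.5, 28.5),
                         liver_semiaxes_mm = c(25, 20, 22),
                         tumor_center_mm = c(40.5, 28.5, 28.5),
                         tumor_radius_mm = 9,
                         hu_background = 20,
                         hu_liver_native = 55,
                         hu_tumor_native = 45,
                         parenchymal_enhancement = 20,
                         tumor_enhancement = 60,
                         residual_fraction = 0.5,
                         stasis_delta = 150,
                         vessel_tree = NULL,
                         deformation_amplitude_mm = 3,
                         noise_sigma_hu = 8,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
               liver_center_mm = liver_center_mm,
               liver_semiaxes_mm = liver_semiaxes_mm,
               tumor_center_mm = tumor_center_mm,
               tumor_radius_mm = tumor_radius_mm,
               hu_background = hu_background,
               hu_liver_native = hu_liver_native,
               hu_tumor_native = hu_tumor_native,
               parenchymal_enhancement = parenchymal_enhancement,
               tumor_enhancement = tumor_enhancement,
               residual_fraction = residual_fraction,
               stasis_delta = stasis_delta,
               vessel_tree = vessel_tree %||% default_vessel_tree(),
               deformation_amplitude_mm = deformation_amplitude_mm,
               noise_sigma_hu = noise_sigma_hu,
               seed = as.integer(seed))
  class(spec) <- "ctha_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default vessels: a feeding artery descending onto the residual cap from
# above the tumor equator (so the tumor's maximal cross-section stays free of
# vessel signal), plus an uninvolved straight vessel in the contralateral
# lobe used to exercise the vessel-exclusion rule of the normal ROI.
default_vessel_tree <- function() {
  list(
    list(points = rbind(c(40.5, 11, 40), c(44, 18, 38),
                        c(45, 24, 36), c(45, 28.5, 34)),
         radius_mm = 1.2, phase = "both", role = "feeder"),
    list(points = rbind(c(14, 18, 28.5), c(14, 39, 28.5)),
         radius_mm = 1.2, phase = "both", role = "bystander"))
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (residual_fraction < 0 || residual_fraction > 1)
      stop("residual_fraction must lie in [0, 1]", call. = FALSE)
    if (deformation_amplitude_mm < 0) stop("deformation amplitude must be >= 0", call. = FALSE)
    if (noise_sigma_hu < 0) stop("noise sigma must be >= 0", call. = FALSE)
    # tumor sphere contained in liver ellipsoid: max of the ellipsoid norm
    # over the sphere is bounded by |(c_t - c_l)/a| + r / min(a)
    rel <- sqrt(sum(((tumor_center_mm - liver_center_mm) / liver_semiaxes_mm)^2))
    if (rel + tumor_radius_mm / min(liver_semiaxes_mm) > 1)
      stop("tumor sphere must be contained in the liver ellipsoid", call. = FALSE)
  })
  invisible(spec)
}

phantom_geometry <- function(spec) {
  list(dim = spec$grid_shape, spacing = spec$spacing_mm,
       origin = c(0, 0, 0), axes = diag(3))
}

# voxel-center world coordinate arrays (as vectors aligned with the array)
grid_coords <- function(geom) {
  d <- geom$dim; sp <- geom$spacing
  list(x = rep(sp[1] * (seq_len(d[1]) - 1), times = d[2] * d[3]) + geom$origin[1],
       y = rep(rep(sp[2] * (seq_len(d[2]) - 1), each = d[1]), times = d[3]) + geom$origin[2],
       z = rep(sp[3] * (seq_len(d[3]) - 1), each = d[1] * d[2]) + geom$origin[3])
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483562) + 1L
}

#' Simulate a smooth inter-acquisition deformation field
#'
#' Superposes a small number of broad Gaussian displacement bumps (bandwidth
#' drawn from 20-30 mm) and rescales so the maximum displacement magnitude
#' equals `amplitude_mm`. The resulting map `x -> x + u(x)` is checked to be
#' fold-free (everywhere-positive Jacobian determinant).
#'
#' @param geometry a [volume()] or a geometry list (`dim`, `spacing`,
#'   `origin`, `axes`) on which to evaluate the field.
#' @param amplitude_mm maximum displacement magnitude, mm (>= 0).
#' @param seed integer seed.
#' @param n_bumps number of Gaussian bumps.
#' @param bandwidth_mm range the bump standard deviations are drawn from.
#' @return A [deformation_field()] on the given grid.
#' @export
simulate_deformation <- function(geometry, amplitude_mm, seed,
                                 n_bumps = 6, bandwidth_mm = c(20, 30)) {
  if (amplitude_mm < 0) stop("amplitude_mm must be >= 0", call. = FALSE)
  geom <- as_geometry(geometry)
  d <- geom$dim
  u <- array(0, c(d, 3L))
  if (amplitude_mm > 0) {
    rs <- local_rng(seed)
    on.exit(restore_rng(rs), add = TRUE)
    extent <- geom$spacing * (d - 1)
    cg <- grid_coords(geom)
    acc <- matrix(0, prod(d), 3)
    for (b in seq_len(n_bumps)) {
      ctr <- geom$origin + stats::runif(3, 0.2, 0.8) * extent
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      sig <- stats::runif(1, bandwidth_mm[1], bandwidth_mm[2])
      amp <- stats::runif(1, 0.3, 1)
      w <- exp(-0.5 * ((cg$x - ctr[1])^2 + (cg$y - ctr[2])^2 +
                         (cg$z - ctr[3])^2) / sig^2)
      acc <- acc + outer(w, amp * dir)
    }
    nrm <- sqrt(rowSums(acc^2))
    mx <- max(nrm)
    if (mx > 0) acc <- acc * (amplitude_mm / mx)
    u <- array(acc, c(d, 3L))
  }
  fld <- deformation_field(u, geom)
  if (amplitude_mm > 0) {
    jd <- field_jacobian(fld)
    if (min(jd) <= 0)
      stop("deformation amplitude too large: the map folds (non-positive Jacobian)",
           call. = FALSE)
  }
  fld
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate one synthetic dual-phase CTHA case
#'
#' Produces the four acquisitions (pre/post x native/arterial) plus complete
#' ground truth. In each pair the native phase is the deformed acquisition
#' while the arterial phase — on whose grid the enhancement map is defined —
#' is at rest, so the truth deformation field is directly comparable to the
#' field estimated with the arterial phase as the fixed image.
#'
#' With zero noise and zero deformation the generated volumes are exact
#' piecewise-constant scenes, and the analytic relative-enhancement values
#' recorded in the truth are reproduced exactly by the processing chain.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `pre_native`, `pre_arterial`, `post_native`,
#'   `post_arterial` (all [volume()]s) and `truth` (masks, deformation
#'   fields, vessel centerlines, analytic expected statistics, seeds).
#' @export
generate_case <- function(spec) {
  validate_phantom_spec(spec)
  geom <- phantom_geometry(spec)
  d <- geom$dim
  ref <- volume(array(0, d), geom$spacing, geom$origin, geom$axes)
  cg <- grid_coords(geom)

  liver <- ((cg$x - spec$liver_center_mm[1]) / spec$liver_semiaxes_mm[1])^2 +
    ((cg$y - spec$liver_center_mm[2]) / spec$liver_semiaxes_mm[2])^2 +
    ((cg$z - spec$liver_center_mm[3]) / spec$liver_semiaxes_mm[3])^2 <= 1
  r2 <- (cg$x - spec$tumor_center_mm[1])^2 + (cg$y - spec$tumor_center_mm[2])^2 +
    (cg$z - spec$tumor_center_mm[3])^2
  tumor <- r2 <= spec$tumor_radius_mm^2

  f <- spec$residual_fraction
  # residual region: spherical cap at the lateral (+x) tumor margin cut by a
  # plane x > x_cut whose cap volume fraction equals residual_fraction
  if (f <= 0) {
    residual <- rep(FALSE, prod(d))
  } else if (f >= 1) {
    residual <- tumor
  } else {
    r <- spec$tumor_radius_mm
    cutfun <- function(dd) (r - dd)^2 * (2 * r + dd) / (4 * r^3) - f
    dcut <- stats::uniroot(cutfun, c(-r, r), tol = 1e-10)$root
    residual <- tumor & (cg$x > spec$tumor_center_mm[1] + dcut)
  }
  stasis <- tumor & !residual

  # vessel intensity fields (max-composited Gaussian-profile tubes)
  vf_pre <- array(0, d); vf_post <- array(0, d)
  vm_pre <- rep(FALSE, prod(d)); vm_post <- rep(FALSE, prod(d))
  for (vs in spec$vessel_tree) {
    tube <- array(0, d)
    pts <- world_to_index(ref, vs$points) - 1  # 0-based voxel coords
    for (s in seq_len(nrow(pts) - 1))
      tube <- cpp_add_tube(tube, d, geom$spacing, pts[s, ], pts[s + 1, ],
                           vs$radius_mm / 2, 250)
    tm <- as.vector(tube) >= 250 * exp(-2)   # within one radius of centerline
    if (vs$phase %in% c("pre_only", "both")) {
      vf_pre <- pmax(vf_pre, tube); vm_pre <- vm_pre | tm
    }
    # a successfully embolized feeder no longer opacifies after treatment:
    # vessels tagged role = "feeder" appear post-treatment only while part of
    # the tumor still enhances
    feeder_occluded <- identical(vs$role, "feeder") && f <= 0
    if (vs$phase %in% c("post_only", "both") && !feeder_occluded) {
      vf_post <- pmax(vf_post, tube); vm_post <- vm_post | tm
    }
  }

  base <- rep(spec$hu_background, prod(d))
  base[liver] <- spec$hu_liver_native
  base[tumor] <- spec$hu_tumor_native

  scene_nat_pre <- base
  scene_art_pre <- base +
    spec$parenchymal_enhancement * (liver & !tumor) +
    spec$tumor_enhancement * tumor + as.vector(vf_pre)

  scene_nat_post <- base + spec$stasis_delta * stasis
  scene_art_post <- scene_nat_post +
    spec$parenchymal_enhancement * (liver & !tumor) +
    spec$tumor_enhancement * residual + as.vector(vf_post)

  # warp_pre/post deform the native scenes; the truth fields recorded for
  # registration comparison are their inverses (the native -> arterial
  # pullback a registration with the arterial phase fixed estimates)
  warp_pre <- simulate_deformation(geom, spec$deformation_amplitude_mm,
                                   derive_seed(spec$seed, 1))
  warp_post <- simulate_deformation(geom, spec$deformation_amplitude_mm,
                                    derive_seed(spec$seed, 2))
  def_pre <- if (spec$deformation_amplitude_mm > 0) invert_field(warp_pre) else warp_pre
  def_post <- if (spec$deformation_amplitude_mm > 0) invert_field(warp_post) else warp_post

  deform <- function(scene, fld) {
    u <- fld$displacements
    cpp_warp_same_grid(array(scene, d), d,
                       u[, , , 1] / geom$spacing[1],
                       u[, , , 2] / geom$spacing[2],
                       u[, , , 3] / geom$spacing[3],
                       TRUE, TRUE, 0)
  }
  noisy <- function(vals, k) {
    if (spec$noise_sigma_hu > 0) {
      rs <- local_rng(derive_seed(spec$seed, 10 + k))
      on.exit(restore_rng(rs), add = TRUE)
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sigma_hu)
    }
    volume(array(vals, d), geom$spacing, geom$origin, geom$axes)
  }

  pre_native <- noisy(deform(scene_nat_pre, warp_pre), 1)
  pre_arterial <- noisy(array(scene_art_pre, d), 2)
  post_native <- noisy(deform(scene_nat_post, warp_post), 3)
  post_arterial <- noisy(array(scene_art_post, d), 4)

  tumor_mask <- mask(array(tumor, d), ref, "tumor")
  residual_mask <- mask(array(residual, d), ref, "residual")
  liver_mask <- mask(array(liver, d), ref, "liver")

  expected <- analytic_expectations(spec, tumor_mask, residual_mask)

  feeder <- Find(function(v) identical(v$role, "feeder"), spec$vessel_tree)
  truth <- list(
    tumor_mask = tumor_mask,
    residual_mask = residual_mask,
    liver_mask = liver_mask,
    vessel_mask_pre = mask(array(vm_pre, d), ref, "vessel"),
    vessel_mask_post = mask(array(vm_post, d), ref, "vessel"),
    vessel_centerlines = spec$vessel_tree,
    new_collateral_present = any(vapply(spec$vessel_tree, function(v)
      v$phase == "post_only", TRUE)),
    deformation_pre = def_pre,
    deformation_post = def_post,
    expected_T_pre = expected$T_pre,
    expected_T_post = expected$T_post,
    expected_T_post_whole = expected$T_post_whole,
    residual_truth = f > 0,
    residual_fraction = f,
    lobe_split_x = spec$liver_center_mm[1],
    tumor_lobe = if (spec$tumor_center_mm[1] > spec$liver_center_mm[1])
      "left" else "right",
    root_mm = if (!is.null(feeder)) feeder$points[1, ] else NULL,
    seed = spec$seed)
  list(pre_native = pre_native, pre_arterial = pre_arterial,
       post_native = post_native, post_arterial = post_arterial,
       truth = truth)
}

# Analytic relative-enhancement values implied by the construction, computed
# from the voxelized masks with the same slice-selection rule the analysis
# uses (maximal in-plane cross-section, axial preferred on ties).
analytic_expectations <- function(spec, tumor_mask, residual_mask) {
  tm <- tumor_mask$values; rm_ <- residual_mask$values
  sp <- spec$spacing_mm
  ax_counts <- apply(tm, 3, sum); co_counts <- apply(tm, 2, sum)
  ax_area <- max(ax_counts) * sp[1] * sp[2]
  co_area <- max(co_counts) * sp[1] * sp[3]
  if (ax_area >= co_area) {
    k <- which.max(ax_counts)
    n_tum <- ax_counts[k]; n_res <- sum(rm_[, , k])
  } else {
    j <- which.max(co_counts)
    n_tum <- co_counts[j]; n_res <- sum(rm_[, j, ])
  }
  ratio <- spec$tumor_enhancement / spec$parenchymal_enhancement
  list(T_pre = ratio,
       T_post = if (spec$residual_fraction > 0) ratio else 0,
       T_post_whole = (n_res / n_tum) * ratio)
}

#' Generate a reproducible phantom cohort
#'
#' Draws `n_cases` case specifications from `base_spec`, assigning exactly
#' `round(n_cases * residual_prevalence)` of them a residual fraction drawn
#' uniformly from `residual_range` and the remainder a residual fraction of
#' zero. Per-case seeds are derived deterministically from the cohort seed,
#' so regenerating with the same arguments reproduces labels and volumes
#' bit-identically.
#'
#' @param n_cases number of cases (>= 1).
#' @param residual_prevalence proportion of residual-truth cases in `[0, 1]`.
#' @param base_spec a [phantom_spec()] providing everything but
#'   `residual_fraction` and `seed`.
#' @param seed cohort seed.
#' @param residual_range range residual fractions are drawn from.
#' @return A tibble with columns `case_id`, `seed`, `residual_fraction`,
#'   `label` (`"non_complete_response"` / `"complete_response"`) and a
#'   list-column `spec` of per-case [phantom_spec()]s.
#' @export
generate_cohort <- function(n_cases, residual_prevalence, base_spec = phantom_spec(),
                            seed = 1L, residual_range = c(0.2, 0.8)) {
  stopifnot(n_cases >= 1, residual_prevalence >= 0, residual_prevalence <= 1)
  n_res <- floor(n_cases * residual_prevalence + 0.5)
  rs <- local_rng(derive_seed(seed, 0))
  on.exit(restore_rng(rs), add = TRUE)
  which_res <- sort(sample.int(n_cases, n_res))
  fracs <- stats::runif(n_cases, residual_range[1], residual_range[2])
  specs <- vector("list", n_cases)
  frac_out <- numeric(n_cases)
  for (i in seq_len(n_cases)) {
    fi <- if (i %in% which_res) fracs[i] else 0
    frac_out[i] <- fi
    sp <- base_spec
    sp$residual_fraction <- fi
    sp$seed <- derive_seed(seed, 100 + i)
    class(sp) <- "ctha_phantom_spec"
    specs[[i]] <- sp
  }
  tibble::tibble(
    case_id = sprintf("case%03d", seq_len(n_cases)),
    seed = vapply(specs, function(s) s$seed, 1L),
    residual_fraction = frac_out,
    label = ifelse(frac_out > 0, "non_complete_response", "complete_response"),
    spec = specs)
}
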