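#' Pipeline configuration
#'
#' Collects every tunable threshold of the processing chain with its
#' default. The effective configuration is embedded verbatim in every
#' report, so each number the method leaves open (high-attenuation cutoff,
#' residual threshold, feeder-overlap rule, ...) is auditable per run.
#'
#' @param tau_hu high-attenuation cutoff for the post-treatment tumor mean
#'   (delta-HU).
#' @param residual_threshold_hu map threshold defining residual regions.
#' @param normal_roi_area_mm2 area of the normal-parenchyma ROI.
#' @param mip_thickness_mm thin-slab MIP thickness for QC renders (5-10 mm
#'   conventional; default the midpoint 7).
#' @param feeder_dilation_mm vessel-mask dilation for feeder classification.
#' @param feeder_overlap_threshold persistent-feeder overlap cutoff.
#' @param vesselness_scales_mm scales of the tubular filter.
#' @param min_vesselness no-artery cutoff for traces.
#' @param ci_alpha two-sided error level for confidence intervals.
#' @param seed global seed; per-case work derives from it deterministically.
#' @param reg deformable-registration settings, see [reg_params()].
#' @param align_on `"reference"` (rigid pre/post alignment on the native
#'   volumes) or `"maps"`.
#' @param keep_volumes retain enhancement maps and ROIs in case reports
#'   (memory-hungry; intended for interactive use and QC plots).
#' @return A `ctha_config` list.
#' @export
run_config <- function(tau_hu = 0, residual_threshold_hu = 20,
                       normal_roi_area_mm2 = 300, mip_thickness_mm = 7,
                       feeder_dilation_mm = 1.2, feeder_overlap_threshold = 0.5,
                       vesselness_scales_mm = c(1, 1.5, 2),
                       min_vesselness = 0.1, ci_alpha = 0.05, seed = 1L,
                       reg = reg_params(), align_on = "reference",
                       keep_volumes = FALSE) {
  structure(list(tau_hu = tau_hu, residual_threshold_hu = residual_threshold_hu,
                 normal_roi_area_mm2 = normal_roi_area_mm2,
                 mip_thickness_mm = mip_thickness_mm,
                 feeder_dilation_mm = feeder_dilation_mm,
                 feeder_overlap_threshold = feeder_overlap_threshold,
                 vesselness_scales_mm = vesselness_scales_mm,
                 min_vesselness = min_vesselness,
                 ci_alpha = ci_alpha, seed = as.integer(seed), reg = reg,
                 align_on = align_on, keep_volumes = keep_volumes),
            class = "ctha_config")
}

#' Case manifest
#'
#' Bundles the four acquisitions of one case with its masks and metadata.
#' Volumes and masks may be given as objects or as NIfTI file paths
#' (resolved at run time).
#'
#' @param case_id unique case identifier.
#' @param pre_native,pre_arterial,post_native,post_arterial [volume()]s or
#'   paths.
#' @param tumor_mask,liver_mask,vessel_mask [mask()]s or paths
#'   (`vessel_mask` optional), on the pre-treatment arterial grid.
#' @param root_mm hepatic-artery root for feeder tracing (optional).
#' @param label reference response label (optional; `"CR"`, `"PR"`, `"SD"`
#'   or collapsed forms).
#' @param lobe_split_x world x of the lobe-split plane; default: liver
#'   centroid.
#' @param tumor_lobe `"left"`/`"right"`; default: from the tumor centroid.
#' @return A `ctha_manifest` list.
#' @export
case_manifest <- function(case_id, pre_native, pre_arterial, post_native,
                          post_arterial, tumor_mask, liver_mask,
                          vessel_mask = NULL, root_mm = NULL, label = NULL,
                          lobe_split_x = NULL, tumor_lobe = NULL,
                          deformation_pre = NULL, deformation_post = NULL) {
  structure(list(case_id = case_id, pre_native = pre_native,
                 pre_arterial = pre_arterial, post_native = post_native,
                 post_arterial = post_arterial, tumor_mask = tumor_mask,
                 liver_mask = liver_mask, vessel_mask = vessel_mask,
                 root_mm = root_mm, label = label,
                 lobe_split_x = lobe_split_x, tumor_lobe = tumor_lobe,
                 deformation_pre = deformation_pre,
                 deformation_post = deformation_post),
            class = "ctha_manifest")
}

#' Manifest from a generated phantom case
#'
#' @param case output of [generate_case()].
#' @param case_id identifier.
#' @param use_truth_fields supply the generator's true deformation fields to
#'   the pipeline instead of estimating them, isolating the statistic path
#'   from registration error.
#' @return A [case_manifest()] with truth-derived masks, root and label.
#' @export
phantom_manifest <- function(case, case_id = "phantom", use_truth_fields = FALSE) {
  tr <- case$truth
  case_manifest(case_id,
                deformation_pre = if (use_truth_fields) tr$deformation_pre,
                deformation_post = if (use_truth_fields) tr$deformation_post,
                pre_native = case$pre_native, pre_arterial = case$pre_arterial,
                post_native = case$post_native, post_arterial = case$post_arterial,
                tumor_mask = tr$tumor_mask, liver_mask = tr$liver_mask,
                vessel_mask = tr$vessel_mask_pre,
                root_mm = tr$root_mm,
                label = if (tr$residual_truth) "non_complete_response"
                        else "complete_response",
                lobe_split_x = tr$lobe_split_x, tumor_lobe = tr$tumor_lobe)
}

resolve_volume <- function(x, what) {
  if (is.character(x)) read_volume(x) else x
}

resolve_mask <- function(x, label) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    v <- read_volume(x)
    mask(array(v$values > 0.5, dim(v$values)), v, label)
  } else x
}

rigid_inverse <- function(transform) {
  Rt <- t(transform$R)
  structure(list(R = Rt,
                 t = -as.vector(Rt %*% transform$t),
                 center = transform$center,
                 par = c(-as.vector(Rt %*% transform$t), -transform$par[4:6])),
            class = "ctha_rigid")
}

# nearest-neighbour resampling of a pre-grid mask onto a post grid through
# the pre->post rigid transform
mask_through_rigid <- function(m, target, transform) {
  inv <- rigid_inverse(transform)       # post world -> pre world
  Tm <- diag(4); Tm[1:3, 1:3] <- inv$R
  Tm[1:3, 4] <- inv$center - inv$R %*% inv$center + inv$t
  M4 <- solve(vol_affine(m)) %*% Tm %*% vol_affine(target)
  vals <- m$values; storage.mode(vals) <- "double"
  out <- cpp_resample_affine(vals, dim(vals), dim(target$values),
                             M4[1:3, , drop = FALSE], FALSE, FALSE, 0)
  mask(array(out > 0.5, dim(target$values)), target, label = m$label)
}

stage_msg <- function(stage, case_id, t0) {
  message(sprintf("[%s] %s: %.1f s", stage, case_id,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full method on one case
#'
#' Executes the chain: deformable registration and subtraction of each
#' native/arterial pair, rigid pre/post co-registration, ROI definition and
#' transfer, relative-enhancement quantitation (with the high-attenuation
#' correction on the post map), response classification, and — for residual
#' calls with a known artery root — residual-region detection and feeder
#' tracing/classification. Deterministic given the manifest and config.
#'
#' @param manifest a [case_manifest()] (or [phantom_manifest()]).
#' @param config a [run_config()].
#' @return A `ctha_case_report`: `result` (one-row tibble), `feeders`
#'   (tibble, possibly empty), `report` (registration reports), the
#'   effective `config` and package `version`; maps and ROIs when
#'   `config$keep_volumes`.
#' @export
run_case <- function(manifest, config = run_config()) {
  stopifnot(inherits(manifest, "ctha_manifest"))
  id <- manifest$case_id
  pre_nat <- resolve_volume(manifest$pre_native)
  pre_art <- resolve_volume(manifest$pre_arterial)
  post_nat <- resolve_volume(manifest$post_native)
  post_art <- resolve_volume(manifest$post_arterial)
  tumor_mask <- resolve_mask(manifest$tumor_mask, "tumor")
  liver_mask <- resolve_mask(manifest$liver_mask, "liver")
  vessel_mask <- resolve_mask(manifest$vessel_mask, "vessel")

  t0 <- as.numeric(Sys.time())
  if (is.null(manifest$deformation_pre)) {
    reg_pre <- register_deformable(pre_art, pre_nat, config$reg)
    reg_post <- register_deformable(post_art, post_nat, config$reg)
    field_pre <- reg_pre$field; field_post <- reg_post$field
    reg_reports <- list(pre = reg_pre$report, post = reg_post$report)
  } else {
    field_pre <- manifest$deformation_pre
    field_post <- manifest$deformation_post %||% manifest$deformation_pre
    reg_reports <- list(pre = "provided", post = "provided")
  }
  stage_msg("register", id, t0)

  t0 <- as.numeric(Sys.time())
  em_pre <- em_set_phase(compute_em(pre_nat, pre_art, field_pre,
                                    paste0(id, ":pre")), "pre")
  em_post <- em_set_phase(compute_em(post_nat, post_art, field_post,
                                     paste0(id, ":post")), "post")
  stage_msg("emap", id, t0)

  t0 <- as.numeric(Sys.time())
  if (!same_geometry(tumor_mask, em_pre))
    tumor_mask <- resample_to_reference(tumor_mask, em_pre)
  if (!same_geometry(liver_mask, em_pre))
    liver_mask <- resample_to_reference(liver_mask, em_pre)
  align <- align_em_pair(em_pre, em_post,
                         pre_ref = pre_nat, post_ref = post_nat,
                         on = config$align_on,
                         exclude_mask = tumor_mask)
  transform <- align$transform

  lobe_split_x <- manifest$lobe_split_x %||% {
    idx <- which(liver_mask$values, arr.ind = TRUE)
    mean(index_to_world(liver_mask, idx)[, 1])
  }
  roi_tumor <- define_tumor_roi(em_pre, tumor_mask)
  tumor_lobe <- manifest$tumor_lobe %||%
    (if (mean(roi_tumor$points[, 1]) > lobe_split_x) "left" else "right")
  roi_normal <- define_normal_roi(em_pre, liver_mask, tumor_lobe,
                                  vessel_mask = vessel_mask,
                                  lobe_split_x = lobe_split_x,
                                  area_mm2 = config$normal_roi_area_mm2,
                                  plane = roi_tumor$plane)
  re_pre <- relative_enhancement(em_pre, roi_tumor, roi_normal,
                                 high_attenuation_mode = FALSE,
                                 tau_hu = config$tau_hu)
  roi_tumor_post <- transfer_roi(roi_tumor, transform, em_post)
  roi_normal_post <- transfer_roi(roi_normal, transform, em_post)
  re_post <- relative_enhancement(em_post, roi_tumor_post, roi_normal_post,
                                  high_attenuation_mode = TRUE,
                                  tau_hu = config$tau_hu)
  call <- classify_response(re_post$T)
  stage_msg("response", id, t0)

  feeders <- tibble::tibble()
  if (call$call == "residual" && !is.null(manifest$root_mm)) {
    t0 <- as.numeric(Sys.time())
    tumor_mask_post <- if (same_geometry(em_pre, em_post) &&
                           max(abs(transform$par)) < 1e-8) tumor_mask
      else mask_through_rigid(tumor_mask, em_post, transform)
    regions <- detect_residual_regions(em_post, tumor_mask_post,
                                       config$residual_threshold_hu)
    if (length(regions) > 0) {
      vness <- vesselness(em_post, config$vesselness_scales_mm)
      root_post <- as.vector(rigid_apply(transform, matrix(manifest$root_mm, 1)))
      inv <- rigid_inverse(transform)
      rows <- list()
      for (ri in seq_along(regions)) {
        tr <- trace_feeder(em_post, regions[[ri]], root_post, vness,
                           min_vesselness = config$min_vesselness)
        if (is.null(tr)) next
        tr$path <- rigid_apply(inv, tr$path)   # express in the pre frame
        fc <- classify_feeder(tr, vessel_mask %||%
                                stop("feeder classification needs a pre-treatment vessel mask",
                                     call. = FALSE),
                              dilation_mm = config$feeder_dilation_mm,
                              overlap_threshold = config$feeder_overlap_threshold)
        rows[[length(rows) + 1]] <-
          dplyr::bind_cols(tibble::tibble(case_id = id, region_id = ri), fc)
      }
      feeders <- dplyr::bind_rows(rows)
    }
    stage_msg("feeders", id, t0)
  }

  result <- dplyr::bind_cols(
    tibble::tibble(case_id = id),
    tibble::tibble(T_pre_RE = re_pre$T, T_post_RE = re_post$T,
                   n_voxels_used = re_post$n_voxels_tumor_used,
                   tau_hu = config$tau_hu,
                   high_attenuation_applied = re_post$high_attenuation_applied,
                   call = call$call,
                   label = manifest$label %||% NA_character_))
  out <- list(case_id = id, result = result, feeders = feeders,
              registration = c(reg_reports, list(rigid = transform)),
              config = config,
              version = as.character(utils::packageVersion("cthaem")))
  if (isTRUE(config$keep_volumes))
    out <- c(out, list(em_pre = em_pre, em_post = em_post,
                       roi_tumor = roi_tumor, roi_normal = roi_normal,
                       roi_tumor_post = roi_tumor_post,
                       roi_normal_post = roi_normal_post))
  structure(out, class = "ctha_case_report")
}

#' @export
print.ctha_case_report <- function(x, ...) {
  cat(sprintf("<ctha_case_report> %s: %s (T_pre %.2f, T_post %.2f)\n",
              x$case_id, x$result$call, x$result$T_pre_RE, x$result$T_post_RE))
  if (nrow(x$feeders)) {
    cat(sprintf("  %d feeder(s): %s\n", nrow(x$feeders),
                paste(x$feeders$status, collapse = ", ")))
  }
  invisible(x)
}

#' Run the method over a cohort and evaluate against reference labels
#'
#' Processes every case, assembles the per-case result table, and — when
#' reference labels are present — cross-tabulates predictions against them
#' and computes the diagnostic-accuracy summary plus the rank-sum comparison
#' of post-treatment relative enhancement between predicted groups. Cases
#' without labels are processed but excluded from the evaluation.
#'
#' @param manifests list of [case_manifest()]s, or a cohort tibble from
#'   [generate_cohort()] (cases are then generated on the fly).
#' @param config a [run_config()].
#' @return A `ctha_cohort_report`: `cases` tibble, `feeders` tibble,
#'   `evaluation` (`confusion`, `metrics`, `ranksum`; `NULL` without
#'   labels), `config`.
#' @export
run_cohort <- function(manifests, config = run_config()) {
  is_cohort_tbl <- is.data.frame(manifests) && "spec" %in% names(manifests)
  ids <- if (is_cohort_tbl) manifests$case_id
         else vapply(manifests, function(m) m$case_id, "")
  if (anyDuplicated(ids))
    stop("duplicate case_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  n <- length(ids)
  reports <- vector("list", n)
  for (i in seq_len(n)) {
    mf <- if (is_cohort_tbl) {
      cs <- generate_case(manifests$spec[[i]])
      m <- phantom_manifest(cs, manifests$case_id[i])
      m$label <- manifests$label[i]
      m
    } else manifests[[i]]
    reports[[i]] <- run_case(mf, config)
  }
  cases <- dplyr::bind_rows(lapply(reports, function(r) r$result))
  feeders <- dplyr::bind_rows(lapply(reports, function(r) r$feeders))
  evaluation <- NULL
  lab <- !is.na(cases$label)
  if (any(lab)) {
    confusion <- cross_tabulate(cases$call[lab], cases$label[lab])
    metrics <- diagnostic_metrics(confusion, config$ci_alpha)
    grp_res <- cases$T_post_RE[lab & cases$call == "residual"]
    grp_non <- cases$T_post_RE[lab & cases$call == "non_residual"]
    ranksum <- if (length(grp_res) && length(grp_non))
      wilcoxon_rank_sum(grp_res, grp_non) else NULL
    evaluation <- list(confusion = confusion, metrics = metrics,
                       ranksum = ranksum)
  }
  structure(list(cases = cases, feeders = feeders, evaluation = evaluation,
                 config = config),
            class = "ctha_cohort_report")
}

#' @export
print.ctha_cohort_report <- function(x, ...) {
  cat(sprintf("<ctha_cohort_report> %d cases, %d residual calls\n",
              nrow(x$cases), sum(x$cases$call == "residual")))
  if (!is.null(x$evaluation)) print(x$evaluation$metrics)
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Materializes a [generate_cohort()] design as NIfTI volumes and truth
#' masks plus a JSON manifest (parameters, labels, expected statistics,
#' per-case seeds), ready for [run_cohort()] or external tools.
#'
#' @param n_cases,residual_prevalence,base_spec,seed see [generate_cohort()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return The manifest path, invisibly.
#' @export
simulate_cohort <- function(n_cases, residual_prevalence,
                            base_spec = phantom_spec(), seed = 1L,
                            out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_cases, residual_prevalence, base_spec, seed)
  entries <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    cs <- generate_case(cohort$spec[[i]])
    id <- cohort$case_id[i]
    pth <- function(nm) file.path(out_dir, paste0(id, "_", nm, ".nii.gz"))
    write_volume(cs$pre_native, pth("pre_native"))
    write_volume(cs$pre_arterial, pth("pre_arterial"))
    write_volume(cs$post_native, pth("post_native"))
    write_volume(cs$post_arterial, pth("post_arterial"))
    write_volume(cs$truth$tumor_mask, pth("tumor_mask"))
    write_volume(cs$truth$liver_mask, pth("liver_mask"))
    write_volume(cs$truth$vessel_mask_pre, pth("vessel_mask"))
    if (cs$truth$residual_truth)
      write_volume(cs$truth$residual_mask, pth("residual_mask"))
    entries[[i]] <- list(
      case_id = id, seed = cohort$seed[i],
      residual_fraction = cohort$residual_fraction[i],
      label = cohort$label[i],
      expected_T_pre = cs$truth$expected_T_pre,
      expected_T_post = cs$truth$expected_T_post,
      expected_T_post_whole = cs$truth$expected_T_post_whole,
      root_mm = cs$truth$root_mm,
      lobe_split_x = cs$truth$lobe_split_x,
      tumor_lobe = cs$truth$tumor_lobe,
      volumes = list(pre_native = basename(pth("pre_native")),
                     pre_arterial = basename(pth("pre_arterial")),
                     post_native = basename(pth("post_native")),
                     post_arterial = basename(pth("post_arterial"))),
      masks = list(tumor = basename(pth("tumor_mask")),
                   liver = basename(pth("liver_mask")),
                   vessel = basename(pth("vessel_mask"))))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(n_cases = n_cases,
                            residual_prevalence = residual_prevalence,
                            seed = seed, cases = entries),
                       manifest_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Serialize a case report to JSON
#'
#' Writes the quantitative results, feeder table, and the full effective
#' configuration. Reports contain no timestamps: identical inputs and
#' configuration produce byte-identical files.
#'
#' @param report a `ctha_case_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  payload <- list(case_id = report$case_id,
                  version = report$version,
                  result = report$result,
                  feeders = report$feeders,
                  rigid_transform = list(R = report$registration$rigid$R,
                                         t = report$registration$rigid$t,
                                         center = report$registration$rigid$center),
                  config = unclass_config(report$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$reg <- unclass(x$reg)
  x
}
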