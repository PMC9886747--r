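# Residual-region detection, vesselness, feeder tracing and classification.

test_that("residual-region detection finds nothing on treated zero-noise phantoms", {
  cs <- generate_case(quick_spec(seed = 14, residual_fraction = 0,
                                 noise_sigma_hu = 0, deformation_amplitude_mm = 0))
  em <- compute_em(cs$post_native, cs$post_arterial, zero_field(cs$post_arterial))
  expect_length(detect_residual_regions(em, cs$truth$tumor_mask), 0)
})

test_that("the residual cap is detected and matches truth; regions sort by size", {
  cs <- generate_case(quick_spec(seed = 15, residual_fraction = 0.5,
                                 deformation_amplitude_mm = 0))
  em <- compute_em(cs$post_native, cs$post_arterial, zero_field(cs$post_arterial))
  regions <- detect_residual_regions(em, cs$truth$tumor_mask)
  expect_gte(length(regions), 1)
  m <- regions[[1]]$mask$values; r <- cs$truth$residual_mask$values
  dice <- 2 * sum(m & r) / (sum(m) + sum(r))
  expect_gt(dice, 0.8)
  sizes <- vapply(regions, function(x) x$n_voxels, 1)
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(vapply(regions, function(x) x$n_voxels >= 5, TRUE)))
  # every region is a subset of the tumor mask
  for (rg in regions)
    expect_true(all(!rg$mask$values | cs$truth$tumor_mask$values))
})

test_that("two disjoint residual blobs give two regions, larger first", {
  d <- c(30, 30, 30)
  ref <- volume(array(0, d))
  vals <- array(0, d)
  tm <- array(FALSE, d); tm[5:26, 5:26, 5:26] <- TRUE
  vals[6:10, 6:10, 6:10] <- 50          # 125 voxels
  vals[18:20, 18:20, 18:20] <- 50       # 27 voxels
  em <- compute_em(volume(array(0, d)), volume(vals), zero_field(ref))
  regions <- detect_residual_regions(em, mask(tm, ref, "tumor"), threshold_hu = 20)
  expect_length(regions, 2)
  expect_equal(regions[[1]]$n_voxels, 125)
  expect_equal(regions[[2]]$n_voxels, 27)
})

test_that("vesselness scores tubes above background, blobs and flat volumes", {
  d <- c(32, 32, 32)
  flat <- volume(array(7, d))
  expect_true(all(vesselness(flat, 1.5)$values == 0))
  # straight tube of radius ~1.5 mm
  tube <- array(0, d)
  tube <- cthaem:::cpp_add_tube(tube, d, c(1, 1, 1), c(15, 15, 4), c(15, 15, 27),
                                1.5 / 2 * 2, 300)   # sigma 1.5
  vt <- vesselness(volume(tube), scales_mm = 1.5)
  centerline <- vt$values[16, 16, 10:22]
  expect_true(all(centerline > 0.5))
  bg <- vt$values[4:8, 4:8, 4:8]
  expect_true(all(bg < 0.05))
  # sphere of the same peak scores lower at its center than the tube centerline
  sph <- array(0, d)
  g <- expand.grid(i = 1:32, j = 1:32, k = 1:32)
  r2 <- (g$i - 16)^2 + (g$j - 16)^2 + (g$k - 16)^2
  sph[] <- 300 * exp(-r2 / (2 * 9))
  vs <- vesselness(volume(sph), scales_mm = 1.5)
  expect_lt(vs$values[16, 16, 16], min(centerline))
  expect_error(vesselness(flat, numeric(0)), "scale")
  expect_error(vesselness(flat, -1), "scale")
})

test_that("feeder tracing follows the tube into the residual cap", {
  cs <- generate_case(two_vessel_spec(seed = 21))
  tr <- cs$truth
  em <- compute_em(cs$post_native, cs$post_arterial, tr$deformation_post)
  regions <- detect_residual_regions(em, tr$tumor_mask)
  vn <- vesselness(em)
  trace <- trace_feeder(em, regions[[1]], tr$root_mm, vn)
  expect_s3_class(trace, "ctha_trace")
  # mean distance from the trace to the true centerline < 2 voxels (1.2 mm)
  ctrline <- tr$vessel_centerlines[[1]]$points
  # densify the polyline
  dens <- do.call(rbind, lapply(seq_len(nrow(ctrline) - 1), function(s) {
    t <- seq(0, 1, length.out = 50)
    outer(1 - t, ctrline[s, ]) + outer(t, ctrline[s + 1, ])
  }))
  en_route <- trace$path[trace$path[, 3] > 33.5, , drop = FALSE]  # outside cap
  dmin <- apply(en_route, 1, function(p) min(sqrt(colSums((t(dens) - p)^2))))
  expect_lt(mean(dmin), 2 * 0.6)
  # all-zero vesselness -> no artery
  vz <- vn; vz$values[] <- 0
  expect_null(trace_feeder(em, regions[[1]], tr$root_mm, vz))
  # root outside the volume errors
  expect_error(trace_feeder(em, regions[[1]], c(-50, 0, 0), vn), "outside")
})

test_that("the traced path is invariant to uniform rescaling of vesselness", {
  cs <- generate_case(two_vessel_spec(seed = 22))
  tr <- cs$truth
  em <- compute_em(cs$post_native, cs$post_arterial, tr$deformation_post)
  regions <- detect_residual_regions(em, tr$tumor_mask)
  vn <- vesselness(em)
  t1 <- trace_feeder(em, regions[[1]], tr$root_mm, vn)
  vn2 <- vn; vn2$values <- vn$values * 0.37
  t2 <- trace_feeder(em, regions[[1]], tr$root_mm, vn2)
  expect_identical(t1$path, t2$path)
})

test_that("the path follows the brighter of two candidate tubes", {
  d <- c(40, 40, 12)
  ref <- volume(array(0, d))
  vals <- array(0, d)
  # two tubes sharing a root, one dim (y = 14) and one bright (y = 26)
  vals <- cthaem:::cpp_add_tube(vals, d, c(1, 1, 1), c(4, 20, 6), c(10, 14, 6), 1, 150)
  vals <- cthaem:::cpp_add_tube(vals, d, c(1, 1, 1), c(10, 14, 6), c(35, 14, 6), 1, 150)
  vals <- cthaem:::cpp_add_tube(vals, d, c(1, 1, 1), c(4, 20, 6), c(10, 26, 6), 1, 300)
  vals <- cthaem:::cpp_add_tube(vals, d, c(1, 1, 1), c(10, 26, 6), c(35, 26, 6), 1, 300)
  # both join a target blob at the far end
  vals[36:38, 12:28, 5:8] <- 200
  tm <- array(FALSE, d); tm[36:38, 12:28, 5:8] <- TRUE
  em <- compute_em(volume(array(0, d)), volume(vals), zero_field(ref))
  regions <- detect_residual_regions(em, mask(tm, ref, "tumor"))
  vn <- vesselness(volume(vals), scales_mm = 1)
  # root reachable from both tubes
  trace <- trace_feeder(em, regions[[1]], c(4, 20, 6), vn, min_vesselness = 0.01)
  expect_s3_class(trace, "ctha_trace")
  mid <- trace$path[trace$path[, 1] > 12 & trace$path[, 1] < 30, , drop = FALSE]
  expect_true(mean(abs(mid[, 2] - 26)) < mean(abs(mid[, 2] - 14)))
})

test_that("feeder classification separates persistent feeders from new collaterals", {
  cs <- generate_case(two_vessel_spec(seed = 23))
  tr <- cs$truth
  expect_true(tr$new_collateral_present)
  em <- compute_em(cs$post_native, cs$post_arterial, tr$deformation_post)
  regions <- detect_residual_regions(em, tr$tumor_mask)
  vn <- vesselness(em)
  feeder_trace <- trace_feeder(em, regions[[1]], tr$root_mm, vn)
  coll_root <- tr$vessel_centerlines[[2]]$points[1, ]
  coll_trace <- trace_feeder(em, regions[[1]], coll_root, vn)
  fc <- classify_feeder(feeder_trace, tr$vessel_mask_pre)
  cc <- classify_feeder(coll_trace, tr$vessel_mask_pre)
  expect_equal(fc$status, "persistent_feeder")
  expect_gt(fc$overlap_fraction, 0.9)
  expect_equal(cc$status, "new_collateral")
  expect_lt(cc$overlap_fraction, 0.1)
  expect_error(classify_feeder(NULL, tr$vessel_mask_pre), "empty")
})

test_that("the overlap rule is >= at the threshold", {
  d <- c(10, 10, 10)
  ref <- volume(array(0, d))
  vm <- array(FALSE, d); vm[1:5, 5, 5] <- TRUE   # x in 0..4 (world)
  # path of 4 points: 2 inside the dilated mask, 2 far outside
  trace <- structure(list(path = rbind(c(2, 4, 4), c(3, 4, 4),
                                       c(8, 8, 8), c(9, 8, 8)),
                          length_mm = 3),
                     class = "ctha_trace")
  fc <- classify_feeder(trace, mask(vm, ref, "vessel"),
                        dilation_mm = 1.2, overlap_threshold = 0.5)
  expect_equal(fc$overlap_fraction, 0.5)
  expect_equal(fc$status, "persistent_feeder")
})
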