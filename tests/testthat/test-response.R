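# ROI definition/transfer and the relative-enhancement statistic.

make_em <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume(values, spacing, origin)
  compute_em(volume(array(0, dim(values)), spacing, origin), v, zero_field(v))
}

test_that("tumor ROI picks the maximal cross-section with the axial tie-break", {
  # sphere: equatorial axial slice, area ~ pi r^2, tie broken toward axial
  d <- c(40, 40, 40)
  g <- expand.grid(i = 1:40, j = 1:40, k = 1:40)
  sphere <- array((g$i - 20)^2 + (g$j - 20)^2 + (g$k - 20)^2 <= 8^2, d)
  ref <- volume(array(0, d))
  em <- make_em(array(0, d))
  roi <- define_tumor_roi(em, mask(sphere, ref, "tumor"))
  expect_equal(roi$plane, "axial")
  expect_equal(roi$slice_mm, 19)   # slice k = 20 (0-based world 19)
  expect_lt(abs(nrow(roi$points) - pi * 64) / (pi * 64), 0.05)
  expect_lt(abs(roi_area(roi) - pi * 64) / (pi * 64), 0.15)
  # oblate ellipsoid taller than wide: coronal cross-section wins
  ell <- array(((g$i - 20) / 6)^2 + ((g$j - 20) / 4)^2 + ((g$k - 20) / 10)^2 <= 1, d)
  roi2 <- define_tumor_roi(em, mask(ell, ref, "tumor"))
  expect_equal(roi2$plane, "coronal")
  # analytic: max coronal area pi*6*10 vs axial pi*6*4
  expect_lt(abs(nrow(roi2$points) - pi * 60) / (pi * 60), 0.1)
  # degenerate single-voxel tumor
  single <- array(FALSE, d); single[5, 6, 7] <- TRUE
  roi3 <- define_tumor_roi(em, mask(single, ref, "tumor"))
  expect_equal(nrow(roi3$points), 1L)
  expect_equal(unname(roi3$points[1, ]), c(4, 5, 6))
  expect_error(define_tumor_roi(em, mask(array(FALSE, d), ref, "tumor")), "empty")
})

test_that("normal ROI avoids vessels and sits in the contralateral lobe", {
  cs <- generate_case(quick_spec(seed = 11, noise_sigma_hu = 0,
                                 deformation_amplitude_mm = 0))
  em <- compute_em(cs$pre_native, cs$pre_arterial, zero_field(cs$pre_arterial))
  tr <- cs$truth
  roi <- define_normal_roi(em, tr$liver_mask, tr$tumor_lobe,
                           vessel_mask = tr$vessel_mask_pre,
                           lobe_split_x = tr$lobe_split_x)
  expect_equal(roi$role, "normal")
  expect_lt(abs(roi_area(roi) - 300) / 300, 0.05)
  # all sample points in the contralateral (here: right, x < split) lobe,
  # inside the liver, and off the vessel mask
  ci <- round(cthaem:::world_to_index(tr$liver_mask, roi$points))
  lin <- cbind(ci)
  inside <- mapply(function(i, j, k) tr$liver_mask$values[i, j, k],
                   ci[, 1], ci[, 2], ci[, 3])
  onvessel <- mapply(function(i, j, k) tr$vessel_mask_pre$values[i, j, k],
                     ci[, 1], ci[, 2], ci[, 3])
  expect_true(all(inside))
  expect_false(any(onvessel))
  expect_true(all(roi$points[, 1] < tr$lobe_split_x))
  # with no vessel mask the ROI still fits (largest inscribed disk)
  roi2 <- define_normal_roi(em, tr$liver_mask, tr$tumor_lobe,
                            lobe_split_x = tr$lobe_split_x)
  expect_lt(abs(roi_area(roi2) - 300) / 300, 0.05)
  # an impossible contralateral lobe errors with advice
  expect_error(define_normal_roi(em, tr$liver_mask, "right",
                                 lobe_split_x = 100), "area_mm2")
})

test_that("ROI transfer is an isometry and snaps slices on the target grid", {
  cs <- generate_case(quick_spec(seed = 12, noise_sigma_hu = 0,
                                 deformation_amplitude_mm = 0))
  em <- compute_em(cs$pre_native, cs$pre_arterial, zero_field(cs$pre_arterial))
  roi <- define_tumor_roi(em, cs$truth$tumor_mask)
  idt <- rigid_identity()
  same <- transfer_roi(roi, idt, em)
  expect_equal(same$points, roi$points)
  shift <- rigid_identity(); shift$t <- c(4, 0, 0)
  moved <- transfer_roi(roi, shift)
  expect_equal(moved$points[, 1], roi$points[, 1] + 4)
  expect_equal(moved$points[, 2:3], roi$points[, 2:3])
  # area preserved under an arbitrary rigid motion (in-plane rotation keeps
  # the region planar)
  rot <- rigid_identity(center = c(28.5, 28.5, 28.5))
  rot$R <- cthaem:::rigid_rotation(c(0, 0, 25 * pi / 180))
  rot$t <- c(2, -1, 3)
  rroi <- transfer_roi(roi, rot)
  expect_equal(roi_area(rroi), roi_area(roi), tolerance = 1e-6)
  # far outside the target volume -> error
  far <- rigid_identity(); far$t <- c(0, 0, 500)
  expect_error(transfer_roi(roi, far, em), "outside")
})

test_that("relative enhancement reproduces hand-computed subset means", {
  d <- c(10, 10, 3)
  vals <- array(0, d)
  # tumor voxels on slice 2: values {0, 0, 0, 0, 40, 40}
  tv <- cbind(i = 2:7, j = 2, k = 2)
  vals[tv] <- c(0, 0, 0, 0, 40, 40)
  # normal voxels: constant 20
  nv <- cbind(i = 2:7, j = 8, k = 2)
  vals[nv] <- 20
  em <- make_em(vals)
  roi_t <- cthaem:::new_planar_roi("axial", 1, cbind(tv[, 1] - 1, tv[, 2] - 1, 1),
                                   cbind(c(0, 8, 8, 0), c(0, 0, 3, 3), 1), "tumor")
  roi_n <- cthaem:::new_planar_roi("axial", 1, cbind(nv[, 1] - 1, nv[, 2] - 1, 1),
                                   cbind(c(0, 8, 8, 0), c(6, 6, 9, 9), 1), "normal")
  plain <- relative_enhancement(em, roi_t, roi_n)
  expect_equal(plain$T, (80 / 6) / 20, tolerance = 1e-12)
  sub <- relative_enhancement(em, roi_t, roi_n, high_attenuation_mode = TRUE)
  expect_equal(sub$T, 40 / 20, tolerance = 1e-12)
  expect_true(sub$high_attenuation_applied)
  expect_equal(sub$n_voxels_tumor_used, 2L)
  # when no voxel exceeds tau, the whole ROI is used and the mode flagged off
  vals2 <- vals; vals2[tv] <- c(-5, -4, -3, 0, -1, 0); em2 <- make_em(vals2)
  allneg <- relative_enhancement(em2, roi_t, roi_n, high_attenuation_mode = TRUE)
  expect_false(allneg$high_attenuation_applied)
  expect_equal(allneg$n_voxels_tumor_used, 6L)
  # simple arithmetic: tumor mean 60, normal 20 -> 3.0
  vals3 <- vals; vals3[tv] <- 60; em3 <- make_em(vals3)
  expect_equal(relative_enhancement(em3, roi_t, roi_n)$T, 3)
  # non-positive normal mean is a normalization error
  vals4 <- vals; vals4[nv] <- -2; em4 <- make_em(vals4)
  expect_error(relative_enhancement(em4, roi_t, roi_n), "normaliz")
})

test_that("T and the classification are invariant to positive rescaling of the map", {
  cs <- generate_case(quick_spec(seed = 13, deformation_amplitude_mm = 0))
  em <- compute_em(cs$post_native, cs$post_arterial, zero_field(cs$post_arterial))
  rt <- define_tumor_roi(em, cs$truth$tumor_mask)
  rn <- define_normal_roi(em, cs$truth$liver_mask, cs$truth$tumor_lobe,
                          vessel_mask = cs$truth$vessel_mask_pre,
                          lobe_split_x = cs$truth$lobe_split_x)
  base <- relative_enhancement(em, rt, rn, TRUE)
  for (c in c(0.5, 2, 13)) {
    sc <- em; sc$values <- em$values * c
    got <- relative_enhancement(sc, rt, rn, TRUE)
    expect_equal(got$T, base$T, tolerance = 1e-9)
    expect_equal(classify_response(got$T)$call, classify_response(base$T)$call)
  }
})

test_that("the residual rule is strict at 1", {
  expect_equal(classify_response(3.05)$call, "residual")
  expect_equal(classify_response(0.48)$call, "non_residual")
  expect_equal(classify_response(1.0)$call, "non_residual")
  expect_equal(classify_response(1 + 1e-12)$call, "residual")
  expect_error(classify_response(NaN), "finite")
  expect_error(classify_response(Inf), "finite")
})

test_that("zero-noise phantoms classify by construction across seeds", {
  for (s in 101:105) {
    cs0 <- generate_case(quick_spec(seed = s, residual_fraction = 0,
                                    noise_sigma_hu = 0, deformation_amplitude_mm = 0))
    em0 <- compute_em(cs0$post_native, cs0$post_arterial, zero_field(cs0$post_arterial))
    rt <- define_tumor_roi(em0, cs0$truth$tumor_mask)
    rn <- define_normal_roi(em0, cs0$truth$liver_mask, cs0$truth$tumor_lobe,
                            vessel_mask = cs0$truth$vessel_mask_pre,
                            lobe_split_x = cs0$truth$lobe_split_x)
    T0 <- relative_enhancement(em0, rt, rn, TRUE)$T
    expect_equal(classify_response(T0)$call, "non_residual")
    cs1 <- generate_case(quick_spec(seed = s, residual_fraction = 1,
                                    noise_sigma_hu = 0, deformation_amplitude_mm = 0))
    em1 <- compute_em(cs1$post_native, cs1$post_arterial, zero_field(cs1$post_arterial))
    T1 <- relative_enhancement(em1, define_tumor_roi(em1, cs1$truth$tumor_mask),
                               rn, TRUE)$T
    expect_equal(classify_response(T1)$call, "residual")
  }
})
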