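# Deformable and rigid registration, warping, and recovery-error metrics.

test_that("self-registration yields a near-identity field", {
  cs <- generate_case(quick_spec(seed = 2, noise_sigma_hu = 0,
                                 deformation_amplitude_mm = 0))
  v <- cs$pre_arterial
  reg <- register_deformable(v, v, reg_params(iterations = c(30, 20, 10)))
  nrm <- sqrt(rowSums(matrix(reg$field$displacements, ncol = 3)^2))
  expect_lt(mean(nrm), 0.1)
})

test_that("metric traces are non-increasing within each level", {
  cs <- generate_case(quick_spec(seed = 12, deformation_amplitude_mm = 3))
  reg <- register_deformable(cs$pre_arterial, cs$pre_native,
                             reg_params(iterations = c(40, 20, 10)))
  for (tr in reg$report$metric_trace)
    expect_true(all(diff(tr) <= 1e-9))
})

test_that("a known smooth self-warp is recovered accurately with positive Jacobian", {
  # moving = fixed warped by a known 3 mm field: pure recovery, no
  # cross-phase intensity differences
  cs <- generate_case(quick_spec(seed = 5, noise_sigma_hu = 0,
                                 deformation_amplitude_mm = 0))
  fixed <- cs$pre_arterial
  g <- cthaem:::as_geometry(fixed)
  w <- simulate_deformation(g, 3, seed = 77)
  u <- w$displacements
  moving <- volume(cthaem:::cpp_warp_same_grid(
    fixed$values, g$dim, u[, , , 1] / g$spacing[1], u[, , , 2] / g$spacing[2],
    u[, , , 3] / g$spacing[3], TRUE, TRUE, 0),
    g$spacing, g$origin, g$axes)
  reg <- register_deformable(fixed, moving)
  truth <- invert_field(w)
  err <- registration_error(reg$field, truth, cs$truth$liver_mask)
  expect_lt(err[["mean_mm"]], 0.5)
  jd <- cthaem:::field_jacobian(reg$field)
  expect_gte(mean(jd[cs$truth$liver_mask$values] > 0), 0.999)
})

test_that("recovery error decreases with deformation amplitude", {
  errs <- sapply(1:10, function(s) {
    sapply(c(5, 1), function(amp) {
      cs <- generate_case(quick_spec(seed = 400 + s,
                                     deformation_amplitude_mm = amp))
      reg <- register_deformable(cs$pre_arterial, cs$pre_native,
                                 reg_params(iterations = c(80, 40, 20)))
      registration_error(reg$field, cs$truth$deformation_pre,
                         cs$truth$liver_mask)[["mean_mm"]]
    })
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
})

test_that("warping through identity and integer-shift fields is exact", {
  v <- fun_volume(function(x, y, z) x * 2 + y - z, dim = c(10, 9, 8))
  f0 <- zero_field(v)
  expect_identical(warp(v, f0)$values, v$values)
  # pure +2-voxel shift along x: out(x) = v(x + 2)
  u <- array(0, c(dim(v$values), 3)); u[, , , 1] <- 2
  f2 <- deformation_field(u, v)
  w <- warp(v, f2)
  expect_equal(w$values[1:8, , ], v$values[3:10, , ], tolerance = 1e-12)
  expect_true(all(is.na(w$values[9:10, , ])))   # shifted out of field
  # masks stay binary under nearest-neighbour warping
  m <- mask(array(rep(c(TRUE, FALSE), length.out = 720), c(10, 9, 8)), v, "tumor")
  wm <- warp(m, f2)
  expect_true(is.logical(wm$values))
})

test_that("warp followed by inverse warp returns close to the original", {
  g <- list(dim = c(32, 32, 32), spacing = c(1.8, 1.8, 1.8),
            origin = c(0, 0, 0), axes = diag(3))
  smooth_vol <- fun_volume(function(x, y, z)
    50 * exp(-((x - 28)^2 + (y - 28)^2 + (z - 28)^2) / 300),
    dim = g$dim, spacing = g$spacing)
  fld <- simulate_deformation(g, 3, seed = 8)
  inv <- invert_field(fld)
  back <- warp(warp(smooth_vol, fld), inv)
  core <- back$values[5:28, 5:28, 5:28]
  orig <- smooth_vol$values[5:28, 5:28, 5:28]
  expect_lt(mean(abs(core - orig), na.rm = TRUE), 0.5)
})

test_that("rigid registration recovers identity, translations and rotations", {
  cs <- generate_case(quick_spec(seed = 6, noise_sigma_hu = 0,
                                 deformation_amplitude_mm = 0))
  fixed <- cs$pre_native
  # identity
  t0 <- register_rigid(fixed, fixed)
  expect_lt(max(abs(t0$t)), 0.1)
  expect_lt(max(abs(t0$par[4:6])) * 180 / pi, 0.1)
  # known 4 mm translation: same content, origin shifted
  moving <- fixed; moving$origin <- fixed$origin + c(4, 0, 0)
  tt <- register_rigid(fixed, moving)
  expect_lt(max(abs(tt$t - c(4, 0, 0))), 0.3)
  expect_lt(max(abs(tt$par[4:6])) * 180 / pi, 0.5)
  # known 3 degree rotation about the craniocaudal (z) axis; resampling the
  # fixed image through Tm makes moving(y) = fixed(T y), so the estimated
  # fixed-to-moving transform is the inverse: -3 degrees
  ang <- 3 * pi / 180
  ctr <- as.vector(cthaem:::index_to_world(fixed, matrix((dim(fixed$values) + 1) / 2, 1)))
  R <- cthaem:::rigid_rotation(c(0, 0, ang))
  A <- cthaem:::vol_affine(fixed)
  Tm <- diag(4); Tm[1:3, 1:3] <- R; Tm[1:3, 4] <- ctr - R %*% ctr
  M4 <- solve(A) %*% Tm %*% A
  mv <- cthaem:::cpp_resample_affine(fixed$values, dim(fixed$values),
                                     dim(fixed$values), M4[1:3, , drop = FALSE],
                                     TRUE, TRUE, 0)
  moving_rot <- volume(mv, fixed$spacing, fixed$origin, fixed$axes)
  tr <- register_rigid(fixed, moving_rot)
  expect_lt(abs(tr$par[6] - (-ang)) * 180 / pi, 0.3)
  expect_lt(max(abs(tr$par[4:5])) * 180 / pi, 0.3)
})

test_that("registration error matches a brute-force per-voxel computation", {
  g <- list(dim = c(6, 5, 4), spacing = c(1, 1, 1), origin = c(0, 0, 0),
            axes = diag(3))
  set.seed(10)
  ue <- array(stats::rnorm(prod(g$dim) * 3, sd = 0.5), c(g$dim, 3))
  ut <- array(stats::rnorm(prod(g$dim) * 3, sd = 0.5), c(g$dim, 3))
  fe <- deformation_field(ue, g); ft <- deformation_field(ut, g)
  ref <- volume(array(0, g$dim), g$spacing)
  roi <- mask(array(stats::runif(prod(g$dim)) > 0.3, g$dim), ref, "liver")
  got <- registration_error(fe, ft, roi)
  # independent loop
  vals <- c()
  for (k in seq_len(g$dim[3])) for (j in seq_len(g$dim[2]))
    for (i in seq_len(g$dim[1]))
      if (roi$values[i, j, k])
        vals <- c(vals, sqrt(sum((ue[i, j, k, ] - ut[i, j, k, ])^2)))
  expect_equal(got[["mean_mm"]], mean(vals), tolerance = 1e-9)
  n <- length(vals)
  expect_equal(got[["std_mm"]], stats::sd(vals) * sqrt((n - 1) / n),
               tolerance = 1e-9)
  # closed forms
  expect_equal(unname(registration_error(fe, fe, roi)), c(0, 0))
  u2 <- array(0, c(g$dim, 3)); u2[, , , 1] <- 2
  got2 <- registration_error(deformation_field(u2, g),
                             deformation_field(array(0, c(g$dim, 3)), g), roi)
  expect_equal(unname(got2), c(2, 0), tolerance = 1e-12)
  empty <- mask(array(FALSE, g$dim), ref, "liver")
  expect_error(registration_error(fe, ft, empty), "empty")
})

test_that("non-overlapping volumes are rejected", {
  a <- volume(array(0, c(5, 5, 5)), origin = c(0, 0, 0))
  b <- volume(array(0, c(5, 5, 5)), origin = c(100, 100, 100))
  expect_error(register_deformable(a, b), "overlap")
  expect_error(register_rigid(a, b), "overlap")
})
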