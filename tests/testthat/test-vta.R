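# Analytic point-source field shared across blocks (0.2 mm fast grid).
ps <- point_source_grid(5.5e-3, 0.12, half_mm = 8, h_mm = 0.2)
eig_ps <- hessian_primary_eigenvalue(ps)
k_ps <- 5.5e-3 / (4 * pi * 0.12)

test_that("threshold units convert V/cm^2 -> V/m^2 by exactly 1e4", {
  for (x in c(26.6, 1, 0.37, 100))
    expect_identical(vta_config(threshold_V_cm2 = x)$threshold_V_m2, x * 1e4)
  expect_error(vta_config(threshold_V_cm2 = -1))
  expect_error(vta_config(spacing_mm = 0))
})

test_that("sampling is exact for constant and affine potentials", {
  g <- grid_from_bbox(rbind(rep(-15, 3), rep(15, 3)), 1)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], g$dim)
  model <- tissue_model(voxel_grid(lab, g$origin, g$spacing),
                        c(BrainGreyMatter = 0.12))
  mkfield <- function(vals) structure(
    list(grid = voxel_grid(vals, g$origin, g$spacing), current = 1e-3,
         active_id = NA_integer_, impedance = NA_real_,
         contact_potential = NA_real_, iterations = 0L, residual = 0,
         model = model, phi_unit = NULL),
    class = "potential_field")
  cfg <- vta_config(box_mm = 10, spacing_mm = 0.5)
  cst <- sample_grid(mkfield(array(3.14, g$dim)), cfg, center = c(0, 0, 0))
  expect_true(all(abs(cst$values - 3.14) < 1e-12))
  ax <- grid_axes(g)
  aff <- outer(outer(0.2 * ax$x, -0.1 * ax$y, "+"), 0.05 * ax$z + 1, "+")
  smp <- sample_grid(mkfield(aff), cfg, center = c(1.2, -0.7, 2.1))
  axf <- grid_axes(smp)
  expect_equal(smp$values,
               outer(outer(0.2 * axf$x, -0.1 * axf$y, "+"),
                     0.05 * axf$z + 1, "+"),
               tolerance = 1e-10)
  expect_error(sample_grid(mkfield(aff), vta_config(box_mm = 50),
                           center = c(0, 0, 0)),
               "exceeds")
})

test_that("Hessian eigenvalues reproduce analytic fields", {
  g <- grid_from_bbox(rbind(rep(-5, 3), rep(5, 3)), 0.5)
  ax <- grid_axes(g)
  # phi = x^2 (x in m): lambda1 = 2 V/m^2 everywhere valid
  phi <- outer(outer((ax$x * 1e-3)^2, rep(0, g$dim[2]), "+"),
               rep(0, g$dim[3]), "+")
  e <- hessian_primary_eigenvalue(voxel_grid(phi, g$origin, g$spacing))
  v <- e$values[2:(g$dim[1] - 1), 2:(g$dim[2] - 1), 2:(g$dim[3] - 1)]
  expect_equal(max(abs(v - 2)), 0, tolerance = 1e-6)
  # affine field: zero curvature
  aff <- outer(outer(2 * ax$x, 3 * ax$y, "+"), -ax$z + 5, "+")
  e0 <- hessian_primary_eigenvalue(voxel_grid(aff, g$origin, g$spacing))
  expect_lt(max(abs(e0$values), na.rm = TRUE), 1e-6)
  # border is invalid
  expect_true(all(is.na(e0$values[1, , ])))
  expect_error(hessian_primary_eigenvalue(
    voxel_grid(phi, g$origin, c(0.5, 0.5, 0.4))), "uniform")
})

test_that("point-source lambda1 matches 2k/r^3 within 1%", {
  pts <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3),
               c(1, 2, 2) / 3 * 3)
  lam <- interp_trilinear(eig_ps, pts)
  exact <- 2 * k_ps / 0.003^3    # 2.70e5 V/m^2
  expect_equal(exact, 2.70e5, tolerance = 1e-3)
  expect_true(all(abs(lam - exact) / exact < 0.01))
})

test_that("harmonic fields have a non-negative primary eigenvalue", {
  ax <- grid_axes(eig_ps)
  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  ok <- !is.na(eig_ps$values) & r2 > 1
  expect_gt(sum(ok), 1e5)
  expect_true(all(eig_ps$values[ok] > -1e-6 * max(eig_ps$values[ok])))
})

test_that("eigenvalues are invariant under axis relabeling", {
  g <- grid_from_bbox(rbind(rep(-4, 3), rep(4, 3)), 0.5)
  ax <- grid_axes(g)
  phi <- outer(outer((ax$x * 1e-3)^2 + 2e-3 * ax$x * 1e-3,
                     -0.5 * (ax$y * 1e-3)^2, "+"),
               3 * (ax$z * 1e-3)^2, "+")
  e1 <- hessian_primary_eigenvalue(voxel_grid(phi, g$origin, g$spacing))
  e2 <- hessian_primary_eigenvalue(voxel_grid(aperm(phi, c(3, 1, 2)),
                                              g$origin, g$spacing))
  expect_equal(aperm(e1$values, c(3, 1, 2)), e2$values, tolerance = 1e-9)
})

test_that("VTA thresholding is monotone and respects exclusions", {
  ax <- grid_axes(eig_ps)
  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  excl <- voxel_grid(r2 <= 1, eig_ps$origin, eig_ps$spacing)
  vols <- vapply(c(13.3, 26.6, 53.2, 1e6), function(thr)
    threshold_vta(eig_ps, vta_config(threshold_V_cm2 = thr,
                                     spacing_mm = 0.2), excl)$volume_mm3,
    numeric(1))
  expect_true(all(diff(vols) < 0))          # non-increasing in threshold
  expect_lt(vols[4], 1)                     # threshold -> inf: volume -> 0
  # non-decreasing in current: scaling phi scales lambda1 linearly
  eig2 <- eig_ps; eig2$values <- eig_ps$values * 2
  v1 <- threshold_vta(eig_ps, vta_config(spacing_mm = 0.2), excl)$volume_mm3
  v2 <- threshold_vta(eig2, vta_config(spacing_mm = 0.2), excl)$volume_mm3
  expect_gt(v2, v1)
  # zero field -> empty VTA
  z <- eig_ps; z$values[] <- 0
  expect_equal(threshold_vta(z, vta_config(spacing_mm = 0.2))$volume_mm3, 0)
  # VTA disjoint from the exclusion region
  v <- threshold_vta(eig_ps, vta_config(spacing_mm = 0.2), excl)
  expect_false(any(v$mask$values & excl$values))
  # lattice mismatch is an error
  bad <- voxel_grid(excl$values, excl$origin + 1, excl$spacing)
  expect_error(threshold_vta(eig_ps, vta_config(spacing_mm = 0.2), bad),
               "lattice")
})

test_that("point-source VTA volume matches 2I/(3 sigma T) at 0.2 mm", {
  ax <- grid_axes(eig_ps)
  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  excl <- voxel_grid(r2 <= 1, eig_ps$origin, eig_ps$spacing)
  v <- threshold_vta(eig_ps, vta_config(spacing_mm = 0.2), excl)
  vol <- v$volume_mm3 + 4 / 3 * pi * 1^3    # analytic add-back of exclusion
  exact <- point_source_vta_mm3(5.5e-3, 0.12, 26.6e4)
  expect_lt(abs(vol - exact) / exact, 0.10)
  # predicted activation radius (2k/T)^(1/3) = 3.015 mm
  r_t <- (2 * k_ps / 26.6e4)^(1 / 3) * 1e3
  expect_equal(r_t, 3.015, tolerance = 1e-3)
  on <- which(v$mask$values)
  expect_lt(sqrt(max(r2[on])), r_t * 1.05)
})
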