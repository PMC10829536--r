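# One moderate homogeneous solve is shared by several assertions below.
mod_h <- homog_sphere_model(half = 24, h = 0.6, a = 1.2, sigma = 0.12)
fld_h <- solve_potential(mod_h, current = 5.5e-3, active_id = 1L,
                         sink = sink_spec("shell", radius = 23))

test_that("analytic_point_source evaluates the closed form", {
  expect_equal(analytic_point_source(5.5e-3, 0.12, 3), 1.2158, tolerance = 1e-4)
  # 1/sigma and 1/r scalings
  expect_equal(analytic_point_source(5.5e-3, 0.24, 3),
               analytic_point_source(5.5e-3, 0.12, 3) / 2)
  expect_equal(analytic_point_source(5.5e-3, 0.12, 6),
               analytic_point_source(5.5e-3, 0.12, 3) / 2)
  expect_lt(analytic_point_source(5.5e-3, 0.12, 1e6), 1e-5)
  expect_error(analytic_point_source(5.5e-3, 0.12, 0), "r > 0")
  expect_error(analytic_point_source(5.5e-3, -1, 3), "sigma")
})

test_that("solver matches the grounded-shell closed form off the source", {
  sig <- 0.12; I <- 5.5e-3; Rout <- 23
  set.seed(2)
  dirs <- matrix(rnorm(3 * 120), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (r in c(3, 5, 8)) {
    phi <- mean(interp_trilinear(fld_h$grid, dirs * r))
    expect_lt(abs(phi - bounded_point_source(I, sig, r, Rout)) /
                analytic_point_source(I, sig, r), 0.02)
  }
})

test_that("discrete maximum principle and sink hold", {
  v <- fld_h$grid$values
  expect_equal(min(v, na.rm = TRUE), 0)
  act <- label_mask(mod_h, "ActiveContact")
  expect_equal(max(v, na.rm = TRUE), max(v[act]))
  expect_true(all(is.finite(v[sigma_grid(mod_h) > 0])))
})

test_that("doubling the injected current exactly doubles the potential", {
  f2 <- solve_potential(mod_h, current = 11e-3, active_id = 1L,
                        sink = sink_spec("shell", radius = 23),
                        x0 = fld_h$phi_unit)
  expect_equal(f2$grid$values, 2 * fld_h$grid$values, tolerance = 1e-7)
  expect_equal(f2$impedance, fld_h$impedance, tolerance = 1e-7)
})

test_that("current is conserved through any closed surface around the contact", {
  sg <- sigma_grid(mod_h)
  # boxes must stay inside the grounded shell (radius 23 mm)
  for (half_box in c(4, 8, 12)) {
    reg <- box_mask(mod_h$labels, rep(-half_box, 3), rep(half_box, 3))
    I <- dbsvta:::cpp_region_flux(sg, fld_h$grid$values,
                                  array(as.integer(reg), dim = dim(reg)),
                                  mod_h$labels$spacing * 1e-3)
    expect_lt(abs(I - 5.5e-3) / 5.5e-3, 0.005)
  }
})

test_that("solution is invariant under relabeling tissues with equal sigma", {
  m2 <- mod_h
  lv <- m2$labels$values
  lv[lv == TISSUE_CODES[["BrainGreyMatter"]]] <- TISSUE_CODES[["Ventricle"]]
  m2$labels$values <- lv
  m2$conductivity <- c(Ventricle = 0.12, ActiveContact = 4e6)
  f2 <- solve_potential(m2, current = 5.5e-3, active_id = 1L,
                        sink = sink_spec("shell", radius = 23),
                        x0 = fld_h$phi_unit)
  expect_equal(f2$grid$values, fld_h$grid$values, tolerance = 1e-7)
})

test_that("impedance follows the spreading-resistance scaling laws", {
  expect_gt(compute_impedance(fld_h), 0)
  m2 <- mod_h
  m2$conductivity <- c(BrainGreyMatter = 0.24, ActiveContact = 4e6)
  f2 <- solve_potential(m2, current = 5.5e-3, active_id = 1L,
                        sink = sink_spec("shell", radius = 23))
  expect_equal(f2$impedance, fld_h$impedance / 2, tolerance = 1e-6)
  f0 <- fld_h; f0$current <- 0
  expect_error(compute_impedance(f0), "zero")
})

test_that("reciprocity: exchanging source and sink preserves impedance", {
  m <- tiny_gm_model()
  f1 <- solve_potential(m, 1e-3, 1L)
  sg <- sigma_grid(m)
  act <- label_mask(m, "ActiveContact")
  bot <- array(FALSE, m$labels$dim); bot[, , 1] <- TRUE
  bot <- bot & sg > 0
  # drive the bottom face at 1 V with the contact grounded
  dirich <- array(0L, m$labels$dim); dirich[act | bot] <- 1L
  dvals <- array(0, m$labels$dim); dvals[bot] <- 1
  r <- dbsvta:::cpp_solve_fv(sg, dirich, dvals, m$labels$spacing * 1e-3,
                             1e-8, 50000L, NULL)
  I_swap <- dbsvta:::cpp_region_flux(sg, r$phi,
                                     array(as.integer(bot), dim = dim(bot)),
                                     m$labels$spacing * 1e-3)
  expect_equal(1 / I_swap, f1$impedance, tolerance = 1e-6)
})

test_that("an insulated contact is reported as a singular system", {
  m <- tiny_gm_model()
  lv <- m$labels$values
  shell <- ellipsoid_mask(m$labels, c(0, 0, 0), rep(4, 3)) &
    !ellipsoid_mask(m$labels, c(0, 0, 0), rep(2.2, 3))
  lv[shell] <- TISSUE_CODES[["LeadShaft"]]
  m$labels$values <- lv
  m$conductivity <- c(m$conductivity, LeadShaft = 0)
  expect_error(solve_potential(m, 1e-3, 1L), "no conductive path")
})

test_that("no-op refinement reproduces the coarse field", {
  f2 <- refine_local(mod_h, fld_h, box_center = c(0, 0, 0), box_size = 12,
                     fine_spacing = 0.6)
  cmp <- resample_trilinear(
    voxel_grid(dbsvta:::fill_na_neighbors(fld_h$grid$values, 8),
               fld_h$grid$origin, fld_h$grid$spacing), f2$grid)
  ok <- !is.na(f2$grid$values) & !is.na(cmp$values) & cmp$values > 1e-3
  expect_lt(max(abs(f2$grid$values[ok] - cmp$values[ok]) /
                  pmax(cmp$values[ok], 1e-6)), 0.02)
})

test_that("refining an analytically bounded region matches the closed form", {
  # manufactured coarse field: exact 1/r potential, homogeneous medium,
  # no contact inside the box -> pure boundary-value re-solve
  sig <- 0.12; I <- 5.5e-3
  src <- point_source_grid(I, sig, half_mm = 12, h_mm = 0.6)
  g <- src
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], g$dim)
  model <- tissue_model(voxel_grid(lab, g$origin, g$spacing),
                        c(BrainGreyMatter = sig))
  coarse <- structure(list(grid = src, current = I, active_id = NA_integer_,
                           impedance = NA_real_, contact_potential = NA_real_,
                           iterations = 0L, residual = 0, model = model,
                           phi_unit = NULL),
                      class = "potential_field")
  # the box must not contain the source singularity: offset it laterally
  fine <- refine_local(model, coarse, box_center = c(5.5, 0, 0),
                       box_size = 6, fine_spacing = 0.25)
  pts <- rbind(c(3.5, 0, 0), c(5, 1, -1), c(6, -1.5, 1.5), c(8, 0.5, 0))
  for (i in seq_len(nrow(pts))) {
    r <- sqrt(sum(pts[i, ]^2))
    phi <- interp_trilinear(fine$grid, pts[i, , drop = FALSE])
    expect_lt(abs(phi - analytic_point_source(I, sig, r)) /
                analytic_point_source(I, sig, r), 0.02)
  }
})

test_that("fine and coarse solutions agree on the refinement box boundary", {
  fine <- refine_local(mod_h, fld_h, box_center = c(0, 0, 0), box_size = 12,
                       fine_spacing = 0.3)
  # one fine-voxel shell just inside the box boundary
  n <- fine$grid$dim
  shell <- array(FALSE, n)
  shell[c(2, n[1] - 1), , ] <- TRUE
  shell[, c(2, n[2] - 1), ] <- TRUE
  shell[, , c(2, n[3] - 1)] <- TRUE
  cmp <- resample_trilinear(
    voxel_grid(dbsvta:::fill_na_neighbors(fld_h$grid$values, 8),
               fld_h$grid$origin, fld_h$grid$spacing), fine$grid)
  ok <- shell & !is.na(fine$grid$values) & !is.na(cmp$values)
  rel <- abs(fine$grid$values[ok] - cmp$values[ok]) / max(cmp$values[ok])
  expect_lt(max(rel), 0.05)
})
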