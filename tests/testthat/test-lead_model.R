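test_that("fit_trajectory recovers an axis-aligned voxel column", {
  g <- grid_from_bbox(rbind(c(-2, -2, 0), c(2, 2, 29)), 1)
  m <- array(FALSE, g$dim)
  m[3, 3, ] <- TRUE
  tr <- fit_trajectory(voxel_grid(m, g$origin, g$spacing))
  expect_equal(abs(tr$direction), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(tr$tip, c(0, 0, 0), tolerance = 1e-9)   # low-z end
  expect_gt(tr$direction[3], 0)                        # points proximally
})

test_that("fit_trajectory rejects empty and non-elongated masks", {
  g <- grid_from_bbox(rbind(rep(-6, 3), rep(6, 3)), 1)
  expect_error(fit_trajectory(voxel_grid(array(FALSE, g$dim),
                                         g$origin, g$spacing)),
               "empty")
  blob <- ellipsoid_mask(g, c(0, 0, 0), rep(5, 3))
  expect_error(fit_trajectory(voxel_grid(blob, g$origin, g$spacing)),
               "anisotropy")
})

test_that("artifact round-trip recovers an oblique trajectory", {
  d <- c(0.30, 0.20, 0.93); d <- d / sqrt(sum(d^2))
  tr <- trajectory(c(-2, 1, -20), d)
  g <- grid_from_bbox(rbind(rep(-30, 3), rep(30, 3)), 1)
  # noiseless: < 1 degree
  a0 <- make_artifact_volume(tr, g, length = 40, noise_sd = 0)
  f0 <- fit_trajectory(artifact_mask(a0))
  expect_lt(angle_deg(f0$direction, d), 1)
  expect_gt(sum(f0$direction * d), 0)
  expect_lt(sqrt(sum((f0$tip - tr$tip)^2)), 1.5)
  # noisy: < 2 degrees
  an <- make_artifact_volume(tr, g, length = 40, noise_sd = 60, seed = 3)
  fn <- fit_trajectory(artifact_mask(an))
  expect_lt(angle_deg(fn$direction, d), 2)
})

test_that("fit_trajectory is equivariant under 90-degree rotation", {
  d <- c(0.25, 0.1, 0.96); d <- d / sqrt(sum(d^2))
  g <- grid_from_bbox(rbind(rep(-20, 3), rep(20, 3)), 1)
  a <- make_artifact_volume(trajectory(c(0, 0, -15), d), g, length = 30,
                            noise_sd = 0)
  f1 <- fit_trajectory(artifact_mask(a))
  # rotate the volume +90 degrees about z: (x,y,z) -> (-y,x,z)
  rot <- aperm(a$values, c(2, 1, 3))
  rot <- rot[dim(rot)[1]:1, , ]
  f2 <- fit_trajectory(artifact_mask(voxel_grid(rot, g$origin, g$spacing)))
  d_rot <- c(-d[2], d[1], d[3])
  expect_lt(angle_deg(f2$direction, d_rot), 1)
})

test_that("build_lead places 2 rings + 6 segments with the closed-form span", {
  geom <- build_lead(trajectory(c(0, 0, 0), c(0, 0, 1)), lead_spec())
  types <- vapply(geom$contacts, `[[`, character(1), "type")
  expect_equal(sum(types == "ring"), 2)
  expect_equal(sum(types == "segment"), 6)
  expect_equal(length(geom$contacts), 8)
  expect_equal(geom$array_span, 4 * 1.5 + 3 * 1.5)     # 10.5 mm
  s1 <- vapply(geom$contacts, `[[`, numeric(1), "s1")
  s0 <- vapply(geom$contacts, `[[`, numeric(1), "s0")
  expect_equal(max(s1) - min(s0), 10.5)
  expect_equal(min(s0), 0)                             # distal ring at tip
  ids <- vapply(geom$contacts, `[[`, integer(1), "id")
  expect_equal(ids, 1:8)
  expect_equal(geom$contacts[[1]]$type, "ring")
  # right lead: ids 9-16, distal ring is contact 9
  geomR <- build_lead(trajectory(c(0, 0, 0), c(0, 0, 1)), lead_spec(),
                      id_offset = 8L)
  idsR <- vapply(geomR$contacts, `[[`, integer(1), "id")
  expect_equal(idsR, 9:16)
  expect_equal(geomR$contacts[[1]]$id, 9L)
  expect_equal(geomR$contacts[[1]]$type, "ring")
  expect_error(lead_spec(seg_arc = 100, seg_gap = 30), "360")
})

test_that("rasterized lead carries the published conductivities", {
  g <- grid_from_bbox(rbind(rep(-8, 3), c(8, 8, 30)), 0.5)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], g$dim)
  model0 <- tissue_model(voxel_grid(lab, g$origin, g$spacing),
                         c(BrainGreyMatter = 0.12))
  geom <- build_lead(trajectory(c(0, 0, -6), c(0.1, 0.05, 0.99)),
                     lead_spec(shaft_length = 30))
  model <- rasterize_lead(geom, model0, active_id = 1L)
  sg <- sigma_grid(model)
  expect_true(all(sg[label_mask(model, "LeadContact")] == 4e6))
  expect_true(all(sg[label_mask(model, "LeadShaft")] == 0))
  expect_true(any(label_mask(model, "ActiveContact")))
  # tissue labels away from the lead untouched
  far <- model$labels$values[1, 1, 1]
  expect_equal(far, TISSUE_CODES[["BrainGreyMatter"]])
  # idempotent
  model2 <- rasterize_lead(geom, model, active_id = 1L)
  expect_identical(model$labels$values, model2$labels$values)
  expect_error(rasterize_lead(geom, model0, active_id = 99L), "not in geometry")
})

test_that("segment contacts are pairwise disjoint on a fine grid", {
  g <- grid_from_bbox(rbind(rep(-3, 3), c(3, 3, 14)), 0.2)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], g$dim)
  model0 <- tissue_model(voxel_grid(lab, g$origin, g$spacing),
                         c(BrainGreyMatter = 0.12))
  geom <- build_lead(trajectory(c(0, 0, -1), c(0, 0, 1)),
                     lead_spec(shaft_length = 13))
  # rasterize each contact as active in turn; actives must not overlap
  masks <- lapply(c(2L, 3L, 4L), function(id) {
    m <- rasterize_lead(geom, model0, active_id = id)
    label_mask(m, "ActiveContact")
  })
  expect_false(any(masks[[1]] & masks[[2]]))
  expect_false(any(masks[[1]] & masks[[3]]))
  expect_false(any(masks[[2]] & masks[[3]]))
  expect_true(all(vapply(masks, any, logical(1))))
})

test_that("shaft voxel volume approximates the analytic cylinder", {
  h <- 0.2
  g <- grid_from_bbox(rbind(rep(-4, 3), c(4, 4, 44)), h)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], g$dim)
  model0 <- tissue_model(voxel_grid(lab, g$origin, g$spacing),
                         c(BrainGreyMatter = 0.12))
  L <- 40
  # generic alignment: a perfectly lattice-aligned centered axis is the
  # worst case for the staircase cross-section
  geom <- build_lead(trajectory(c(0.07, 0.03, 0), c(0.05, 0.03, 0.998)),
                     lead_spec(shaft_length = L))
  model <- rasterize_lead(geom, model0, active_id = 1L)
  lead_vox <- label_mask(model, "LeadShaft") |
    label_mask(model, "LeadContact") | label_mask(model, "ActiveContact")
  vol <- sum(lead_vox) * h^3
  exact <- pi * 0.635^2 * L
  expect_lt(abs(vol - exact) / exact, 0.10)
})
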