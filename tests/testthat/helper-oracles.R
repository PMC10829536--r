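# Shared fixtures and independent oracles, all built in code.

# Homogeneous medium with a spherical active contact at the origin and a
# grounded spherical shell (radius sink_r) as the distant return.
homog_sphere_model <- function(half = 24, h = 0.6, a = 1.2, sigma = 0.12) {
  g <- grid_from_bbox(rbind(rep(-half, 3), rep(half, 3)), h)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], dim = g$dim)
  act <- ellipsoid_mask(g, c(0, 0, 0), rep(a, 3))
  if (!any(act)) {  # sub-voxel contact: use the center voxel
    ij <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
    act[ij[1], ij[2], ij[3]] <- TRUE
  }
  lab[act] <- TISSUE_CODES[["ActiveContact"]]
  tissue_model(voxel_grid(lab, g$origin, g$spacing),
               c(BrainGreyMatter = sigma, ActiveContact = 4e6))
}

# Exact potential in the grounded-shell configuration: a centered source
# of current I in conductivity sigma inside a grounded sphere of radius
# R_out behaves as I/(4 pi sigma) * (1/r - 1/R_out)  [r, R_out in mm].
bounded_point_source <- function(current, sigma, r_mm, R_out_mm) {
  current / (4 * pi * sigma) * (1 / (r_mm * 1e-3) - 1 / (R_out_mm * 1e-3))
}

# Analytic point-source potential field phi = k/r sampled on a cube grid
# (k = I / (4 pi sigma), r in meters). NA at the singular center voxel.
point_source_grid <- function(current, sigma, half_mm = 10, h_mm = 0.2) {
  g <- grid_from_bbox(rbind(rep(-half_mm, 3), rep(half_mm, 3)), h_mm)
  ax <- grid_axes(g)
  r2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  k <- current / (4 * pi * sigma)
  phi <- k / (sqrt(r2) * 1e-3)
  phi[r2 == 0] <- NA
  voxel_grid(phi, g$origin, g$spacing)
}

# Closed-form VTA of a point source: lambda1 = 2k/r^3 >= T inside radius
# (2k/T)^(1/3), so the volume is 2I/(3 sigma T).
point_source_vta_mm3 <- function(current, sigma, threshold_V_m2) {
  2 * current / (3 * sigma * threshold_V_m2) * 1e9
}

# Overlap lens of two equal spheres of radius r with centers d apart.
sphere_lens_mm3 <- function(r, d) {
  if (d >= 2 * r) return(0)
  pi * (4 * r + d) * (2 * r - d)^2 / 12
}

angle_deg <- function(u, v) {
  c <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, c)) * 180 / pi
}

# A small solvable heterogeneous phantom for fast calibration tests:
# all gray matter, cube domain, bottom-face sink, cube contact.
tiny_gm_model <- function(half = 15, h = 1, sigma_gm = 0.12) {
  g <- grid_from_bbox(rbind(rep(-half, 3), rep(half, 3)), h)
  lab <- array(TISSUE_CODES[["BrainGreyMatter"]], dim = g$dim)
  act <- ellipsoid_mask(g, c(0, 0, 0), rep(1.4, 3))
  lab[act] <- TISSUE_CODES[["ActiveContact"]]
  tissue_model(voxel_grid(lab, g$origin, g$spacing),
               c(BrainGreyMatter = sigma_gm, ActiveContact = 4e6))
}
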