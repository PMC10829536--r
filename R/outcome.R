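#' VTA / target-nucleus overlap
#'
#' The target mask is resampled onto the VTA lattice by nearest neighbour
#' (preserving binarity); the overlap is the AND-count times the fine
#' voxel volume, and the coverage percentage is taken against the target
#' volume measured on its own native grid (avoiding double discretization
#' error).
#'
#' @param vta a \code{vta_result}
#' @param target binary \code{voxel_grid} in the same world frame
#' @return list with \code{overlap_mm3} and \code{percent_of_target}
#' @export
overlap_volume <- function(vta, target) {
  tvol <- mask_volume(target)
  if (tvol == 0) stop("target mask is empty")
  vg <- vta$mask
  t_lo <- target$origin; t_hi <- upper_corner(target)
  v_lo <- vg$origin; v_hi <- upper_corner(vg)
  if (any(t_lo > v_hi) || any(t_hi < v_lo)) {
    warning("target and VTA world extents are disjoint; overlap is 0")
    return(list(overlap_mm3 = 0, percent_of_target = 0))
  }
  t_on_v <- resample_nearest(target, vg, outside = 0L)
  ov <- sum(vg$values & t_on_v$values != 0) * prod(vg$spacing)
  list(overlap_mm3 = ov, percent_of_target = 100 * ov / tvol)
}

#' Percent improvement of a pre/post clinical score
#'
#' \code{100 * (pre - post) / pre}, full precision (round for reporting).
#'
#' @param pre,post scores in [0, 40]; \code{pre} must be > 0
#' @return percent improvement (numeric, not rounded)
#' @export
percent_improvement <- function(pre, post) {
  for (s in c(pre, post))
    if (is.na(s) || s != round(s) || s < 0 || s > 40)
      stop("scores must be integers in [0, 40]")
  if (pre == 0) stop("pre-op score must be > 0")
  100 * (pre - post) / pre
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for \code{\link{run_pipeline}}.
#' Defaults reproduce the synthetic study world: patient fixtures, the
#' default phantom, the directional lead spec, a ~509 mm^3 nucleus placed
#' medially to the active contact at a patient/side-specific distance, and
#' the printed solver/VTA settings.
#'
#' @param patient 1 or 2
#' @param side "left" or "right"
#' @param fast if TRUE use the 0.2 mm VTA grid and 0.4 mm refinement
#'   (documented fast mode) instead of 0.1 / 0.25 mm
#' @param out_dir optional output directory for artifacts (CSV + JSON)
#' @param seed RNG seed (pseudo-CT noise)
#' @param phantom_spacing coarse grid spacing (mm)
#' @param nucleus_offset_mm medial distance from the active-contact
#'   centroid to the nucleus center; default chosen per patient/side
#' @param nucleus_semi_axes nucleus semi-axes (mm)
#' @param calibrate run the impedance calibration (default TRUE)
#' @param artifact_noise_sd pseudo-CT noise SD (intensity units)
#' @return a \code{pipeline_config}
#' @export
pipeline_config <- function(patient = 1, side = c("left", "right"),
                            fast = FALSE, out_dir = NULL, seed = 20210901L,
                            phantom_spacing = 1.5,
                            nucleus_offset_mm = NULL,
                            nucleus_semi_axes = c(4.9, 6.2, 4.0),
                            calibrate = TRUE, artifact_noise_sd = 50) {
  side <- match.arg(side)
  if (is.null(nucleus_offset_mm)) {
    tab <- list(`1` = c(left = 7.3, right = 7.0),
                `2` = c(left = 7.6, right = 7.8))
    nucleus_offset_mm <- tab[[as.character(patient)]][[side]]
  }
  structure(list(patient = patient, side = side, fast = fast,
                 out_dir = out_dir, seed = as.integer(seed),
                 phantom_spacing = phantom_spacing,
                 nucleus_offset_mm = nucleus_offset_mm,
                 nucleus_semi_axes = nucleus_semi_axes,
                 calibrate = calibrate,
                 artifact_noise_sd = artifact_noise_sd,
                 refine_box_mm = 22,
                 refine_spacing_mm = if (fast) 0.4 else 0.25,
                 vta = vta_config(spacing_mm = if (fast) 0.2 else 0.1)),
            class = "pipeline_config")
}

#' Run the full per-patient-side modeling pipeline
#'
#' phantom -> pseudo-CT artifact -> trajectory fit -> lead build/rasterize
#' -> coarse solve -> gray-matter impedance calibration -> local refined
#' solve -> Hessian eigenvalue VTA -> nucleus overlap -> report row.
#' Deterministic for a fixed config and seed.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param verbose print stage progress
#' @return an \code{overlap_report}: list with \code{report} (one-row
#'   data.frame matching the clinical table schema), plus the intermediate
#'   objects (\code{model}, \code{calibration}, \code{field_coarse},
#'   \code{field_fine}, \code{vta}, \code{nucleus}, \code{geom})
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  rec <- patient_fixture(config$patient)
  active_id <- rec$active_contact[[config$side]]
  target_R <- rec$impedance_ohm[[config$side]]
  id_offset <- if (config$side == "left") 0L else 8L

  say("[1/7] building head phantom (patient %d, %.2g mm grid)",
      config$patient, config$phantom_spacing)
  spec <- default_phantom_spec(config$patient, spacing = config$phantom_spacing)
  model0 <- stage("phantom", build_head_phantom(spec))

  say("[2/7] pseudo-CT artifact + trajectory fit")
  traj_true <- default_trajectory(config$side)
  art <- stage("artifact", make_artifact_volume(
    traj_true, model0$labels, lead_radius = 0.635, length = 40,
    noise_sd = config$artifact_noise_sd, seed = config$seed))
  traj <- stage("fit_trajectory", fit_trajectory(artifact_mask(art)))

  say("[3/7] lead geometry + rasterization (active contact %d)", active_id)
  geom <- stage("build_lead", build_lead(traj, lead_spec(),
                                         id_offset = id_offset))
  model <- stage("rasterize_lead", rasterize_lead(geom, model0, active_id))

  say("[4/7] impedance calibration to %.0f ohm", target_R)
  if (config$calibrate) {
    cal <- stage("calibrate", calibrate_gm_conductivity(
      model, current = rec$current_A, target_R = target_R,
      active_id = active_id))
    model <- cal$model
    coarse <- cal$field
  } else {
    cal <- NULL
    coarse <- stage("solve", solve_potential(model, current = rec$current_A,
                                             active_id = active_id))
  }
  say("      achieved %.1f ohm, sigma_GM = %.4f S/m",
      compute_impedance(coarse),
      model$conductivity[["BrainGreyMatter"]])

  say("[5/7] local refinement (%.2g mm box at %.2g mm)",
      config$refine_box_mm, config$refine_spacing_mm)
  box_ctr <- contact_centroid(geom, active_id)
  fine <- stage("refine", refine_local(
    model, coarse, box_center = box_ctr, box_size = config$refine_box_mm,
    fine_spacing = config$refine_spacing_mm, geom = geom,
    match_current = TRUE))

  say("[6/7] VTA (%.2g mm grid, threshold %.1f V/cm^2)",
      config$vta$spacing_mm, config$vta$threshold_V_cm2)
  phi_f <- stage("sample_grid", sample_grid(fine, config$vta,
                                            center = box_ctr))
  eig <- stage("hessian", hessian_primary_eigenvalue(phi_f))
  margin <- config$vta$shell_voxels * config$vta$spacing_mm +
    config$refine_spacing_mm
  excl <- lead_exclusion_mask(geom, phi_f, margin)
  vta <- stage("threshold_vta", threshold_vta(eig, config$vta, excl))

  say("[7/7] nucleus overlap + outcome")
  ctr <- contact_centroid(geom, active_id)
  medial <- if (config$side == "left") c(1, 0, 0) else c(-1, 0, 0)
  nuc_center <- ctr + config$nucleus_offset_mm * medial
  nucleus <- stage("nucleus", build_target_nucleus(
    nuc_center, config$nucleus_semi_axes, phi_f))
  ov <- stage("overlap", overlap_volume(vta, nucleus))
  impr <- percent_improvement(rec$ybocs_pre, rec$ybocs_post)

  report <- data.frame(
    patient = config$patient,
    side = config$side,
    active_contact = active_id,
    current_mA = rec$current_A * 1e3,
    target_impedance_ohm = target_R,
    achieved_impedance_ohm = compute_impedance(coarse),
    sigma_gm_S_per_m = model$conductivity[["BrainGreyMatter"]],
    vta_mm3 = vta$volume_mm3,
    overlap_mm3 = ov$overlap_mm3,
    percent_of_target = ov$percent_of_target,
    ybocs_pre = rec$ybocs_pre,
    ybocs_post = rec$ybocs_post,
    percent_improvement = round(impr),
    stringsAsFactors = FALSE)

  out <- structure(list(report = report, record = rec, config = config,
                        model = model, calibration = cal,
                        field_coarse = coarse, field_fine = fine,
                        vta = vta, nucleus = nucleus, geom = geom,
                        percent_improvement_raw = impr),
                   class = "overlap_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk (CSV row + JSON)
#' @param x an \code{overlap_report}
#' @param dir output directory (created if needed)
#' @return invisibly, the CSV path
#' @export
write_report <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tag <- sprintf("patient%d_%s", x$config$patient, x$config$side)
  csv <- file.path(dir, paste0(tag, "_report.csv"))
  utils::write.csv(x$report, csv, row.names = FALSE)
  js <- c(as.list(x$report),
          list(percent_improvement_raw = x$percent_improvement_raw,
               threshold_V_m2 = x$vta$threshold_V_m2))
  jsonlite::write_json(js, file.path(dir, paste0(tag, "_report.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
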