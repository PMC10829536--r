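#' Tissue labels used by the head phantoms and lead rasterization
#'
#' Integer codes for the label grid. Codes 1-6 are the six conductive
#' tissue classes of the volume conductor model; 90-92 are reserved for
#' the lead (insulating shaft, passive metal contacts, active contact).
#' 0 marks exterior (air), which carries no unknowns.
#' @export
TISSUE_CODES <- c(
  Exterior            = 0L,
  AverageBody         = 1L,
  Skull               = 2L,
  BrainGreyMatter     = 3L,
  BrainWhiteMatter    = 4L,
  CerebroSpinalFluid  = 5L,
  Ventricle           = 6L,
  LeadShaft           = 90L,
  LeadContact         = 91L,
  ActiveContact       = 92L
)

#' Tissue conductivity table (S/m at low frequency)
#'
#' Literature DC conductivities for the six head compartments. Gray matter
#' differs per patient model (0.120 vs 0.090 S/m); all other tissues are
#' shared. Gray matter is the parameter later adjusted by impedance
#' calibration.
#'
#' @param patient 1 or 2
#' @return named numeric vector, label name -> sigma (S/m); includes the
#'   insulating \code{Exterior} entry (0 S/m)
#' @export
conductivity_table <- function(patient = 1) {
  if (!patient %in% c(1, 2)) stop("unknown patient id: ", patient)
  c(Exterior           = 0,
    AverageBody        = 0.400,
    Skull              = 0.300,
    BrainGreyMatter    = if (patient == 1) 0.120 else 0.090,
    BrainWhiteMatter   = 0.058,
    CerebroSpinalFluid = 1.800,
    Ventricle          = 0.300)
}

#' Compartment descriptor for a phantom
#' @param name compartment name (for diagnostics)
#' @param tissue tissue label name (must have a conductivity entry)
#' @param shape "ellipsoid" or "box"
#' @param center,semi_axes ellipsoid parameters (mm)
#' @param lower,upper box corners (mm)
#' @param priority painting priority; compartments are painted in list
#'   order (outermost first), equal priorities must not overlap
#' @return a \code{compartment} list
#' @export
compartment <- function(name, tissue, shape = c("ellipsoid", "box"),
                        center = NULL, semi_axes = NULL,
                        lower = NULL, upper = NULL, priority = NA_real_) {
  shape <- match.arg(shape)
  structure(list(name = name, tissue = tissue, shape = shape,
                 center = center, semi_axes = semi_axes,
                 lower = lower, upper = upper, priority = priority),
            class = "compartment")
}

#' Head phantom specification
#'
#' Describes a nested multi-compartment head: an "average body" slab below
#' the head carries the distant current return, and nested ellipsoids stand
#' in for scalp, skull, CSF, gray matter, white matter, a deep gray nucleus
#' region, and ventricles. Compartments are listed outermost first; each
#' voxel takes the label of the innermost (last-listed) compartment
#' containing its center.
#'
#' @param compartments list of \code{compartment}s, outermost first
#' @param conductivity named label -> sigma table (S/m); must cover the six
#'   head tissue names
#' @param spacing grid spacing (mm)
#' @param bbox 2 x 3 world bounding box (mm)
#' @param seed noise seed carried to downstream pseudo-CT generation
#' @return a \code{phantom_spec}
#' @export
phantom_spec <- function(compartments, conductivity, spacing = 1.5,
                         bbox = rbind(c(-70, -70, -110), c(70, 70, 70)),
                         seed = 20210901L) {
  need <- c("AverageBody", "Skull", "BrainGreyMatter", "BrainWhiteMatter",
            "CerebroSpinalFluid", "Ventricle")
  miss <- setdiff(need, names(conductivity))
  if (length(miss))
    stop("conductivity table missing tissue(s): ", paste(miss, collapse = ", "))
  if (any(conductivity < 0)) stop("conductivities must be >= 0")
  bbox <- matrix(as.numeric(bbox), nrow = 2)
  structure(list(compartments = compartments, conductivity = conductivity,
                 spacing = as.numeric(spacing), bbox = bbox,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default head phantom for a patient model
#'
#' The stated default world: ~140 x 140 x 180 mm at 1.5 mm spacing, nested
#' ellipsoidal compartments for all six tissue classes, a deep-gray
#' ellipsoid (basal-ganglia stand-in) around the lead target so the active
#' contact sits in gray matter, and a body slab at the bottom carrying the
#' current sink.
#'
#' @param patient 1 or 2 (selects the gray-matter conductivity)
#' @param spacing grid spacing in mm (default 1.5)
#' @return a \code{phantom_spec}
#' @export
default_phantom_spec <- function(patient = 1, spacing = 1.5) {
  comps <- list(
    compartment("body_slab", "AverageBody", "box",
                lower = c(-70, -70, -110), upper = c(70, 70, -75)),
    compartment("scalp", "AverageBody", center = c(0, 0, -10),
                semi_axes = c(68, 68, 80)),
    compartment("skull", "Skull", center = c(0, 0, -10),
                semi_axes = c(64, 64, 76)),
    compartment("csf", "CerebroSpinalFluid", center = c(0, 0, -10),
                semi_axes = c(60, 60, 72)),
    compartment("gray_matter", "BrainGreyMatter", center = c(0, 0, -10),
                semi_axes = c(57, 57, 69)),
    compartment("white_matter", "BrainWhiteMatter", center = c(0, 0, -12),
                semi_axes = c(48, 48, 58)),
    compartment("deep_gray", "BrainGreyMatter", center = c(0, 8, -18),
                semi_axes = c(22, 26, 20)),
    compartment("ventricles", "Ventricle", center = c(0, 6, 6),
                semi_axes = c(8, 12, 10))
  )
  phantom_spec(comps, conductivity_table(patient), spacing = spacing)
}

#' Voxelize a phantom specification into a tissue model
#'
#' Paints compartments in list order (outermost first), so each voxel ends
#' up labeled by the innermost compartment containing its center.
#'
#' @param spec a \code{phantom_spec}
#' @return a \code{tissue_model}
#' @export
build_head_phantom <- function(spec) {
  g <- grid_from_bbox(spec$bbox, spec$spacing, value = TISSUE_CODES[["Exterior"]])
  labels <- array(TISSUE_CODES[["Exterior"]], dim = g$dim)
  masks <- vector("list", length(spec$compartments))
  for (ci in seq_along(spec$compartments)) {
    cp <- spec$compartments[[ci]]
    if (!cp$tissue %in% names(TISSUE_CODES))
      stop("unknown tissue label: ", cp$tissue)
    m <- if (cp$shape == "ellipsoid") {
      lo <- cp$center - cp$semi_axes
      hi <- cp$center + cp$semi_axes
      if (any(lo < spec$bbox[1, ] - spec$spacing) ||
          any(hi > spec$bbox[2, ] + spec$spacing))
        stop("compartment '", cp$name, "' extends outside the bounding box")
      ellipsoid_mask(g, cp$center, cp$semi_axes)
    } else {
      box_mask(g, cp$lower, cp$upper)
    }
    if (!any(m)) warning("compartment '", cp$name, "' is empty after voxelization")
    masks[[ci]] <- m
    labels[m] <- TISSUE_CODES[[cp$tissue]]
  }
  # compartments sharing an explicit priority must not overlap
  pr <- vapply(spec$compartments, function(cp) cp$priority, numeric(1))
  if (anyDuplicated(pr[!is.na(pr)])) {
    for (a in which(!is.na(pr))) for (b in which(!is.na(pr))) {
      if (a < b && pr[a] == pr[b] && any(masks[[a]] & masks[[b]]))
        stop("compartments '", spec$compartments[[a]]$name, "' and '",
             spec$compartments[[b]]$name,
             "' share a priority but overlap")
    }
  }
  tissue_model(voxel_grid(labels, g$origin, g$spacing), spec$conductivity)
}

#' Tissue model: label grid plus conductivity table
#'
#' @param labels a \code{voxel_grid} of integer tissue codes
#'   (see \code{\link{TISSUE_CODES}})
#' @param conductivity named label name -> sigma (S/m)
#' @return a \code{tissue_model}
#' @export
tissue_model <- function(labels, conductivity) {
  codes <- unique(as.vector(labels$values))
  known <- TISSUE_CODES[names(conductivity)]
  miss <- setdiff(codes, known)
  if (length(miss))
    stop("label code(s) without a conductivity entry: ",
         paste(miss, collapse = ", "))
  if (any(conductivity < 0)) stop("conductivities must be >= 0")
  structure(list(labels = labels, conductivity = conductivity),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("tissue_model\n")
  print(x$labels)
  tab <- table(factor(x$labels$values, levels = TISSUE_CODES,
                      labels = names(TISSUE_CODES)))
  tab <- tab[tab > 0]
  for (nm in names(tab))
    cat(sprintf("  %-20s %8d voxels  sigma = %s S/m\n", nm, tab[[nm]],
                format(x$conductivity[[nm]])))
  invisible(x)
}

#' Per-voxel conductivity grid (S/m) of a tissue model
#' @param model a \code{tissue_model}
#' @return numeric 3-D array matching the label grid
#' @export
sigma_grid <- function(model) {
  codes <- TISSUE_CODES[names(model$conductivity)]
  lut <- numeric(max(codes) + 1L)
  lut[codes + 1L] <- model$conductivity
  out <- lut[model$labels$values + 1L]
  dim(out) <- model$labels$dim
  out
}

#' Logical mask of voxels carrying a given label
#' @param model a \code{tissue_model}
#' @param label tissue label name
#' @return logical 3-D array
#' @export
label_mask <- function(model, label) {
  model$labels$values == TISSUE_CODES[[label]]
}

#' Synthetic target nucleus (NAcc stand-in)
#'
#' Binarizes an ellipsoid on the given lattice. Default proportions give a
#' nucleus of roughly 500 mm^3, the scale implied by published overlap
#' percentages for accumbens-sized targets.
#'
#' @param center nucleus center (mm)
#' @param semi_axes semi-axis lengths (mm)
#' @param grid lattice to rasterize on (a \code{voxel_grid})
#' @return binary \code{voxel_grid}
#' @export
build_target_nucleus <- function(center, semi_axes, grid) {
  m <- ellipsoid_mask(grid, center, semi_axes)
  if (!any(m)) stop("target nucleus mask is empty on this grid")
  voxel_grid(m, grid$origin, grid$spacing)
}

#' Pseudo-CT lead artifact volume
#'
#' Emulates the hyperdense blooming artifact a metal DBS lead leaves in CT:
#' high intensity within roughly a lead radius (plus half a voxel of blur)
#' of the lead axis, additive Gaussian noise elsewhere. Deterministic for a
#' fixed seed.
#'
#' @param trajectory a \code{\link{trajectory}} (tip + unit direction)
#' @param grid lattice to rasterize on
#' @param lead_radius lead radius (mm)
#' @param length artifact length along the axis from the tip (mm)
#' @param noise_sd additive Gaussian noise SD in intensity units
#' @param seed RNG seed
#' @param intensity peak artifact intensity (arbitrary CT-like units)
#' @return numeric \code{voxel_grid}
#' @export
make_artifact_volume <- function(trajectory, grid, lead_radius = 0.635,
                                 length = 40, noise_sd = 0, seed = 1L,
                                 intensity = 1000) {
  d2 <- dist2_to_segment(grid, trajectory$tip, trajectory$direction,
                         0, length)
  r_art <- lead_radius + 0.5 * max(grid$spacing)  # blooming/blur margin
  vals <- ifelse(d2 <= r_art^2, intensity, 0)
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(base::length(vals), 0, noise_sd)
  }
  dim(vals) <- grid$dim
  voxel_grid(vals, grid$origin, grid$spacing)
}

#' Threshold a pseudo-CT volume into a binary artifact mask
#' @param art numeric \code{voxel_grid}
#' @param threshold intensity threshold (default half the nominal peak)
#' @return binary \code{voxel_grid}
#' @export
artifact_mask <- function(art, threshold = 500) {
  voxel_grid(art$values > threshold, art$origin, art$spacing)
}

# squared distance from every voxel center to the axis segment
# tip + t*dir, t in [t0, t1]; dir must be unit length
dist2_to_segment <- function(g, tip, dir, t0, t1) {
  ax <- grid_axes(g)
  sx <- (ax$x - tip[1]) * dir[1]
  sy <- (ax$y - tip[2]) * dir[2]
  sz <- (ax$z - tip[3]) * dir[3]
  S <- outer(outer(sx, sy, "+"), sz, "+")
  vx2 <- (ax$x - tip[1])^2
  vy2 <- (ax$y - tip[2])^2
  vz2 <- (ax$z - tip[3])^2
  V2 <- outer(outer(vx2, vy2, "+"), vz2, "+")
  Tc <- pmin(pmax(S, t0), t1)
  pmax(V2 - 2 * Tc * S + Tc^2, 0)
}

#' Clinical patient fixtures
#'
#' Returns the published stimulation settings, measured impedances and
#' pre/post clinical scores for the two study patients: monopolar cathodic
#' stimulation on contact 1 (left lead) / 9 (right lead), 60 us pulses at
#' 160 Hz.
#'
#' @param id patient id, 1 or 2
#' @return a \code{patient_record}: list with \code{id},
#'   \code{active_contact} (left/right), \code{current_A},
#'   \code{pulse_width_us}, \code{frequency_Hz}, \code{impedance_ohm}
#'   (left/right), \code{ybocs_pre}, \code{ybocs_post}
#' @export
patient_fixture <- function(id) {
  if (!length(id) == 1 || !id %in% c(1, 2))
    stop("unknown patient id: ", paste(id, collapse = ","),
         " (fixtures exist for patients 1 and 2)")
  rec <- if (id == 1) {
    list(id = 1L,
         active_contact = c(left = 1L, right = 9L),
         current_A = 5.5e-3,
         pulse_width_us = 60,
         frequency_Hz = 160,
         impedance_ohm = c(left = 926, right = 926),
         ybocs_pre = 31L, ybocs_post = 10L)
  } else {
    list(id = 2L,
         active_contact = c(left = 1L, right = 9L),
         current_A = 5.25e-3,
         pulse_width_us = 60,
         frequency_Hz = 160,
         impedance_ohm = c(left = 1262, right = 1150),
         ybocs_pre = 40L, ybocs_post = 24L)
  }
  validate_patient_record(rec)
  structure(rec, class = "patient_record")
}

validate_patient_record <- function(rec) {
  stopifnot(rec$current_A > 0, all(rec$impedance_ohm > 0))
  for (s in c(rec$ybocs_pre, rec$ybocs_post))
    if (s != round(s) || s < 0 || s > 40)
      stop("Y-BOCS scores must be integers in [0, 40]")
  invisible(rec)
}

#' Default lead trajectory for the synthetic phantoms
#'
#' An oblique trajectory whose distal tip sits inside the deep-gray
#' compartment of \code{\link{default_phantom_spec}}, pointing proximally
#' up and laterally out (a frontal burr-hole approach). Left and right are
#' mirror images in x.
#'
#' @param side "left" (negative x) or "right"
#' @return a \code{\link{trajectory}}
#' @export
default_trajectory <- function(side = c("left", "right")) {
  side <- match.arg(side)
  s <- if (side == "left") -1 else 1
  trajectory(tip = c(s * 6, 10, -22), direction = c(s * 0.25, 0.18, 0.95))
}
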