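#' VTA computation settings
#'
#' The activation-function threshold is entered in V/cm^2 as printed in
#' the clinical modeling literature and stored internally in V/m^2
#' (factor exactly 1e4). The default 26.6 V/cm^2 corresponds to myelinated
#' axons of 5.7 um diameter with 70 ohm axoplasmic resistivity; no cable
#' model is evaluated here, the threshold is a configurable constant.
#'
#' @param box_mm edge of the sampling cube centered on the active contact
#' @param spacing_mm fine grid resolution (default 0.1 mm; use 0.2 mm as a
#'   fast mode)
#' @param threshold_V_cm2 activation threshold in V/cm^2
#' @param shell_voxels exclusion shell around conductor/insulator voxels,
#'   in fine-grid voxels
#' @return a \code{vta_config}
#' @export
vta_config <- function(box_mm = 20, spacing_mm = 0.1,
                       threshold_V_cm2 = 26.6, shell_voxels = 2) {
  stopifnot(box_mm > 0, spacing_mm > 0, threshold_V_cm2 > 0,
            shell_voxels >= 0)
  structure(list(box_mm = box_mm, spacing_mm = spacing_mm,
                 threshold_V_cm2 = threshold_V_cm2,
                 threshold_V_m2 = threshold_V_cm2 * 1e4,
                 shell_voxels = shell_voxels),
            class = "vta_config")
}

#' Sample the potential onto the fine VTA grid
#'
#' Trilinear interpolation of the solved potential at the voxel centers of
#' a regular cube (default 20 mm at 0.1 mm) centered on the active
#' contact. Insulator voxels of the source field (NA) are first filled by
#' neighbour averaging so the interpolant is defined next to the lead;
#' those nodes are removed later by the exclusion mask.
#'
#' @param field a \code{potential_field} (typically the refined solve)
#' @param cfg a \code{\link{vta_config}}
#' @param center cube center (mm); default: active-contact centroid of the
#'   field's model
#' @return a \code{voxel_grid} of phi (volts) on the fine lattice
#' @export
sample_grid <- function(field, cfg = vta_config(), center = NULL) {
  src <- field$grid
  if (is.null(center)) {
    act <- which(label_mask(field$model, "ActiveContact"))
    if (!length(act))
      stop("field's model has no active contact; supply `center`")
    center <- colMeans(grid_coords(field$model$labels)[act, , drop = FALSE])
  }
  n <- as.integer(round(cfg$box_mm / cfg$spacing_mm)) + 1L
  origin <- center - cfg$box_mm / 2
  dst <- voxel_grid(array(0, dim = rep(n, 3)), origin,
                    rep(cfg$spacing_mm, 3))
  if (any(origin < src$origin - 1e-9) ||
      any(upper_corner(dst) > upper_corner(src) + 1e-9))
    stop("VTA sampling box exceeds the solved field's grid")
  vals <- src$values
  if (anyNA(vals)) vals <- fill_na_neighbors(vals, iters = 8)
  resample_trilinear(voxel_grid(vals, src$origin, src$spacing), dst)
}

#' Primary eigenvalue field of the potential Hessian
#'
#' Second-order central differences give the 3 x 3 matrix of second
#' spatial derivatives of phi at each node; its algebraically largest
#' eigenvalue is the activation function along the orientation of maximal
#' axonal excitability. Units are V/m^2 (grid spacing is converted from
#' mm). The one-node border, and any node whose 19-point stencil touches a
#' non-finite value, are marked invalid (NA).
#'
#' @param phi a \code{voxel_grid} of potential (volts) with uniform spacing
#' @return an \code{eigen_field}: a \code{voxel_grid} of lambda_1 (V/m^2)
#'   with NA at invalid nodes
#' @export
hessian_primary_eigenvalue <- function(phi) {
  if (any(phi$dim < 3)) stop("grid must be at least 3 voxels wide per axis")
  if (diff(range(phi$spacing)) > 1e-9 * max(phi$spacing))
    stop("Hessian requires uniform (isotropic) grid spacing")
  lam <- cpp_hessian_lambda1(array(as.numeric(phi$values), dim = phi$dim),
                             phi$spacing[1] * 1e-3)
  g <- voxel_grid(lam, phi$origin, phi$spacing)
  class(g) <- c("eigen_field", class(g))
  g
}

#' Exclusion mask around the lead body
#'
#' Fine-grid nodes too close to conductor/insulator voxels for finite
#' differences to be meaningful: within the lead radius plus a safety
#' margin of the axis (the lead interior plus the exclusion shell).
#'
#' @param geom a \code{lead_geometry}
#' @param grid the fine \code{voxel_grid}
#' @param margin_mm shell width beyond the lead radius (mm); typically
#'   \code{shell_voxels * fine spacing + source spacing}
#' @return binary \code{voxel_grid}
#' @export
lead_exclusion_mask <- function(geom, grid, margin_mm) {
  r <- geom$spec$radius + margin_mm
  d2 <- dist2_to_segment(grid, geom$trajectory$tip, geom$trajectory$direction,
                         -margin_mm, geom$spec$shaft_length)
  voxel_grid(d2 <= r^2, grid$origin, grid$spacing)
}

#' Threshold the eigenvalue field into a VTA
#'
#' Activation mask = (lambda_1 >= threshold) AND valid AND NOT excluded;
#' volume = voxel count x spacing^3.
#'
#' @param eig an \code{eigen_field} from
#'   \code{\link{hessian_primary_eigenvalue}}
#' @param cfg a \code{\link{vta_config}}
#' @param exclusion optional binary \code{voxel_grid} on the same lattice
#' @return a \code{vta_result}: \code{mask} (binary \code{voxel_grid}),
#'   \code{volume_mm3}, \code{threshold_V_m2}, \code{excluded}
#' @export
threshold_vta <- function(eig, cfg = vta_config(), exclusion = NULL) {
  excl <- if (is.null(exclusion)) NULL else {
    if (!same_lattice(eig, exclusion))
      stop("exclusion mask is not on the eigenvalue field's lattice")
    exclusion$values != 0
  }
  m <- !is.na(eig$values) & eig$values >= cfg$threshold_V_m2
  if (!is.null(excl)) m <- m & !excl
  structure(list(mask = voxel_grid(m, eig$origin, eig$spacing),
                 volume_mm3 = sum(m) * prod(eig$spacing),
                 threshold_V_m2 = cfg$threshold_V_m2,
                 excluded = exclusion),
            class = "vta_result")
}

#' @export
print.vta_result <- function(x, ...) {
  cat(sprintf("vta_result: %.1f mm^3 at threshold %.3g V/m^2 (%.1f V/cm^2)\n",
              x$volume_mm3, x$threshold_V_m2, x$threshold_V_m2 / 1e4))
  invisible(x)
}
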