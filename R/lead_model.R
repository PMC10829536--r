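#' Lead trajectory
#'
#' Distal tip point and unit direction of the lead axis in world mm
#' coordinates. The direction points from the tip toward the proximal end
#' (up the shaft).
#'
#' @param tip distal tip (mm), length 3
#' @param direction axis direction (normalized internally)
#' @return a \code{trajectory}
#' @export
trajectory <- function(tip, direction) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be non-zero")
  structure(list(tip = as.numeric(tip), direction = as.numeric(direction) / nd),
            class = "trajectory")
}

#' Directional lead specification
#'
#' Geometry of an 8-contact directional DBS lead: a distal ring, two levels
#' of three radial segments, and a proximal ring (distal to proximal), with
#' published Abbott 6172-style dimensions as defaults. Segment arcs default
#' to 100 degrees with 20 degree gaps (three 120 degree pitches).
#'
#' @param contact_height contact height along the axis (mm)
#' @param radius lead radius (mm)
#' @param spacing edge-to-edge inter-contact spacing (mm)
#' @param rows level types distal to proximal
#' @param seg_arc segment arc (degrees)
#' @param seg_gap inter-segment gap (degrees); 3*(arc+gap) must equal 360
#' @param shaft_sigma shaft conductivity (S/m, insulator)
#' @param contact_sigma contact metal conductivity (S/m)
#' @param shaft_length modeled shaft length from the tip (mm)
#' @return a \code{lead_spec}
#' @export
lead_spec <- function(contact_height = 1.5, radius = 0.635, spacing = 1.5,
                      rows = c("ring", "segmented", "segmented", "ring"),
                      seg_arc = 100, seg_gap = 20,
                      shaft_sigma = 0, contact_sigma = 4e6,
                      shaft_length = 40) {
  stopifnot(contact_height > 0, radius > 0, spacing > 0, shaft_length > 0)
  if (length(rows) != 4 || rows[1] != "ring" || rows[4] != "ring" ||
      any(rows[2:3] != "segmented"))
    stop("rows must encode ring, segmented, segmented, ring (distal to proximal)")
  if (abs(3 * (seg_arc + seg_gap) - 360) > 1e-9)
    stop("3*(seg_arc + seg_gap) must equal 360 degrees")
  structure(list(contact_height = contact_height, radius = radius,
                 spacing = spacing, rows = rows, seg_arc = seg_arc,
                 seg_gap = seg_gap, shaft_sigma = shaft_sigma,
                 contact_sigma = contact_sigma, shaft_length = shaft_length),
            class = "lead_spec")
}

# any unit vector orthogonal to d, plus the third frame vector
axis_frame <- function(d) {
  e <- if (abs(d[1]) <= abs(d[2]) && abs(d[1]) <= abs(d[3])) c(1, 0, 0)
  else if (abs(d[2]) <= abs(d[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- e - sum(e * d) * d
  u <- u / sqrt(sum(u^2))
  w <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, w = w)
}

#' Build the 8-contact lead geometry along a trajectory
#'
#' Places the contact array distal to proximal starting at the trajectory
#' tip: ring, 3 segments, 3 segments, ring, each level spanning
#' \code{contact_height} along the axis with \code{spacing} gaps. Contact
#' ids are \code{id_offset + 1 .. 8} with \code{id_offset + 1} the distal
#' ring (use \code{id_offset = 8} for a right lead so its distal ring is
#' contact 9).
#'
#' @param traj a \code{\link{trajectory}}
#' @param spec a \code{\link{lead_spec}}
#' @param id_offset integer offset added to contact ids 1..8
#' @return a \code{lead_geometry}
#' @export
build_lead <- function(traj, spec = lead_spec(), id_offset = 0L) {
  h <- spec$contact_height; sp <- spec$spacing
  fr <- axis_frame(traj$direction)
  contacts <- list()
  id <- id_offset
  for (lev in 1:4) {
    s0 <- (lev - 1) * (h + sp)
    s1 <- s0 + h
    if (spec$rows[lev] == "ring") {
      id <- id + 1L
      contacts[[length(contacts) + 1L]] <-
        list(id = id, level = lev, type = "ring", s0 = s0, s1 = s1,
             arc = NULL)
    } else {
      for (seg in 0:2) {
        id <- id + 1L
        ctr <- seg * 120
        contacts[[length(contacts) + 1L]] <-
          list(id = id, level = lev, type = "segment", s0 = s0, s1 = s1,
               arc = c(ctr - spec$seg_arc / 2, ctr + spec$seg_arc / 2))
      }
    }
  }
  structure(list(trajectory = traj, spec = spec, contacts = contacts,
                 id_offset = as.integer(id_offset),
                 frame = fr,
                 array_span = 4 * h + 3 * sp),
            class = "lead_geometry")
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat(sprintf(
    "lead_geometry: %d contacts (ids %d-%d), array span %.2f mm, tip (%s) mm\n",
    length(x$contacts), x$contacts[[1]]$id,
    x$contacts[[length(x$contacts)]]$id, x$array_span,
    paste(signif(x$trajectory$tip, 4), collapse = ", ")))
  invisible(x)
}

contact_ids <- function(geom) vapply(geom$contacts, `[[`, integer(1), "id")

#' Centroid of a contact's solid (world mm)
#' @param geom a \code{lead_geometry}
#' @param id contact id
#' @return length-3 world point
#' @export
contact_centroid <- function(geom, id) {
  ix <- match(id, contact_ids(geom))
  if (is.na(ix)) stop("contact id ", id, " not in geometry")
  ct <- geom$contacts[[ix]]
  s <- (ct$s0 + ct$s1) / 2
  p <- geom$trajectory$tip + s * geom$trajectory$direction
  if (ct$type == "segment") {
    amid <- mean(ct$arc) * pi / 180
    p <- p + geom$spec$radius *
      (cos(amid) * geom$frame$u + sin(amid) * geom$frame$w)
  }
  p
}

#' Fit a lead trajectory to a binary artifact mask
#'
#' Total-least-squares line through the mask voxel centers: the direction
#' is the principal axis of the coordinate cloud, the tip is the extreme
#' point projected onto the axis at the distal end, and the returned
#' direction points tip -> proximal. The mask must be elongated (ratio of
#' principal extents >= 3), otherwise the centerline is not identifiable.
#'
#' @param mask binary \code{voxel_grid}
#' @param distal rule disambiguating the distal (deep) end:
#'   \code{"lowz"} (default, deeper = smaller z) or \code{"highz"}
#' @param min_anisotropy minimum principal-axis singular-value ratio
#' @return a \code{\link{trajectory}}
#' @export
fit_trajectory <- function(mask, distal = c("lowz", "highz"),
                           min_anisotropy = 3) {
  distal <- match.arg(distal)
  sel <- which(mask$values != 0)
  if (!length(sel)) stop("artifact mask is empty")
  pts <- grid_coords(mask)[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  sv <- svd(cen, nu = 0, nv = 3)
  aniso <- sv$d[1] / max(sv$d[2], .Machine$double.eps)
  if (aniso < min_anisotropy)
    stop(sprintf(
      "mask fails the anisotropy check: principal-extent ratio %.2f < %.1f (not an elongated lead artifact)",
      aniso, min_anisotropy))
  d <- sv$v[, 1]
  t <- drop(cen %*% d)
  p_lo <- ctr + min(t) * d
  p_hi <- ctr + max(t) * d
  tip_is_lo <- if (distal == "lowz") p_lo[3] <= p_hi[3] else p_lo[3] > p_hi[3]
  if (tip_is_lo) trajectory(p_lo, d) else trajectory(p_hi, -d)
}

#' Rasterize a lead geometry into a tissue model
#'
#' Labels shaft voxels as insulator (0 S/m), non-active contact voxels as
#' conductor metal, and the active contact with a dedicated source label.
#' Contacts are one-voxel-thick surface shells at the lead radius (at
#' coarse spacing the whole sub-voxel cross-section collapses onto the
#' shell). All other tissue labels are left unchanged; the operation is
#' idempotent.
#'
#' @param geom a \code{lead_geometry}
#' @param model a \code{tissue_model}
#' @param active_id contact id driven as the stimulation source
#' @param allow_clip allow the shaft to exit the grid (used when
#'   rasterizing into a local refinement box); the full-model default
#'   treats an exiting lead as an error
#' @return a new \code{tissue_model} with lead labels and lead
#'   conductivities added to the table
#' @export
rasterize_lead <- function(geom, model, active_id, allow_clip = FALSE) {
  if (!active_id %in% contact_ids(geom))
    stop("active_id ", active_id, " not in geometry (ids ",
         paste(range(contact_ids(geom)), collapse = "-"), ")")
  g <- model$labels
  traj <- geom$trajectory
  sp <- geom$spec
  hmax <- max(g$spacing)
  r_eff <- max(sp$radius, 0.51 * hmax)   # keep a sub-voxel lead connected
  # the shaft must stay inside the grid (unless clipping into a subgrid)
  ends <- rbind(traj$tip, traj$tip + sp$shaft_length * traj$direction)
  lo <- g$origin - 0.5 * g$spacing
  hi <- upper_corner(g) + 0.5 * g$spacing
  if (!allow_clip &&
      (any(t(ends) < lo - r_eff) || any(t(ends) > hi + r_eff)))
    stop("lead exits the model grid")

  ax <- grid_axes(g)
  vx <- ax$x - traj$tip[1]; vy <- ax$y - traj$tip[2]; vz <- ax$z - traj$tip[3]
  d <- traj$direction
  S <- outer(outer(vx * d[1], vy * d[2], "+"), vz * d[3], "+")
  V2 <- outer(outer(vx^2, vy^2, "+"), vz^2, "+")
  RHO2 <- pmax(V2 - S^2, 0)
  u <- geom$frame$u; w <- geom$frame$w
  PU <- outer(outer(vx * u[1], vy * u[2], "+"), vz * u[3], "+")
  PW <- outer(outer(vx * w[1], vy * w[2], "+"), vz * w[3], "+")
  ANG <- (atan2(PW, PU) * 180 / pi) %% 360

  labels <- g$values
  in_shaft <- RHO2 <= r_eff^2 & S >= 0 & S <= sp$shaft_length
  labels[in_shaft] <- TISSUE_CODES[["LeadShaft"]]

  shell_lo2 <- max(r_eff - hmax, 0)^2
  assigned <- array(FALSE, dim = g$dim)
  for (ct in geom$contacts) {
    sel <- in_shaft & S >= ct$s0 & S <= ct$s1 &
      RHO2 >= shell_lo2 & !assigned
    if (ct$type == "segment") {
      a <- ct$arc %% 360
      sel <- sel & (if (a[1] <= a[2]) ANG >= a[1] & ANG <= a[2]
                    else ANG >= a[1] | ANG <= a[2])
    }
    if (ct$id == active_id && !any(sel)) {
      # sub-voxel contact between lattice planes: claim the voxel whose
      # center is nearest the contact centroid so the source never vanishes
      ctr <- contact_centroid(geom, ct$id)
      ijk <- round((ctr - g$origin) / g$spacing) + 1
      if (any(ijk < 1) || any(ijk > g$dim))
        stop("active contact ", active_id, " lies outside the model grid")
      sel <- array(FALSE, g$dim)
      sel[ijk[1], ijk[2], ijk[3]] <- TRUE
    }
    code <- if (ct$id == active_id) TISSUE_CODES[["ActiveContact"]]
    else TISSUE_CODES[["LeadContact"]]
    labels[sel] <- code
    assigned <- assigned | sel
  }

  cond <- model$conductivity
  cond[["LeadShaft"]] <- sp$shaft_sigma
  cond[["LeadContact"]] <- sp$contact_sigma
  cond[["ActiveContact"]] <- sp$contact_sigma
  tissue_model(voxel_grid(labels, g$origin, g$spacing), cond)
}
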