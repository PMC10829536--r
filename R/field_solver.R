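#' Current sink specification
#'
#' Where the distant return electrode (IPG case) is grounded. The default
#' rule grounds the bottom face of the domain (the base of the body slab
#' in the default phantom), the discrete stand-in for a far return anode.
#' A spherical-shell rule (ground everything beyond a radius) and an
#' explicit mask are available for verification against closed forms.
#'
#' @param rule "bottom", "shell" or "mask"
#' @param radius shell radius (mm), for rule "shell"
#' @param center shell center (mm), for rule "shell"
#' @param mask logical array, for rule "mask"
#' @return a \code{sink_spec} (Dirichlet value is always 0 V)
#' @export
sink_spec <- function(rule = c("bottom", "shell", "mask"),
                      radius = NULL, center = c(0, 0, 0), mask = NULL) {
  rule <- match.arg(rule)
  structure(list(rule = rule, radius = radius, center = center, mask = mask,
                 value = 0),
            class = "sink_spec")
}

sink_mask <- function(sink, model, sigma) {
  g <- model$labels
  m <- switch(sink$rule,
    bottom = {
      m <- array(FALSE, g$dim); m[, , 1] <- TRUE; m
    },
    shell = {
      if (is.null(sink$radius)) stop("shell sink needs a radius")
      ax <- grid_axes(g)
      r2 <- outer(outer((ax$x - sink$center[1])^2,
                        (ax$y - sink$center[2])^2, "+"),
                  (ax$z - sink$center[3])^2, "+")
      r2 >= sink$radius^2
    },
    mask = {
      if (is.null(sink$mask)) stop("mask sink needs a mask")
      sink$mask
    })
  m & sigma > 0
}

#' Solve the quasi-static potential for monopolar stimulation
#'
#' Finite-volume discretization of \eqn{\nabla\cdot(\sigma\nabla\varphi)=0}
#' on the voxel grid with harmonic-mean face conductivities. The active
#' contact is an equipotential surface: unit Dirichlet (1 V) is applied on
#' its voxels and 0 V on the sink; zero-flux conditions hold on all other
#' exterior faces, and sigma = 0 voxels are excluded from the unknown set
#' (exact insulation). By linearity the solution is then scaled so the
#' total current leaving the contact equals \code{current}; the
#' electrode-sink impedance falls out as a by-product.
#'
#' @param model a \code{tissue_model} containing exactly one active-contact
#'   label region (see \code{\link{rasterize_lead}})
#' @param current injected current (A)
#' @param active_id informational contact id stored with the field
#' @param sink a \code{\link{sink_spec}}
#' @param tol relative residual tolerance of the conjugate-gradient solve
#' @param maxit iteration cap
#' @param x0 optional warm-start unit-potential array
#' @return a \code{potential_field}: list with \code{grid} (phi in volts,
#'   NA at insulator voxels), \code{current}, \code{active_id},
#'   \code{impedance} (ohm), \code{contact_potential} (V),
#'   \code{iterations}, \code{residual}, \code{model}, \code{phi_unit}
#' @export
solve_potential <- function(model, current, active_id = NA_integer_,
                            sink = sink_spec(), tol = 1e-8, maxit = 50000,
                            x0 = NULL) {
  sg <- sigma_grid(model)
  active <- label_mask(model, "ActiveContact")
  if (!any(active)) stop("model has no active-contact voxels")
  snk <- sink_mask(sink, model, sg)
  if (!any(snk)) stop("sink region is empty")
  if (any(active & snk)) stop("sink overlaps the active contact")

  dirich <- array(0L, dim = model$labels$dim)
  dirich[active] <- 1L
  dirich[snk] <- 1L
  dvals <- array(0, dim = model$labels$dim)
  dvals[active] <- 1

  res <- cpp_solve_fv(sg, dirich, dvals, model$labels$spacing * 1e-3,
                      tol, as.integer(maxit),
                      if (is.null(x0)) NULL else x0)
  if (!res$converged)
    stop(sprintf("potential solve did not converge in %d iterations (relative residual %.3g)",
                 res$iterations, res$relres))
  I_unit <- cpp_region_flux(sg, res$phi, array(as.integer(active),
                                               dim = dim(active)),
                            model$labels$spacing * 1e-3)
  if (!is.finite(I_unit) || I_unit <= 1e-300)
    stop("no conductive path between the active contact and the sink (singular system)")
  scale <- current / I_unit
  structure(list(grid = voxel_grid(res$phi * scale, model$labels$origin,
                                   model$labels$spacing),
                 current = current, active_id = active_id,
                 impedance = 1 / I_unit,
                 contact_potential = scale,
                 iterations = res$iterations, residual = res$relres,
                 model = model, phi_unit = res$phi),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential_field: contact %s, I = %.3g mA, R = %s ohm, %d CG iterations (relres %.2g)\n",
              format(x$active_id), x$current * 1e3,
              if (is.finite(x$impedance)) sprintf("%.1f", x$impedance) else "NA",
              x$iterations, x$residual))
  print(x$grid)
  invisible(x)
}

#' Electrode-sink impedance of a solved field
#'
#' With the unit-Dirichlet-and-scale excitation this is the contact
#' potential divided by the injected current, i.e. 1 V over the total
#' unscaled current.
#'
#' @param field a \code{potential_field}
#' @return impedance in ohm
#' @export
compute_impedance <- function(field) {
  if (is.null(field$current) || field$current == 0)
    stop("field has zero injected current")
  field$impedance
}

#' Closed-form potential of a point current source in a uniform medium
#'
#' \eqn{\varphi(r) = I / (4\pi\sigma r)}. The reference oracle for solver
#' verification; exact for an infinite homogeneous medium.
#'
#' @param current injected current (A)
#' @param sigma conductivity (S/m)
#' @param points either an n x 3 matrix of world points (mm) with the
#'   source at the origin, or a numeric vector of radii (mm)
#' @return potential in volts per point
#' @export
analytic_point_source <- function(current, sigma, points) {
  if (sigma <= 0) stop("sigma must be > 0")
  r_mm <- if (is.matrix(points)) sqrt(rowSums(points^2)) else as.numeric(points)
  if (any(r_mm <= 0)) stop("points must be away from the source (r > 0)")
  current / (4 * pi * sigma * r_mm * 1e-3)
}

# Fill NA cells (insulator interiors) by repeatedly averaging finite
# 6-neighbours; used only to give interpolation something smooth to chew
# on near the lead (those voxels are excluded from the VTA anyway).
fill_na_neighbors <- function(a, iters = 8) {
  n <- dim(a)
  for (it in seq_len(iters)) {
    na <- is.na(a)
    if (!any(na)) break
    s <- array(0, n); cnt <- array(0, n)
    ix <- seq_len(n[1]); iy <- seq_len(n[2]); iz <- seq_len(n[3])
    shifts <- list(
      list(src = list(ix[-1], iy, iz), dst = list(ix[-n[1]], iy, iz)),
      list(src = list(ix[-n[1]], iy, iz), dst = list(ix[-1], iy, iz)),
      list(src = list(ix, iy[-1], iz), dst = list(ix, iy[-n[2]], iz)),
      list(src = list(ix, iy[-n[2]], iz), dst = list(ix, iy[-1], iz)),
      list(src = list(ix, iy, iz[-1]), dst = list(ix, iy, iz[-n[3]])),
      list(src = list(ix, iy, iz[-n[3]]), dst = list(ix, iy, iz[-1])))
    ok <- !is.na(a)
    av <- a; av[!ok] <- 0
    for (sh in shifts) {
      s[sh$dst[[1]], sh$dst[[2]], sh$dst[[3]]] <-
        s[sh$dst[[1]], sh$dst[[2]], sh$dst[[3]]] +
        av[sh$src[[1]], sh$src[[2]], sh$src[[3]]]
      cnt[sh$dst[[1]], sh$dst[[2]], sh$dst[[3]]] <-
        cnt[sh$dst[[1]], sh$dst[[2]], sh$dst[[3]]] +
        ok[sh$src[[1]], sh$src[[2]], sh$src[[3]]]
    }
    fill <- na & cnt > 0
    a[fill] <- s[fill] / cnt[fill]
  }
  a
}

#' Locally refined re-solve around the lead
#'
#' Re-solves the potential on a fine subgrid (a cube of \code{box_size} mm
#' around \code{box_center}) with tissue labels resampled at the fine
#' spacing (and the lead re-rasterized from geometry when \code{geom} is
#' given). Dirichlet values on the box faces are trilinearly interpolated
#' from the coarse solution; the active contact keeps its coarse
#' equipotential value, so by construction fine and coarse agree on the
#' box boundary. When the refined impedance itself is the quantity of
#' interest (sub-voxel contacts), the face values generated by the coarse
#' contact current can optionally be reconciled with the fine contact
#' current by fixed-point sweeps (\code{couple_iterations > 0}; face
#' values scale linearly with the current driving them).
#'
#' @param model the coarse \code{tissue_model}
#' @param coarse the coarse solved \code{potential_field}
#' @param box_center box center (mm); default: active-contact centroid
#' @param box_size cube edge (mm), default 20
#' @param fine_spacing fine grid spacing (mm)
#' @param geom optional \code{lead_geometry} to re-rasterize at fine spacing
#' @param relabel optional function \code{tissue_model -> tissue_model}
#'   applied to the fine-grid model after resampling (e.g. to re-rasterize
#'   a non-lead electrode shape at the fine spacing)
#' @param match_current if TRUE, rescale the fine solution so the contact
#'   current equals \code{coarse$current} (current-controlled stimulation);
#'   if FALSE the solution stays voltage-true to the coarse field
#' @param couple_iterations fixed-point sweeps reconciling face data with
#'   the fine contact current (0 = keep the coarse face values exactly)
#' @param tol,maxit solver controls
#' @return a \code{potential_field} on the fine grid (impedance recomputed
#'   from the resolved contact)
#' @export
refine_local <- function(model, coarse, box_center = NULL, box_size = 20,
                         fine_spacing = 0.25, geom = NULL, relabel = NULL,
                         match_current = FALSE, couple_iterations = 0,
                         tol = 1e-8, maxit = 50000) {
  cg <- coarse$grid
  if (any(fine_spacing > cg$spacing + 1e-12))
    stop("fine_spacing must not exceed the coarse spacing")
  if (is.null(box_center)) {
    act <- which(label_mask(model, "ActiveContact"))
    if (!length(act)) stop("no active contact to center the box on")
    box_center <- colMeans(grid_coords(model$labels)[act, , drop = FALSE])
  }
  lower <- box_center - box_size / 2
  # snap the fine origin onto the coarse lattice so no-op refinement is exact
  origin_f <- cg$origin + round((lower - cg$origin) / cg$spacing) * cg$spacing
  nf <- as.integer(floor(box_size / fine_spacing)) + 1L
  fine_def <- voxel_grid(array(0, dim = rep(nf, 3)), origin_f,
                         rep(fine_spacing, 3))
  if (any(origin_f < cg$origin - 1e-9) ||
      any(upper_corner(fine_def) > upper_corner(cg) + 1e-9))
    stop("refinement box exits the coarse domain")

  labels_f <- resample_nearest(model$labels, fine_def,
                               outside = TISSUE_CODES[["Exterior"]])
  model_f <- tissue_model(labels_f, model$conductivity)
  if (!is.null(geom)) {
    active_id <- coarse$active_id
    if (is.na(active_id)) stop("coarse field carries no active contact id")
    # clear coarse lead labels inside the box (fill with the modal
    # surrounding tissue), then re-rasterize the lead finely
    lv <- model_f$labels$values
    lead_codes <- TISSUE_CODES[c("LeadShaft", "LeadContact", "ActiveContact")]
    is_lead <- lv %in% lead_codes
    bg <- lv[!is_lead & lv != TISSUE_CODES[["Exterior"]]]
    fill_code <- if (length(bg)) as.integer(names(which.max(table(bg))))
    else TISSUE_CODES[["BrainGreyMatter"]]
    lv[is_lead] <- fill_code
    model_f <- rasterize_lead(geom,
                              tissue_model(voxel_grid(lv, origin_f,
                                                      fine_def$spacing),
                                           model$conductivity),
                              active_id, allow_clip = TRUE)
  }
  if (!is.null(relabel)) model_f <- relabel(model_f)
  sg <- sigma_grid(model_f)

  phi_src <- fill_na_neighbors(cg$values, iters = 8)
  src_grid <- voxel_grid(phi_src, cg$origin, cg$spacing)
  bnd_vals <- resample_trilinear(src_grid, fine_def)$values

  face <- array(FALSE, dim = fine_def$dim)
  face[c(1, nf), , ] <- TRUE; face[, c(1, nf), ] <- TRUE
  face[, , c(1, nf)] <- TRUE
  face <- face & sg > 0 & !is.na(bnd_vals)

  active_f <- label_mask(model_f, "ActiveContact")
  v_c <- coarse$contact_potential

  solve_once <- function(face_scale, x0 = NULL) {
    dirich <- array(0L, dim = fine_def$dim)
    dvals <- array(0, dim = fine_def$dim)
    dirich[face] <- 1L
    dvals[face] <- bnd_vals[face] * face_scale
    if (any(active_f)) {
      dirich[active_f] <- 1L
      dvals[active_f] <- v_c
    }
    res <- cpp_solve_fv(sg, dirich, dvals, fine_def$spacing * 1e-3,
                        tol, as.integer(maxit), x0)
    if (!res$converged)
      stop(sprintf("refined solve did not converge (relres %.3g)", res$relres))
    res
  }

  scale_face <- 1
  res <- solve_once(scale_face)
  I_f <- NA_real_
  if (any(active_f)) {
    reg <- array(as.integer(active_f), dim = dim(active_f))
    I_f <- cpp_region_flux(sg, res$phi, reg, fine_def$spacing * 1e-3)
    it <- 0
    while (it < couple_iterations) {
      it <- it + 1
      new_scale <- I_f / coarse$current
      if (abs(new_scale - scale_face) < 1e-4 * abs(scale_face)) break
      scale_face <- new_scale
      res <- solve_once(scale_face, x0 = res$phi)
      I_f <- cpp_region_flux(sg, res$phi, reg, fine_def$spacing * 1e-3)
    }
  }

  phi <- res$phi
  R_f <- if (is.finite(I_f) && I_f > 0) v_c / I_f else NA_real_
  current_out <- coarse$current
  if (match_current && is.finite(I_f) && I_f > 0) {
    phi <- phi * (coarse$current / I_f)
  } else if (is.finite(I_f)) {
    current_out <- I_f
  }
  structure(list(grid = voxel_grid(phi, origin_f, fine_def$spacing),
                 current = current_out, active_id = coarse$active_id,
                 impedance = R_f,
                 contact_potential = if (match_current && is.finite(I_f))
                   v_c * coarse$current / I_f else v_c,
                 iterations = res$iterations, residual = res$relres,
                 model = model_f, phi_unit = NULL),
            class = "potential_field")
}
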