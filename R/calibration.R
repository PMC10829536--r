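#' Calibrate gray-matter conductivity against a measured impedance
#'
#' Reproduces the per-patient tuning step of the volume conductor model:
#' the simulated electrode-sink impedance is matched to the clinically
#' measured electrode-IPG impedance by adjusting the gray-matter
#' conductivity alone, with every other tissue pinned to its table value.
#' Impedance is strictly decreasing in the gray-matter conductivity, so a
#' guarded bisection on the bracket converges deterministically.
#'
#' @param model a \code{tissue_model} with the lead already rasterized
#'   (one active-contact region)
#' @param current injected current (A); impedance itself is
#'   current-independent but the returned field is scaled to it
#' @param target_R measured impedance to match (ohm)
#' @param bracket conductivity bracket \code{c(sigma_lo, sigma_hi)} (S/m);
#'   the impedance at \code{sigma_lo} must be above the target and at
#'   \code{sigma_hi} below it
#' @param tol relative impedance tolerance (default 0.5\%)
#' @param max_iter bisection cap
#' @param active_id,sink,solver_tol,solver_maxit passed to
#'   \code{\link{solve_potential}}
#' @param impedance_fn optional replacement for the impedance evaluator;
#'   a function \code{(model, x0) -> list(impedance=, phi_unit=, field=)}.
#'   Used to evaluate impedance on a locally refined grid (see
#'   \code{\link{refined_impedance_fn}}).
#' @return a \code{calibration_result}: \code{sigma_gm},
#'   \code{achieved_ohm}, \code{target_ohm}, \code{iterations},
#'   \code{bracket}, \code{model} (calibrated), \code{field} (last solve),
#'   \code{converged}
#' @export
calibrate_gm_conductivity <- function(model, current, target_R,
                                      bracket = c(0.02, 0.5), tol = 0.005,
                                      max_iter = 60, active_id = NA_integer_,
                                      sink = sink_spec(), solver_tol = 1e-8,
                                      solver_maxit = 50000,
                                      impedance_fn = NULL) {
  if (any(bracket <= 0) || bracket[1] >= bracket[2])
    stop("bracket must be positive and increasing")
  if (target_R <= 0) stop("target impedance must be > 0")

  warm <- NULL
  eval_R <- function(sgm) {
    m <- model
    m$conductivity[["BrainGreyMatter"]] <- sgm
    if (is.null(impedance_fn)) {
      f <- solve_potential(m, current = current, active_id = active_id,
                           sink = sink, tol = solver_tol,
                           maxit = solver_maxit, x0 = warm)
      warm <<- f$phi_unit
      list(impedance = f$impedance, field = f, model = m)
    } else {
      r <- impedance_fn(m, warm)
      warm <<- r$phi_unit
      list(impedance = r$impedance, field = r$field, model = m)
    }
  }

  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- eval_R(lo); e_hi <- eval_R(hi)
  R_lo <- e_lo$impedance; R_hi <- e_hi$impedance
  if (R_lo <= R_hi)
    stop(sprintf("impedance is not decreasing over the bracket (R(%.4g) = %.1f, R(%.4g) = %.1f ohm)",
                 lo, R_lo, hi, R_hi))
  if (target_R > R_lo || target_R < R_hi)
    stop(sprintf("target %.1f ohm outside the bracket's impedance range [%.1f, %.1f] ohm (sigma in [%.4g, %.4g] S/m)",
                 target_R, R_hi, R_lo, lo, hi))

  best <- if (abs(R_lo - target_R) < abs(R_hi - target_R))
    c(e_lo, list(sigma = lo)) else c(e_hi, list(sigma = hi))
  it <- 0
  converged <- abs(best$impedance - target_R) / target_R <= tol
  while (!converged && it < max_iter) {
    it <- it + 1
    mid <- (lo + hi) / 2
    e <- eval_R(mid)
    if (abs(e$impedance - target_R) < abs(best$impedance - target_R))
      best <- c(e, list(sigma = mid))
    if (abs(e$impedance - target_R) / target_R <= tol) {
      converged <- TRUE
      break
    }
    if (e$impedance > target_R) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * hi) break
  }
  if (!converged)
    warning(sprintf("calibration stopped after %d iterations at %.1f ohm (target %.1f)",
                    it, best$impedance, target_R))
  structure(list(sigma_gm = best$sigma, achieved_ohm = best$impedance,
                 target_ohm = target_R, iterations = it,
                 bracket = bracket, model = best$model, field = best$field,
                 converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: sigma_GM = %.4f S/m, achieved %.1f ohm (target %.1f, %+.2f%%), %d bisection iterations\n",
              x$sigma_gm, x$achieved_ohm, x$target_ohm,
              100 * (x$achieved_ohm - x$target_ohm) / x$target_ohm,
              x$iterations))
  invisible(x)
}

#' Impedance evaluator on a locally refined grid
#'
#' Builds an \code{impedance_fn} for \code{\link{calibrate_gm_conductivity}}
#' that solves coarse, then re-solves a fine box around the contact and
#' reports the refined impedance. Use when the coarse lattice cannot
#' resolve the contact (sub-voxel electrodes).
#'
#' @param current injected current (A)
#' @param sink a \code{\link{sink_spec}}
#' @param box_size,fine_spacing,geom,relabel,couple_iterations passed to
#'   \code{\link{refine_local}}
#' @param active_id stored contact id
#' @param solver_tol,solver_maxit solver controls
#' @return a function suitable as \code{impedance_fn}
#' @export
refined_impedance_fn <- function(current, sink = sink_spec(), box_size = 10,
                                 fine_spacing = 0.1, geom = NULL,
                                 relabel = NULL, active_id = NA_integer_,
                                 couple_iterations = 3,
                                 solver_tol = 1e-8, solver_maxit = 50000) {
  function(model, x0) {
    coarse <- solve_potential(model, current = current, active_id = active_id,
                              sink = sink, tol = solver_tol,
                              maxit = solver_maxit, x0 = x0)
    fine <- refine_local(model, coarse, box_size = box_size,
                         fine_spacing = fine_spacing, geom = geom,
                         relabel = relabel,
                         couple_iterations = couple_iterations,
                         tol = solver_tol, maxit = solver_maxit)
    list(impedance = fine$impedance, phi_unit = coarse$phi_unit, field = fine)
  }
}
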