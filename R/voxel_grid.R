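#' Regular voxel grid
#'
#' The single gridded container used throughout the package: a 3-D array of
#' values on a regular axis-aligned lattice in right-handed world millimetre
#' coordinates. The voxel-center convention is used everywhere:
#' \code{world(i,j,k) = origin + (index - 1) * spacing} for 1-based indices,
#' so \code{origin} is the world coordinate of the center of voxel
#' \code{[1,1,1]}.
#'
#' @param values 3-D array (numeric, integer or logical).
#' @param origin world coordinate (mm) of the first voxel center, length 3.
#' @param spacing per-axis voxel edge length (mm), length 3 or scalar.
#' @return An object of class \code{voxel_grid}: list with fields
#'   \code{values}, \code{origin}, \code{spacing}, \code{dim}.
#' @export
voxel_grid <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(values = values, origin = origin, spacing = spacing,
                 dim = dim(values)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Voxel-center coordinates along each axis
#' @param g a \code{voxel_grid}
#' @return list of numeric vectors \code{x}, \code{y}, \code{z} (mm)
#' @export
grid_axes <- function(g) {
  list(x = g$origin[1] + (seq_len(g$dim[1]) - 1) * g$spacing[1],
       y = g$origin[2] + (seq_len(g$dim[2]) - 1) * g$spacing[2],
       z = g$origin[3] + (seq_len(g$dim[3]) - 1) * g$spacing[3])
}

#' World coordinates of every voxel center
#' @param g a \code{voxel_grid}
#' @return n x 3 matrix (mm), rows in array (column-major) order
#' @export
grid_coords <- function(g) {
  ax <- grid_axes(g)
  n <- g$dim
  cbind(rep(ax$x, times = n[2] * n[3]),
        rep(rep(ax$y, each = n[1]), times = n[3]),
        rep(ax$z, each = n[1] * n[2]))
}

#' Build an empty grid covering a world bounding box
#'
#' @param bbox 2 x 3 matrix: rows = lower and upper world corners (mm).
#' @param spacing voxel edge length (mm), scalar or length 3.
#' @param value fill value.
#' @return a \code{voxel_grid} whose first voxel center sits at the lower
#'   corner and whose extent covers the box.
#' @export
grid_from_bbox <- function(bbox, spacing, value = 0) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  n <- pmax(2L, as.integer(floor((bbox[2, ] - bbox[1, ]) / spacing)) + 1L)
  voxel_grid(array(value, dim = n), origin = bbox[1, ], spacing = spacing)
}

upper_corner <- function(g) g$origin + (g$dim - 1) * g$spacing

same_lattice <- function(a, b, tol = 1e-6) {
  all(a$dim == b$dim) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Ellipsoid mask on a grid
#'
#' Marks voxels whose centers lie inside the axis-aligned ellipsoid
#' \eqn{\sum ((x_i - c_i)/a_i)^2 \le 1}.
#'
#' @param g a \code{voxel_grid} (defines the lattice; values ignored)
#' @param center ellipsoid center (mm)
#' @param semi_axes semi-axis lengths (mm), all > 0
#' @return logical 3-D array
#' @export
ellipsoid_mask <- function(g, center, semi_axes) {
  if (any(semi_axes <= 0)) stop("degenerate ellipsoid: semi_axes must be > 0")
  ax <- grid_axes(g)
  dx2 <- ((ax$x - center[1]) / semi_axes[1])^2
  dy2 <- ((ax$y - center[2]) / semi_axes[2])^2
  dz2 <- ((ax$z - center[3]) / semi_axes[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+")
  m <= 1
}

#' Axis-aligned box mask on a grid
#' @param g a \code{voxel_grid}
#' @param lower,upper world corners (mm)
#' @return logical 3-D array
#' @export
box_mask <- function(g, lower, upper) {
  ax <- grid_axes(g)
  mx <- ax$x >= lower[1] & ax$x <= upper[1]
  my <- ax$y >= lower[2] & ax$y <= upper[2]
  mz <- ax$z >= lower[3] & ax$z <= upper[3]
  outer(outer(mx, my, "&"), mz, "&")
}

#' Trilinear interpolation at arbitrary world points
#'
#' @param g a \code{voxel_grid} with numeric values
#' @param pts n x 3 matrix of world coordinates (mm)
#' @return numeric vector; NA outside the grid hull
#' @export
interp_trilinear <- function(g, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  gidx <- sweep(sweep(pts, 2, g$origin), 2, g$spacing, "/")  # 0-based cont.
  n <- g$dim
  out <- rep(NA_real_, nrow(pts))
  eps <- 1e-9
  ok <- gidx[, 1] >= -eps & gidx[, 2] >= -eps & gidx[, 3] >= -eps &
    gidx[, 1] <= n[1] - 1 + eps & gidx[, 2] <= n[2] - 1 + eps &
    gidx[, 3] <= n[3] - 1 + eps
  if (!any(ok)) return(out)
  gi <- pmin(pmax(gidx[ok, , drop = FALSE], 0),
             matrix(n - 1, sum(ok), 3, byrow = TRUE))
  i0 <- pmin(floor(gi[, 1]), n[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(gi[, 2]), n[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(gi[, 3]), n[3] - 2); k0 <- pmax(k0, 0)
  tx <- gi[, 1] - i0; ty <- gi[, 2] - j0; tz <- gi[, 3] - k0
  v <- g$values
  at <- function(di, dj, dk)
    v[cbind(i0 + 1 + di, j0 + 1 + dj, k0 + 1 + dk)]
  c00 <- at(0, 0, 0) * (1 - tx) + at(1, 0, 0) * tx
  c10 <- at(0, 1, 0) * (1 - tx) + at(1, 1, 0) * tx
  c01 <- at(0, 0, 1) * (1 - tx) + at(1, 0, 1) * tx
  c11 <- at(0, 1, 1) * (1 - tx) + at(1, 1, 1) * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

#' Nearest-neighbor resampling onto another lattice
#'
#' Used for label and mask grids where interpolation must preserve
#' discreteness.
#'
#' @param g source \code{voxel_grid}
#' @param dst destination \code{voxel_grid} (lattice definition)
#' @param outside value assigned to destination voxels outside the source
#' @return a \code{voxel_grid} on the destination lattice
#' @export
resample_nearest <- function(g, dst, outside = 0L) {
  ax <- grid_axes(dst)
  ix <- round((ax$x - g$origin[1]) / g$spacing[1]) + 1
  iy <- round((ax$y - g$origin[2]) / g$spacing[2]) + 1
  iz <- round((ax$z - g$origin[3]) / g$spacing[3]) + 1
  okx <- ix >= 1 & ix <= g$dim[1]
  oky <- iy >= 1 & iy <= g$dim[2]
  okz <- iz >= 1 & iz <= g$dim[3]
  ix <- pmin(pmax(ix, 1), g$dim[1])
  iy <- pmin(pmax(iy, 1), g$dim[2])
  iz <- pmin(pmax(iz, 1), g$dim[3])
  vals <- g$values[ix, iy, iz, drop = FALSE]
  dim(vals) <- c(length(ix), length(iy), length(iz))
  inb <- outer(outer(okx, oky, "&"), okz, "&")
  vals[!inb] <- outside
  voxel_grid(vals, origin = dst$origin, spacing = dst$spacing)
}

#' Trilinear resampling onto another lattice
#' @inheritParams resample_nearest
#' @return a \code{voxel_grid} on the destination lattice; NA outside the
#'   source hull
#' @export
resample_trilinear <- function(g, dst) {
  vals <- cpp_resample_trilinear(
    array(as.numeric(g$values), dim = g$dim), g$origin, g$spacing,
    as.integer(dst$dim), dst$origin, dst$spacing)
  voxel_grid(vals, origin = dst$origin, spacing = dst$spacing)
}

#' Volume represented by the TRUE voxels of a mask grid
#' @param g a \code{voxel_grid} with logical (or 0/1) values
#' @return volume in mm^3
#' @export
mask_volume <- function(g) sum(g$values != 0, na.rm = TRUE) * prod(g$spacing)
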