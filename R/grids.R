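#' Regularly spaced 3D voxel field
#'
#' `scalar_grid()` is the universal spatial container of the package: a
#' regularly spaced voxel field with an origin (corner of the first voxel),
#' per-axis spacing and a unit tag.  The centre of voxel `(i, j, k)` (1-based)
#' is at `origin + (c(i, j, k) - 1/2) * spacing`.
#'
#' @param origin numeric length-3, corner of the grid (Å).
#' @param spacing numeric length-3 (or scalar, recycled), voxel edge lengths (Å).
#' @param dim integer length-3, voxel counts per axis.
#' @param values numeric array of dimension `dim` (default all zero).
#' @param unit unit tag, one of `"kcal/mol"`, `"angstrom"`, `"mg/mL"`,
#'   `"dimensionless"`.
#' @return An object of class `scalar_grid`.
#' @export
scalar_grid <- function(origin, spacing, dim, values = NULL,
                        unit = c("kcal/mol", "angstrom", "mg/mL", "dimensionless")) {
  unit <- match.arg(unit)
  origin <- as.numeric(origin)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  dim <- as.integer(dim)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dim) == 3)
  if (any(spacing <= 0)) stop("grid spacing must be > 0 on all axes")
  if (any(dim < 1)) stop("grid dim must be >= 1 on all axes")
  if (is.null(values)) values <- array(0, dim)
  if (!is.array(values) || !all(base::dim(values) == dim))
    stop("values must be an array of dimension `dim`")
  structure(list(origin = origin, spacing = spacing, dim = dim,
                 values = values, unit = unit),
            class = "scalar_grid")
}

#' Grid geometry from a bounding box
#'
#' Builds the `origin`/`spacing`/`dim` triple covering `[lower, upper]` with
#' (approximately) the requested spacing; the box is expanded outward so that
#' an integer number of voxels fits exactly.
#'
#' @param lower,upper numeric length-3 bounds (Å).
#' @param spacing voxel edge length (Å), scalar or length-3.
#' @return A list with `origin`, `spacing`, `dim` suitable for [scalar_grid()].
#' @export
grid_spec <- function(lower, upper, spacing = 6) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(upper > lower), all(spacing > 0))
  dim <- pmax(1L, as.integer(ceiling((upper - lower) / spacing - 1e-9)))
  centre <- (lower + upper) / 2
  origin <- centre - dim * spacing / 2
  list(origin = origin, spacing = spacing, dim = dim)
}

#' Voxel-centre coordinates along one axis
#' @param grid a `scalar_grid` (or a `grid_spec()` list).
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-centre coordinates (Å).
#' @export
voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 0.5) * grid$spacing[axis]
}

#' All voxel-centre coordinates as an n-by-3 matrix (x fastest)
#' @param grid a `scalar_grid` or grid spec list.
#' @return Matrix with one row per voxel, in array storage order.
#' @export
voxel_center_matrix <- function(grid) {
  cx <- voxel_centers(grid, 1); cy <- voxel_centers(grid, 2); cz <- voxel_centers(grid, 3)
  cbind(x = rep(cx, times = length(cy) * length(cz)),
        y = rep(rep(cy, each = length(cx)), times = length(cz)),
        z = rep(cz, each = length(cx) * length(cy)))
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid> %d x %d x %d voxels, spacing %s Å, unit %s\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(signif(x$spacing, 4), collapse = " x "), x$unit))
  fin <- x$values[is.finite(x$values)]
  if (length(fin))
    cat(sprintf("  range (finite): [%g, %g]; origin (%g, %g, %g)\n",
                min(fin), max(fin), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Trilinear interpolation of a grid at arbitrary points
#'
#' Values are clamped to the nearest voxel centre outside the grid interior.
#'
#' @param grid a `scalar_grid`.
#' @param points n-by-3 matrix of coordinates (Å).
#' @return Numeric vector of interpolated values.
#' @export
grid_interp <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  u <- sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/") - 0.5
  u <- pmin(pmax(u, 0), matrix(rep(grid$dim - 1L, each = nrow(points)), ncol = 3))
  i0 <- pmin(floor(u), matrix(rep(grid$dim - 2L, each = nrow(points)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- u - i0
  v <- grid$values
  idx <- function(di, dj, dk)
    v[cbind(i0[, 1] + 1 + di, i0[, 2] + 1 + dj, i0[, 3] + 1 + dk)]
  (idx(0,0,0) * (1-f[,1]) + idx(1,0,0) * f[,1]) * (1-f[,2]) * (1-f[,3]) +
  (idx(0,1,0) * (1-f[,1]) + idx(1,1,0) * f[,1]) * f[,2]     * (1-f[,3]) +
  (idx(0,0,1) * (1-f[,1]) + idx(1,0,1) * f[,1]) * (1-f[,2]) * f[,3] +
  (idx(0,1,1) * (1-f[,1]) + idx(1,1,1) * f[,1]) * f[,2]     * f[,3]
}

# internal: flat (array-order) radial and axial coordinates of voxel centres
.grid_rz <- function(grid) {
  cm <- voxel_center_matrix(grid)
  list(r = sqrt(cm[, 1]^2 + cm[, 2]^2), z = cm[, 3])
}
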