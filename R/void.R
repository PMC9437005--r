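#' Void-analysis grid specification
#'
#' @param lower,upper bounding box of the analysis volume (Å).
#' @param voxel_size cubic cell edge l_c (Å): 6 for PMF work, finer (1-2) for
#'   connectivity analysis.
#' @param slab_height height of the cylindrical occupancy segments (Å).
#' @param profile_radius radius of the occupancy cylinder (Å), normally the
#'   confinement radius (500 or 250).
#' @return An object of class `void_grid_spec`.
#' @export
void_grid_spec <- function(lower, upper, voxel_size = 6, slab_height = 6,
                           profile_radius = 500) {
  stopifnot(voxel_size > 0, slab_height > 0, profile_radius > 0)
  gs <- grid_spec(lower, upper, voxel_size)
  structure(list(voxel_size = voxel_size, lower = lower, upper = upper,
                 slab_height = slab_height, profile_radius = profile_radius,
                 origin = gs$origin, spacing = gs$spacing, dim = gs$dim),
            class = "void_grid_spec")
}

#' Distance-to-nearest-obstacle map (R_max)
#'
#' For every voxel centre, the distance to the nearest obstacle surface: the
#' nearest mesh-bead surface (centre distance minus the 3 Å bead radius) or
#' the centre of the nearest sterically excluded voxel (any exclusion
#' potential above `threshold`), whichever is closer.  A voxel is accessible
#' to a probe of radius R_p iff `R_max >= R_p`.  Values are negative inside
#' bead volumes and at excluded voxels themselves (an excluded voxel gets
#' `-voxel_size/2`), so a point probe is correctly barred from them; with no
#' obstacles at all the map is `+Inf`.
#'
#' @param mesh a [mesh_config()] (may have zero chains).
#' @param exclusion_grids list of `scalar_grid` potentials (scaffold, lipid,
#'   confinement); they are sampled at the void-grid voxel centres.
#' @param spec a [void_grid_spec()].
#' @param threshold potential level above which a voxel counts as excluded.
#' @return A `scalar_grid` of class `rmax_map` (Å) with attributes
#'   `excluded` (logical array) and `bead_radius`.
#' @export
compute_rmax <- function(mesh, exclusion_grids = list(), spec,
                         threshold = 1e-9) {
  g <- scalar_grid(spec$origin, spec$spacing, spec$dim, unit = "angstrom")
  nvox <- prod(g$dim)
  mask <- rep(FALSE, nvox)
  if (length(exclusion_grids)) {
    centers <- voxel_center_matrix(g)
    for (ex in exclusion_grids)
      mask <- mask | grid_interp(ex, centers) > threshold
  }
  half <- min(g$spacing) / 2
  if (any(mask)) {
    d2 <- cpp_edt_sq(mask, g$dim, g$spacing)
    dexcl <- sqrt(d2)
    dexcl[d2 >= 1e29] <- Inf
  } else dexcl <- rep(Inf, nvox)
  bead_radius <- if (length(mesh$chains)) mesh$chains[[1]]$bead_radius else 3
  xyz <- if (length(mesh$chains)) mesh_coords(mesh)$xyz
         else matrix(numeric(0), ncol = 3)
  cap <- ifelse(is.finite(dexcl), dexcl, 1e30)
  cell <- max(12, 2 * max(g$spacing))
  dbead <- cpp_rmax_bead(xyz, bead_radius, g$origin, g$spacing, g$dim,
                         cap, cell)
  dbead[dbead >= 1e29] <- Inf
  rmax <- pmin(dbead, dexcl)
  rmax[mask] <- -half
  g$values <- array(rmax, g$dim)
  class(g) <- c("rmax_map", class(g))
  attr(g, "excluded") <- array(mask, g$dim)
  attr(g, "bead_radius") <- bead_radius
  attr(g, "frame_id") <- mesh$frame_id
  g
}

#' Threshold an R_max map into a void (accessibility) map
#'
#' @param rmax an `rmax_map` from [compute_rmax()].
#' @param probe_radius spherical probe radius R_p (Å), >= 0.
#' @return An object of class `void_map`: logical accessibility lattice plus
#'   grid geometry, `probe_radius` and `frame_id`.
#' @export
classify_voids <- function(rmax, probe_radius) {
  if (probe_radius < 0) stop("probe radius must be >= 0")
  structure(list(accessible = rmax$values >= probe_radius,
                 origin = rmax$origin, spacing = rmax$spacing, dim = rmax$dim,
                 probe_radius = probe_radius,
                 frame_id = attr(rmax, "frame_id") %||% 1L),
            class = "void_map")
}

#' @export
print.void_map <- function(x, ...) {
  cat(sprintf("<void_map> R_p = %g Å, %d/%d voxels accessible (frame %s)\n",
              x$probe_radius, sum(x$accessible), length(x$accessible),
              x$frame_id))
  invisible(x)
}

#' 1D occupancy profile of a void map
#'
#' Splits the lattice into co-axial cylindrical segments (radius
#' `profile_radius`, height `slab_height`) and counts accessible voxels whose
#' centres fall inside each segment.
#'
#' @param voidmap a [classify_voids()] result.
#' @param spec the [void_grid_spec()] (for slab height and cylinder radius).
#' @return Object of class `occupancy_profile`: data frame with `z` (slab
#'   centre), `h` (accessible cells), `n` (cells in the segment), `P1`
#'   (`h/n`) and `A` (`h * l_c^2`, Å^2); attributes `A_c` (confinement
#'   cross-section) and `l_c`.
#' @export
occupancy_profile <- function(voidmap, spec) {
  rz <- .grid_rz(voidmap)
  zmin <- voidmap$origin[3]
  nslab <- max(1L, as.integer(round(voidmap$dim[3] * voidmap$spacing[3] /
                                    spec$slab_height)))
  slab <- pmin(pmax(floor((rz$z - zmin) / spec$slab_height), 0), nslab - 1)
  incyl <- rz$r <= spec$profile_radius
  if (!any(incyl)) stop("profile cylinder lies outside the grid")
  acc <- as.logical(voidmap$accessible)
  h <- .weighted_tabulate(slab[incyl] + 1, as.numeric(acc[incyl]), nslab)
  n <- .weighted_tabulate(slab[incyl] + 1, rep(1, sum(incyl)), nslab)
  if (any(n == 0)) stop("empty slab: cylinder not covered by the grid")
  l_c <- voidmap$spacing[1]
  out <- data.frame(z = zmin + (seq_len(nslab) - 0.5) * spec$slab_height,
                    h = h, n = n, P1 = h / n, A = h * l_c^2)
  attr(out, "A_c") <- pi * spec$profile_radius^2
  attr(out, "l_c") <- l_c
  attr(out, "probe_radius") <- voidmap$probe_radius
  attr(out, "frame_id") <- voidmap$frame_id
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Ensemble average of occupancy profiles
#'
#' Pointwise mean and standard error of `h` and `P1` over frames sharing one
#' z grid.
#'
#' @param profiles list of [occupancy_profile()] results.
#' @return Data frame `z`, `h`, `h_sem`, `P1`, `P1_sem` with attributes
#'   `A_c`, `l_c`, `n_frames`.
#' @export
ensemble_average_occupancy <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  z <- profiles[[1]]$z
  for (p in profiles)
    if (length(p$z) != length(z) || any(abs(p$z - z) > 1e-9))
      stop("profiles do not share a z grid")
  hm <- vapply(profiles, `[[`, numeric(length(z)), "h")
  pm <- vapply(profiles, `[[`, numeric(length(z)), "P1")
  hm <- matrix(hm, nrow = length(z)); pm <- matrix(pm, nrow = length(z))
  nf <- length(profiles)
  sem <- function(m) if (nf > 1) apply(m, 1, sd) / sqrt(nf) else rep(0, nrow(m))
  out <- data.frame(z = z, h = rowMeans(hm), h_sem = sem(hm),
                    P1 = rowMeans(pm), P1_sem = sem(pm))
  attr(out, "A_c") <- attr(profiles[[1]], "A_c")
  attr(out, "l_c") <- attr(profiles[[1]], "l_c")
  attr(out, "probe_radius") <- attr(profiles[[1]], "probe_radius")
  attr(out, "n_frames") <- nf
  class(out) <- c("occupancy_profile", "data.frame")
  out
}
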