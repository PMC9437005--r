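#' Nuclear-envelope surface specification
#'
#' The envelope midsurface is the rotationally symmetric curve
#' `(r - 0.6 B)^2 + 4 z^2 = B^2` for `|z| < flatten_z`, and
#' `[r - 0.6 B - (|z| - flatten_z)^2]^2 + 4 z^2 = B^2` otherwise: a translated
#' ellipse whose outer corners are flattened so the membrane is not raised at
#' the edge of the system.  The flattened branch is evaluated exactly in
#' this form, with `(|z| - flatten_z)^2` carrying Å units.
#'
#' @param B ellipse size parameter (Å).
#' @param flatten_z |z| at which the flattened branch takes over (Å).
#' @param wall_height repulsive wall height (kcal/mol).
#' @param wall_softness gaussian decay width of the repulsive wall (Å).
#' @return An object of class `envelope_spec`.
#' @export
envelope_spec <- function(B = 300, flatten_z = 97.2, wall_height = 15,
                          wall_softness = 10) {
  stopifnot(B > 0, flatten_z > 0, wall_height >= 0, wall_softness > 0)
  structure(list(B = B, flatten_z = flatten_z, wall_height = wall_height,
                 wall_softness = wall_softness), class = "envelope_spec")
}

#' Radial coordinate of the envelope surface at a given height
#'
#' Solves the envelope surface equation for `r` at height `z`.  The outer
#' branch takes the `+` root, the inner branch the `-` root; a negative root
#' or `|z| > B/2` has no physical surface and yields `NA`.
#'
#' @param z height(s) along the pore axis (Å).
#' @param spec an [envelope_spec()].
#' @param branch `"outer"` or `"inner"`.
#' @return Radial coordinate(s) r (Å), `NA` where no surface exists.
#' @export
envelope_radius <- function(z, spec = envelope_spec(),
                            branch = c("outer", "inner")) {
  branch <- match.arg(branch)
  B <- spec$B
  disc <- B^2 - 4 * z^2
  s <- ifelse(disc >= 0, sqrt(pmax(disc, 0)), NA_real_)
  shift <- ifelse(abs(z) < spec$flatten_z, 0, (abs(z) - spec$flatten_z)^2)
  r <- 0.6 * B + shift + if (branch == "outer") s else -s
  r[!is.na(r) & r < 0] <- NA_real_
  r
}

# Dense sample of the envelope mid-surface curve in the (r, z) half-plane.
.envelope_curve <- function(spec, n = 2000) {
  zs <- seq(-spec$B / 2, spec$B / 2, length.out = n)
  ro <- envelope_radius(zs, spec, "outer")
  ri <- envelope_radius(zs, spec, "inner")
  rbind(cbind(r = ro, z = zs)[!is.na(ro), , drop = FALSE],
        cbind(r = ri, z = zs)[!is.na(ri), , drop = FALSE])
}

#' Build the steric nuclear-envelope potential grid
#'
#' A purely repulsive wall: `V = wall_height * exp(-(d / wall_softness)^2)`
#' where `d` is the distance from the voxel centre to the envelope
#' mid-surface, so the potential equals `wall_height` on the membrane
#' mid-plane and decays to zero away from it, spanning exactly
#' `[0, wall_height]` kcal/mol.
#'
#' @param spec an [envelope_spec()].
#' @param gspec grid geometry from [grid_spec()].
#' @return A `scalar_grid` in kcal/mol.
#' @export
build_envelope_grid <- function(spec = envelope_spec(), gspec) {
  g <- scalar_grid(gspec$origin, gspec$spacing, gspec$dim, unit = "kcal/mol")
  crv <- .envelope_curve(spec)
  zc <- voxel_centers(g, 3)
  nxy <- g$dim[1] * g$dim[2]
  cm <- voxel_center_matrix(g)[seq_len(nxy), 1:2, drop = FALSE]
  rvox <- sqrt(cm[, 1]^2 + cm[, 2]^2)
  rg <- seq(0, max(rvox) + min(g$spacing), by = min(g$spacing) / 2)
  vals <- numeric(nxy * length(zc))
  dr2 <- outer(rg, crv[, "r"], "-")^2
  for (k in seq_along(zc)) {
    m <- sweep(dr2, 2, (zc[k] - crv[, "z"])^2, "+")
    dmin <- sqrt(m[cbind(seq_along(rg), max.col(-m, ties.method = "first"))])
    vslice <- spec$wall_height * exp(-(dmin / spec$wall_softness)^2)
    vals[(k - 1) * nxy + seq_len(nxy)] <-
      approx(rg, vslice, xout = rvox, rule = 2)$y
  }
  g$values <- array(vals, g$dim)
  g
}

#' Cylindrical confinement specification
#'
#' Zero inside a cylinder of the given radius and height co-axial with the
#' pore axis; outside, a harmonic potential on the overshoot distance with
#' the given spring constant.
#'
#' @param radius cylinder radius (Å); 500 and 250 are the two study values.
#' @param height cylinder height (Å).
#' @param spring_k spring constant (kcal mol^-1 Å^-2).
#' @return An object of class `confinement_spec`.
#' @export
confinement_spec <- function(radius = 500, height = 1200, spring_k = 0.01) {
  stopifnot(radius > 0, height > 0, spring_k > 0)
  structure(list(radius = radius, height = height, spring_k = spring_k),
            class = "confinement_spec")
}

#' Confinement potential at arbitrary points
#' @param points n-by-3 coordinate matrix (Å).
#' @param spec a [confinement_spec()].
#' @return Potential values (kcal/mol).
#' @export
confinement_energy <- function(points, spec = confinement_spec()) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- sqrt(points[, 1]^2 + points[, 2]^2)
  dr <- pmax(r - spec$radius, 0)
  dz <- pmax(abs(points[, 3]) - spec$height / 2, 0)
  0.5 * spec$spring_k * (dr^2 + dz^2)
}

#' Build the cylindrical confinement grid
#' @param spec a [confinement_spec()].
#' @param gspec grid geometry from [grid_spec()].
#' @return A `scalar_grid` in kcal/mol.
#' @export
build_confinement_grid <- function(spec = confinement_spec(), gspec) {
  g <- scalar_grid(gspec$origin, gspec$spacing, gspec$dim, unit = "kcal/mol")
  g$values <- array(confinement_energy(voxel_center_matrix(g), spec), g$dim)
  g
}
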