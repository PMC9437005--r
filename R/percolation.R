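#' Connected components of the accessible lattice
#'
#' Partitions accessible voxels into disjoint sets by union-find with path
#' compression: two accessible voxels share a label iff they are connected
#' through a chain of neighbouring accessible voxels.  Face adjacency
#' (6-connectivity) is the default, since a spherical probe cannot pass
#' through an edge or corner contact; 26-connectivity is available for
#' sensitivity checks.
#'
#' @param voidmap a [classify_voids()] result.
#' @param connectivity 6 or 26.
#' @return Integer array of labels (0 = inaccessible, 1..K for components)
#'   with attribute `n_components`.
#' @export
label_components <- function(voidmap, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  lab <- cpp_label_components(as.logical(voidmap$accessible), voidmap$dim,
                              as.integer(connectivity))
  out <- array(lab, voidmap$dim)
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

# z-layer index whose voxel centres are nearest to z (error outside lattice)
.layer_index <- function(voidmap, z) {
  zc <- voidmap$origin[3] + (seq_len(voidmap$dim[3]) - 0.5) * voidmap$spacing[3]
  if (z < zc[1] - voidmap$spacing[3] / 2 || z > zc[length(zc)] + voidmap$spacing[3] / 2)
    stop("source/sink layer outside the lattice: z = ", z)
  which.min(abs(zc - z))
}

#' Does an open path connect the two faces of the pore?
#'
#' A layer of voxels at `source_z` (above the mesh) and one at `sink_z`
#' (below) are the path endpoints; an open path exists iff some accessible
#' component contains voxels of both layers.
#'
#' @param voidmap a [classify_voids()] result.
#' @param source_z,sink_z layer heights (Å); the NPC volume is `|z| < 200`.
#' @param connectivity 6 or 26.
#' @return Object of class `connectivity_result`: `open_path`,
#'   `n_components`, `probe_radius`, `frame_id`, `source_z`, `sink_z`.
#' @export
open_path_exists <- function(voidmap, source_z = 200, sink_z = -200,
                             connectivity = 6) {
  lab <- label_components(voidmap, connectivity)
  ks <- .layer_index(voidmap, source_z)
  kk <- .layer_index(voidmap, sink_z)
  src <- unique(as.integer(lab[, , ks])); src <- src[src > 0]
  snk <- unique(as.integer(lab[, , kk])); snk <- snk[snk > 0]
  structure(list(open_path = length(intersect(src, snk)) > 0,
                 n_components = attr(lab, "n_components"),
                 probe_radius = voidmap$probe_radius,
                 frame_id = voidmap$frame_id,
                 source_z = source_z, sink_z = sink_z),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity> R_p = %g Å frame %s: open path %s (%d components)\n",
              x$probe_radius, x$frame_id, x$open_path, x$n_components))
  invisible(x)
}

#' Open-path probability across an ensemble
#'
#' For each probe radius, the fraction of mesh configurations with an open
#' path between the source and sink layers, with a Clopper-Pearson binomial
#' confidence band.  The percolation radius point estimate is the smallest
#' radius at which `p_open` drops below 0.5, located by linear interpolation
#' between the bracketing radii.
#'
#' @param ensemble list of [mesh_config()].
#' @param probe_radii probe radii to scan (Å).
#' @param spec a [void_grid_spec()] for the connectivity lattice.
#' @param exclusion_grids steric grids passed to [compute_rmax()].
#' @param source_z,sink_z layer heights (Å).
#' @param connectivity 6 or 26.
#' @param conf_level confidence level of the band.
#' @return Object of class `percolation_curve`: data frame with
#'   `probe_radius`, `p_open`, `n`, `ci_lo`, `ci_hi`; attributes
#'   `percolation_radius` and `bracket` (the radii straddling p = 0.5).
#' @export
percolation_curve <- function(ensemble, probe_radii, spec,
                              exclusion_grids = list(),
                              source_z = 200, sink_z = -200,
                              connectivity = 6, conf_level = 0.95) {
  if (inherits(ensemble, "mesh_config")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1)
  probe_radii <- sort(probe_radii)
  open <- matrix(FALSE, length(ensemble), length(probe_radii))
  for (f in seq_along(ensemble)) {
    rmax <- compute_rmax(ensemble[[f]], exclusion_grids, spec)
    for (j in seq_along(probe_radii)) {
      vm <- classify_voids(rmax, probe_radii[j])
      open[f, j] <- open_path_exists(vm, source_z, sink_z,
                                     connectivity)$open_path
    }
  }
  n <- nrow(open)
  x <- colSums(open)
  alpha <- 1 - conf_level
  ci_lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  ci_hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  out <- data.frame(probe_radius = probe_radii, p_open = x / n, n = n,
                    ci_lo = ci_lo, ci_hi = ci_hi)
  est <- .percolation_radius(out)
  attr(out, "percolation_radius") <- est$radius
  attr(out, "bracket") <- est$bracket
  class(out) <- c("percolation_curve", "data.frame")
  out
}

.percolation_radius <- function(curve) {
  p <- curve$p_open; r <- curve$probe_radius
  below <- which(p < 0.5)
  if (!length(below)) return(list(radius = NA_real_, bracket = c(NA, NA)))
  j <- below[1]
  if (j == 1) return(list(radius = r[1], bracket = c(NA, r[1])))
  r0 <- r[j - 1]; r1 <- r[j]; p0 <- p[j - 1]; p1 <- p[j]
  radius <- if (p0 == p1) r1 else r0 + (0.5 - p0) / (p1 - p0) * (r1 - r0)
  list(radius = radius, bracket = c(r0, r1))
}

#' Write a percolation curve as TSV (plus JSON summary)
#' @param curve a [percolation_curve()] result.
#' @param path output TSV path.
#' @export
write_percolation_curve <- function(curve, path) {
  write_profile_tsv(as.data.frame(curve), path,
                    meta = list(percolation_radius = attr(curve, "percolation_radius"),
                                bracket = attr(curve, "bracket")))
}
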