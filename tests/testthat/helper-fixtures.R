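# Shared fixtures and independent oracles, all generated in code.

# Small anchored-chain ensemble inside a cylindrical confinement.
toy_stoich <- function(n_chains = 8L, len = 40L) {
  stoichiometry(data.frame(name = "Toy", copies = n_chains, first = 1L,
                           last = len, anchor_end = "C"), name = "toy")
}

toy_ensemble <- function(n_frames = 2, n_chains = 8L, len = 40L,
                         ring = 50, seed = 1, grids = list()) {
  build_mesh_ensemble(toy_stoich(n_chains, len), grids = grids,
                      n_frames = n_frames, seed = seed, ring_radius = ring)
}

# Exhaustive per-voxel R_max oracle: min over bead surfaces and excluded
# voxel centres, with the same negative-inside conventions as compute_rmax.
brute_rmax <- function(mesh, exclusion_grids, spec, bead_radius = 3,
                       threshold = 1e-9) {
  g <- scalar_grid(spec$origin, spec$spacing, spec$dim)
  cm <- voxel_center_matrix(g)
  n <- nrow(cm)
  mask <- rep(FALSE, n)
  for (ex in exclusion_grids) mask <- mask | grid_interp(ex, cm) > threshold
  xyz <- if (length(mesh$chains)) mesh_coords(mesh)$xyz
         else matrix(numeric(0), ncol = 3)
  dbead <- rep(Inf, n)
  for (b in seq_len(nrow(xyz)))
    dbead <- pmin(dbead, sqrt((cm[, 1] - xyz[b, 1])^2 +
                              (cm[, 2] - xyz[b, 2])^2 +
                              (cm[, 3] - xyz[b, 3])^2) - bead_radius)
  dexcl <- rep(Inf, n)
  if (any(mask)) {
    ev <- cm[mask, , drop = FALSE]
    for (v in seq_len(nrow(ev)))
      dexcl <- pmin(dexcl, sqrt((cm[, 1] - ev[v, 1])^2 +
                                (cm[, 2] - ev[v, 2])^2 +
                                (cm[, 3] - ev[v, 3])^2))
  }
  out <- pmin(dbead, dexcl)
  out[mask] <- -min(spec$spacing) / 2
  array(out, spec$dim)
}

# Breadth-first-search flood fill: the independent connectivity oracle.
bfs_label <- function(acc, connectivity = 6) {
  d <- dim(acc)
  offs <- if (connectivity == 6) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    o <- expand.grid(-1:1, -1:1, -1:1)
    o <- o[rowSums(abs(o)) > 0, ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  lab <- array(0L, d); cur <- 0L
  idx <- which(acc, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    i0 <- idx[s, ]
    if (lab[i0[1], i0[2], i0[3]] != 0) next
    cur <- cur + 1L
    queue <- matrix(i0, ncol = 3)
    lab[i0[1], i0[2], i0[3]] <- cur
    while (nrow(queue)) {
      p <- queue[nrow(queue), ]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (o in offs) {
        q <- p + o
        if (any(q < 1) || any(q > d)) next
        if (acc[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition of the TRUE voxels?
same_partition <- function(lab1, lab2, acc) {
  a <- as.integer(lab1[acc]); b <- as.integer(lab2[acc])
  all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# void map wrapper around a raw logical array (unit spacing lattice)
raw_void_map <- function(acc, spacing = 1, probe_radius = 1) {
  structure(list(accessible = acc, origin = c(0, 0, 0),
                 spacing = rep(spacing, 3), dim = dim(acc),
                 probe_radius = probe_radius, frame_id = 1L),
            class = "void_map")
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}

# Hard cylindrical constriction of open radius `a` inside a confinement
# cylinder of radius R_c: the void-pipeline PMF plateau must reproduce the
# closed-form annulus result -ln(pi (a - R_p)^2 / (pi R_c^2)).  Returns the
# absolute error (kBT) of the measured plateau at cell size l_c.
annulus_pipeline_error <- function(l_c, R_c = 150, a = 80, Rp = 10, L = 60,
                                   z_half = 120) {
  vgs <- void_grid_spec(c(-R_c, -R_c, -z_half), c(R_c, R_c, z_half),
                        voxel_size = l_c, slab_height = l_c,
                        profile_radius = R_c)
  ex <- scalar_grid(vgs$origin, vgs$spacing, vgs$dim)
  cm <- voxel_center_matrix(ex)
  r <- sqrt(cm[, 1]^2 + cm[, 2]^2)
  ex$values <- array(as.numeric(r > a & abs(cm[, 3]) < L / 2) * 5, vgs$dim)
  rm <- compute_rmax(mesh_config(list()), list(ex), vgs)
  prof <- occupancy_profile(classify_voids(rm, Rp), vgs)
  avg <- ensemble_average_occupancy(list(prof))
  pmf <- pmf_from_occupancy(avg)
  plateau <- mean(pmf$F[abs(pmf$z) < L / 2 - 2 * l_c])
  theory <- -log((a - Rp)^2 / R_c^2)
  abs(plateau - theory)
}

# steric cylinder: voxels outside radius `radius` carry a positive potential
# (closes the lateral boundary of percolation fixtures)
cylinder_exclusion <- function(vgs, radius) {
  g <- scalar_grid(vgs$origin, vgs$spacing, vgs$dim)
  cm <- voxel_center_matrix(g)
  g$values <- array(as.numeric(sqrt(cm[, 1]^2 + cm[, 2]^2) > radius) * 2,
                    vgs$dim)
  g
}

# trapezoidal barrier: plateau of height exactly H (kBT) over |z| < hw with
# linear ramps of width w, so the escape prefactor is nearly H-independent
# and the Arrhenius slope of ln(tau) vs H approaches 1
plateau_pmf <- function(H, z = seq(-40, 40, by = 1), hw = 6, w = 6) {
  pmf_profile(z, H * pmax(0, pmin(1, (hw + w - abs(z)) / w)))
}
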