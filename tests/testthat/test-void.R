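test_that("R_max reproduces simple geometric cases", {
  # single bead: voxel centre 10 Å from the bead centre has R_max = 7
  vgs <- void_grid_spec(c(-20, -20, -20), c(20, 20, 20), voxel_size = 5,
                        profile_radius = 18)
  mesh <- mesh_config(list(bead_chain(matrix(c(2.5, 2.5, 2.5), 1))))
  rm <- compute_rmax(mesh, list(), vgs)
  cm <- voxel_center_matrix(rm)
  at <- which(abs(cm[, 1] - 2.5) < 1e-9 & abs(cm[, 2] - 2.5) < 1e-9 &
              abs(cm[, 3] - 12.5) < 1e-9)         # 10 Å along z
  expect_length(at, 1)
  expect_equal(as.numeric(rm$values)[at], 7)
  # empty mesh, no grids: +Inf sentinel everywhere
  rm0 <- compute_rmax(mesh_config(list()), list(), vgs)
  expect_true(all(is.infinite(rm0$values) & rm0$values > 0))
})

test_that("R_max equals the exhaustive oracle with beads and exclusion grids", {
  set.seed(21)
  vgs <- void_grid_spec(c(-32, -32, -32), c(32, 32, 32), voxel_size = 4,
                        profile_radius = 30)
  for (rep in 1:3) {
    beads <- matrix(runif(3 * 20, -28, 28), ncol = 3)
    mesh <- mesh_config(list(bead_chain(beads)))
    ex <- scalar_grid(vgs$origin, vgs$spacing, vgs$dim)
    ex$values <- array(as.numeric(runif(prod(vgs$dim)) < 0.02) * 3, vgs$dim)
    rm <- compute_rmax(mesh, list(ex), vgs)
    oracle <- brute_rmax(mesh, list(ex), vgs)
    expect_equal(as.numeric(rm$values), as.numeric(oracle), tolerance = 1e-9)
  }
})

test_that("R_max is 1-Lipschitz across neighbouring voxels", {
  ens <- toy_ensemble(n_frames = 1, n_chains = 6L, len = 25L, ring = 40,
                      seed = 3)
  vgs <- void_grid_spec(c(-80, -80, -80), c(80, 80, 80), voxel_size = 5,
                        profile_radius = 70)
  rm <- compute_rmax(ens[[1]], list(), vgs)
  v <- rm$values
  for (ax in 1:3) {
    d <- apply(v, setdiff(1:3, ax), diff)
    expect_lte(max(abs(d)), rm$spacing[ax] + 1e-9)
  }
})

test_that("void classification thresholds R_max and nests across probe radii", {
  ens <- toy_ensemble(n_frames = 1, n_chains = 6L, len = 25L, ring = 40,
                      seed = 5)
  vgs <- void_grid_spec(c(-80, -80, -80), c(80, 80, 80), voxel_size = 5,
                        profile_radius = 70)
  rm <- compute_rmax(ens[[1]], list(), vgs)
  expect_error(classify_voids(rm, -1), "probe radius")
  # probe 0: everywhere not inside an obstacle
  vm0 <- classify_voids(rm, 0)
  expect_equal(vm0$accessible, rm$values >= 0)
  radii <- c(0, 2, 5, 9, 14, 20)
  prev <- NULL
  for (rp in radii) {
    acc <- classify_voids(rm, rp)$accessible
    expect_identical(acc, rm$values >= rp)
    if (!is.null(prev)) expect_true(all(prev | !acc))  # acc subset of prev
    prev <- acc
  }
  # strict shrinkage when beads are present
  expect_lt(sum(classify_voids(rm, 20)$accessible),
            sum(classify_voids(rm, 0)$accessible))
})

test_that("a large probe carves an excluded shell of the proper thickness around a chain", {
  # geometric reading of a void map: every voxel centre within
  # (R_p + bead radius) of a bead centre must be inaccessible
  ch <- generate_chain(c(0, 0, 0), 30, seed = 2)
  mesh <- mesh_config(list(ch))
  vgs <- void_grid_spec(c(-90, -90, -90), c(90, 90, 90), voxel_size = 3,
                        profile_radius = 80)
  rm <- compute_rmax(mesh, list(), vgs)
  rp <- 22.4
  acc <- classify_voids(rm, rp)$accessible
  cm <- voxel_center_matrix(rm)
  dmin <- apply(ch$xyz, 1, function(p)
    sqrt((cm[, 1] - p[1])^2 + (cm[, 2] - p[2])^2 + (cm[, 3] - p[3])^2))
  dmin <- do.call(pmin, as.data.frame(dmin))
  expect_true(all(!acc[dmin < rp + 3]))
  expect_true(all(acc[dmin >= rp + 3]))
})

test_that("occupancy profiles count accessible voxels per cylindrical slab", {
  vgs <- void_grid_spec(c(-24, -24, -24), c(24, 24, 24), voxel_size = 4,
                        slab_height = 4, profile_radius = 20)
  rm0 <- compute_rmax(mesh_config(list()), list(), vgs)
  vm <- classify_voids(rm0, 5)
  prof <- occupancy_profile(vm, vgs)
  expect_true(all(prof$P1 == 1))
  expect_equal(prof$A, prof$h * 16)
  # excluded slab at |z| < 4 drives P1 to 0 there only
  ex <- scalar_grid(vgs$origin, vgs$spacing, vgs$dim)
  cm <- voxel_center_matrix(ex)
  ex$values <- array(as.numeric(abs(cm[, 3]) < 4) * 2, ex$dim)
  vm2 <- classify_voids(compute_rmax(mesh_config(list()), list(ex), vgs), 0)
  prof2 <- occupancy_profile(vm2, vgs)
  expect_true(all(prof2$P1[abs(prof2$z) < 4] == 0))
  expect_true(all(prof2$P1[abs(prof2$z) > 8] == 1))
  # random map: counts equal a direct per-slab recount
  set.seed(9)
  vm3 <- vm
  vm3$accessible <- array(runif(prod(vgs$dim)) < 0.4, vgs$dim)
  prof3 <- occupancy_profile(vm3, vgs)
  rz <- cbind(sqrt(cm[, 1]^2 + cm[, 2]^2), cm[, 3])
  for (k in seq_len(nrow(prof3))) {
    sel <- rz[, 1] <= 20 & abs(rz[, 2] - prof3$z[k]) < 2
    expect_equal(prof3$h[k], sum(vm3$accessible[sel]))
  }
})

test_that("ensemble averaging returns pointwise means and standard errors", {
  vgs <- void_grid_spec(c(-24, -24, -24), c(24, 24, 24), voxel_size = 4,
                        slab_height = 4, profile_radius = 20)
  base <- occupancy_profile(
    classify_voids(compute_rmax(mesh_config(list()), list(), vgs), 0), vgs)
  # identical profiles: mean = profile, SEM = 0
  avg <- ensemble_average_occupancy(list(base, base, base))
  expect_equal(avg$h, base$h)
  expect_true(all(avg$h_sem == 0))
  expect_equal(attr(avg, "n_frames"), 3)
  # alternating {0,1} occupancies average to 0.5
  p0 <- base; p0$h <- rep(0, nrow(p0)); p0$P1 <- rep(0, nrow(p0))
  p1 <- base; p1$h <- p1$n; p1$P1 <- rep(1, nrow(p1))
  avg01 <- ensemble_average_occupancy(list(p0, p1))
  expect_true(all(avg01$P1 == 0.5))
  # SEM matches the direct formula on random profiles
  set.seed(17)
  profs <- lapply(1:100, function(i) {
    p <- base; p$h <- rpois(nrow(p), 20); p$P1 <- p$h / p$n; p
  })
  avg100 <- ensemble_average_occupancy(profs)
  hmat <- vapply(profs, `[[`, numeric(nrow(base)), "h")
  expect_equal(avg100$h_sem, apply(hmat, 1, sd) / 10, tolerance = 1e-12)
  # heterogeneous grids are rejected
  bad <- base; bad$z <- bad$z + 1
  expect_error(ensemble_average_occupancy(list(base, bad)), "z grid")
})
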