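test_that("envelope surface solves its implicit equation", {
  spec <- envelope_spec()
  # ellipse branch at the midplane: r = 0.6 B + B
  expect_equal(envelope_radius(0, spec, "outer"), 480)
  # inner root is negative at z = 0: no physical surface
  expect_true(is.na(envelope_radius(0, spec, "inner")))
  # beyond the envelope extent
  expect_true(is.na(envelope_radius(160, spec, "outer")))
  # flattened branch: cross-check against a bisection solve of the implicit
  # equation [r - 0.6B - (|z|-97.2)^2]^2 + 4 z^2 = B^2
  for (z in c(100, 120, 140)) {
    r_ana <- envelope_radius(z, spec, "outer")
    f <- function(r) (r - 0.6 * spec$B - (abs(z) - spec$flatten_z)^2)^2 +
      4 * z^2 - spec$B^2
    lo <- 0.6 * spec$B + (abs(z) - spec$flatten_z)^2  # vertex: f < 0 here
    hi <- lo + 2 * spec$B
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    expect_equal(r_ana, (lo + hi) / 2, tolerance = 1e-9)
  }
  # both branches agree at the switch height
  eps <- 1e-9
  expect_equal(envelope_radius(spec$flatten_z - eps, spec),
               envelope_radius(spec$flatten_z + eps, spec), tolerance = 1e-6)
})

test_that("envelope grid is a bounded repulsive wall, symmetric about the axis", {
  spec <- envelope_spec()
  gs <- grid_spec(c(-550, -550, -160), c(550, 550, 160), spacing = 12)
  g <- build_envelope_grid(spec, gs)
  v <- as.numeric(g$values)
  expect_true(all(v >= 0 & v <= spec$wall_height + 1e-9))
  # far inside the pore lumen the wall vanishes
  expect_lt(grid_interp(g, matrix(c(0, 0, 0), 1)), 1e-6)
  # voxels near the membrane mid-surface reach (essentially) the full height
  expect_gt(max(v), 0.9 * spec$wall_height)
  # 40 Å inward of the surface the gaussian ramp (width 10 Å) has decayed
  rs <- envelope_radius(0, spec, "outer")
  expect_lt(grid_interp(g, matrix(c(rs - 40, 0, 0), 1)),
            0.05 * spec$wall_height)
  # rotational symmetry: same radius, different azimuth, within one voxel
  r <- 480
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  vals <- grid_interp(g, cbind(r * cos(th), r * sin(th), 0))
  expect_lt(max(vals) - min(vals), 0.1 * spec$wall_height)
})

test_that("scaffold convolution: FFT equals direct summation; delta kernel; empty", {
  gs <- grid_spec(c(-72, -72, -72), c(72, 72, 72), spacing = 6)
  kern <- pair_potential_table()
  # empty scaffold -> identically zero
  g0 <- build_scaffold_potential(data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0), type = character(0)),
                                 "G", kern, gs)
  expect_true(all(g0$values == 0))
  # one bead with a tabulated step kernel reproduces the kernel shape
  step_tab <- pair_potential_table(kernels = list(r = seq(0, 50, 0.25),
                                                  K = as.numeric(seq(0, 50, 0.25) < 6)),
                                   cutoff = 50)
  b1 <- data.frame(x = 1, y = 0.5, z = -1, type = "Y")
  g1 <- build_scaffold_potential(b1, "X", step_tab, gs)
  cm <- voxel_center_matrix(g1)
  # the bead is snapped to the centre of its containing voxel
  ctr <- gs$origin + (floor((c(1, 0.5, -1) - gs$origin) / gs$spacing) + 0.5) *
    gs$spacing
  d <- sqrt((cm[, 1] - ctr[1])^2 + (cm[, 2] - ctr[2])^2 + (cm[, 3] - ctr[3])^2)
  inside <- d < 6 - 1e-6
  expect_true(all(abs(as.numeric(g1$values)[inside] - 1) < 1e-6))
  outside <- d > 6 + 6     # one voxel of slack around the step edge
  expect_true(all(abs(as.numeric(g1$values)[outside]) < 1e-6))
  # 10 random beads on a small grid: FFT vs direct within 1e-6 relative
  set.seed(3)
  gs24 <- grid_spec(c(-60, -60, -60), c(60, 60, 60), spacing = 5)
  beads <- data.frame(x = runif(10, -50, 50), y = runif(10, -50, 50),
                      z = runif(10, -50, 50),
                      type = sample(c("F", "G", "S"), 10, replace = TRUE))
  gf <- build_scaffold_potential(beads, "A", kern, gs24, method = "fft")
  gd <- build_scaffold_potential(beads, "A", kern, gs24, method = "direct")
  scale <- max(abs(gd$values))
  expect_lt(max(abs(gf$values - gd$values)) / scale, 1e-6)
})

test_that("confinement grid is harmonic outside the cylinder and monotone in r", {
  spec <- confinement_spec(radius = 500, height = 1200, spring_k = 0.01)
  expect_equal(confinement_energy(matrix(c(400, 0, 0), 1), spec), 0)
  # 10 Å radial overshoot: 0.5 * 0.01 * 10^2
  expect_equal(confinement_energy(matrix(c(510, 0, 0), 1), spec), 0.5)
  r <- seq(0, 700, by = 10)
  v <- confinement_energy(cbind(r, 0, 0), spec)
  expect_true(all(diff(v) >= 0))
  gs <- grid_spec(c(-650, -650, -700), c(650, 650, 700), spacing = 50)
  g <- build_confinement_grid(spec, gs)
  cm <- voxel_center_matrix(g)
  expect_equal(as.numeric(g$values), confinement_energy(cm, spec))
})

test_that("grid containers enforce geometry and interpolate linearly", {
  expect_error(scalar_grid(c(0, 0, 0), c(1, -1, 1), c(2, 2, 2)), "spacing")
  g <- scalar_grid(c(0, 0, 0), c(2, 2, 2), c(4, 4, 4))
  expect_equal(voxel_centers(g, 1), c(1, 3, 5, 7))
  cm <- voxel_center_matrix(g)
  g$values <- array(cm[, 1] + 2 * cm[, 2] - cm[, 3], g$dim)  # linear field
  pts <- cbind(runif(20, 1, 7), runif(20, 1, 7), runif(20, 1, 7))
  expect_equal(grid_interp(g, pts), pts[, 1] + 2 * pts[, 2] - pts[, 3],
               tolerance = 1e-12)
})
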