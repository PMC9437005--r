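test_that("occupancy inversion cancels for a fully open confinement and adds ln 2 per halving", {
  z <- seq(-57, 57, by = 6)
  A_c <- pi * 150^2
  full <- A_c / 36                      # cells of a fully accessible slab
  df <- data.frame(z = z, h = rep(full, length(z)))
  pmf <- pmf_from_occupancy(df, A_c = A_c, l_c = 6)
  expect_equal(pmf$F, rep(0, length(z)), tolerance = 1e-12)
  df2 <- df; df2$h[10] <- full / 2
  pmf2 <- pmf_from_occupancy(df2, A_c = A_c, l_c = 6)
  expect_equal(pmf2$F[10], log(2), tolerance = 1e-12)
  # hard wall: zero occupancy is +Inf, and negative occupancy is rejected
  df3 <- df; df3$h[3] <- 0
  expect_true(is.infinite(pmf_from_occupancy(df3, A_c = A_c, l_c = 6)$F[3]))
  expect_error(pmf_from_occupancy(df, A_c = -1, l_c = 6), "positive")
})

test_that("the void pipeline reproduces the closed-form annulus PMF", {
  # small version of the constriction fixture (acceptance runs the full one)
  err <- annulus_pipeline_error(6, R_c = 90, a = 55, Rp = 8, L = 48,
                                z_half = 90)
  expect_lt(err, 0.1)
})

test_that("trace inversion recovers flat and gaussian-well potentials", {
  set.seed(23)
  # uniform samples: flat within binomial noise
  zs <- runif(200000, -100, 100)
  pf <- pmf_from_trace(zs, bin_width = 10)
  expect_lt(max(abs(pf$F[is.finite(pf$F)])), 0.1)
  # gaussian well V(z) = z^2 / (2 sigma^2): sampled exactly by rnorm
  sigma <- 50
  zg <- rnorm(300000, 0, sigma)
  pg <- pmf_from_trace(zg, bin_width = 10)
  sel <- is.finite(pg$F) & abs(pg$z) < 2 * sigma
  Vtheory <- pg$z^2 / (2 * sigma^2)
  shift <- mean((pg$F - Vtheory)[sel])
  resid <- (pg$F - Vtheory - shift)[sel]
  expect_true(all(abs(resid) < 3 * pg$stderr[sel] + 1e-3))
  expect_error(pmf_from_trace(rnorm(100)), "1000")
})

test_that("symmetrisation averages probabilities, conserves mass and reports asymmetry", {
  z <- seq(-95, 95, by = 10)
  # already symmetric: unchanged, asymmetry 0
  Fsym <- cos(z / 30)
  p0 <- pmf_profile(z, Fsym)
  s0 <- symmetrize_pmf(p0)
  expect_equal(s0$F, Fsym, tolerance = 1e-12)
  expect_equal(attr(s0, "asymmetry"), 0)
  # asymmetric step: mirrored probability mean, idempotent
  Fstep <- ifelse(z > 0, 1, 0)
  p1 <- pmf_profile(z, Fstep)
  s1 <- symmetrize_pmf(p1)
  expect_equal(s1$F, -log((exp(-Fstep) + exp(-rev(Fstep))) / 2))
  expect_equal(symmetrize_pmf(s1)$F, s1$F, tolerance = 1e-12)
  expect_equal(attr(symmetrize_pmf(s1), "asymmetry"), 0, tolerance = 1e-12)
  # probability mass conserved
  expect_equal(sum(exp(-s1$F)), sum(exp(-Fstep)), tolerance = 1e-12)
  # asymmetry equals a direct recomputation on random profiles
  set.seed(29)
  for (rep in 1:20) {
    F <- rnorm(length(z))
    s <- symmetrize_pmf(pmf_profile(z, F))
    direct <- mean(abs(F - rev(F)))
    expect_equal(attr(s, "asymmetry"), direct, tolerance = 1e-12)
  }
  expect_error(symmetrize_pmf(pmf_profile(z + 1, Fsym)), "symmetric")
})

test_that("barrier heights average the PMF over the central window", {
  z <- seq(-99.5, 99.5, by = 1)
  expect_equal(barrier_height(pmf_profile(z, 0))$value, 0)
  rect <- ifelse(abs(z) < 50, 2, 0)
  expect_equal(barrier_height(pmf_profile(z, rect))$value, 2)
  # triangle: peak 3 kBT at z = 0, zero at |z| = 100; mean over |z| < 50 is
  # 3 * (1 - 25/100) = 2.25
  tri <- 3 * pmax(1 - abs(z) / 100, 0)
  expect_equal(barrier_height(pmf_profile(z, tri))$value, 2.25)
  # uncertainty comes from the asymmetry statistic
  skew <- tri + 0.5 * (z > 0)
  b <- barrier_height(pmf_profile(z, skew))
  expect_gt(b$uncertainty, 0)
  expect_error(barrier_height(pmf_profile(seq(10, 60, 1), 0)),
               "does not")
})

test_that("void-derived and trace-derived PMFs close the loop through 1D dynamics", {
  # brownian dynamics on a known PMF, then boltzmann inversion, must return
  # the input within sampling error
  z <- seq(-200, 200, by = 5)
  V <- 1.5 * exp(-z^2 / (2 * 40^2))
  pmf <- pmf_profile(z, V)
  dp <- diffusivity_profile(data.frame(z = z, A = 100), D0 = 1000,
                            model = "constant")
  # samples are decorrelated (RMS displacement between samples > bin width)
  # so the per-bin binomial standard errors apply
  tr <- bd_trace(pmf, dp, z_start = -150, z_lo = -200, z_hi = 200,
                 n_samples = 120000, sample_every = 0.25, step_length = 1.5,
                 seed = 31)
  pt <- pmf_from_trace(tr$z, bin_width = 10)
  sel <- is.finite(pt$F) & abs(pt$z) < 150
  Vt <- approx(z, V, xout = pt$z[sel])$y
  shift <- mean(pt$F[sel] - Vt)
  expect_true(all(abs(pt$F[sel] - Vt - shift) <
                  3 * pt$stderr[sel] + 0.05))
})

test_that("PMF TSV output carries both energy units and metadata", {
  z <- seq(-30, 30, by = 10)
  pmf <- pmf_profile(z, z / 30)
  path <- tempfile(fileext = ".tsv")
  write_pmf_tsv(pmf, path, meta = list(probe_radius = 15))
  df <- read_profile_tsv(path)
  expect_equal(df$F_kcal, df$F_kBT * 0.5925)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$probe_radius, 15)
  expect_equal(meta$source, "void")
  unlink(c(path, paste0(path, ".json")))
})
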