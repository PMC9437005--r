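test_that("local diffusion models follow their closed forms", {
  z <- seq(0, 50, by = 1)
  # constant area: D = D0 under every model
  for (m in c("reguera_rubi", "zwanzig", "constant")) {
    dp <- diffusivity_profile(data.frame(z = z, A = 400), D0 = 120, model = m)
    expect_equal(dp$D, rep(120, length(z)))
  }
  # linear half-width with slope 1: D0/sqrt(2) vs D0/1.5
  w <- 100 + z
  lin <- data.frame(z = z, A = pi * w^2)
  drr <- diffusivity_profile(lin, D0 = 120, model = "reguera_rubi")
  dzw <- diffusivity_profile(lin, D0 = 120, model = "zwanzig")
  expect_equal(drr$D[2:50], rep(120 / sqrt(2), 49), tolerance = 1e-9)
  expect_equal(dzw$D[2:50], rep(120 / 1.5, 49), tolerance = 1e-9)
  # random smooth area: both models equal their formulas pointwise, and the
  # Reguera-Rubi correction is always the milder one
  set.seed(37)
  A <- (300 + 150 * sin(z / 7) + 50 * cos(z / 3))
  dr <- diffusivity_profile(data.frame(z = z, A = A), D0 = 80,
                            model = "reguera_rubi")
  dz <- diffusivity_profile(data.frame(z = z, A = A), D0 = 80,
                            model = "zwanzig")
  s <- dr$dwdz
  expect_equal(dr$D, 80 / sqrt(1 + s^2), tolerance = 1e-12)
  expect_equal(dz$D, 80 / (1 + 0.5 * s^2), tolerance = 1e-12)
  expect_true(all(dz$D <= dr$D + 1e-12))
  expect_true(all(dr$D > 0 & dr$D <= 80))
  expect_error(diffusivity_profile(data.frame(z = z, A = A - 400), D0 = 80),
               "hard wall")
})

test_that("transition rates obey the flat-potential limit and detailed balance", {
  z <- seq(-650, 250, by = 10)
  dp <- diffusivity_profile(data.frame(z = z, A = 100), D0 = 500,
                            model = "constant")
  flat <- transition_rates(dp, pmf_profile(z, 0), d = 2)
  expect_equal(flat$up, rep(500 / 4, length(flat$up)), tolerance = 1e-12)
  expect_equal(flat$dn[-1], rep(500 / 4, length(flat$dn) - 1),
               tolerance = 1e-12)
  expect_equal(flat$dn[1], 0)          # reflecting end
  # random potential: k_{n->m} / k_{m->n} = exp(-(V_m - V_n))
  set.seed(41)
  zc <- seq(-600, 200, by = 25)
  Vr <- rnorm(length(zc), sd = 1.5)
  rr <- transition_rates(dp, pmf_profile(zc, Vr), d = 5)
  n <- length(rr$z)
  ratio <- rr$up[-n] / rr$dn[-1]
  dV <- diff(.interp <- approx(zc, Vr, xout = rr$z, rule = 2)$y)
  expect_equal(log(ratio), -dV, tolerance = 1e-9)
  # hard-wall node: all rates in and out vanish
  Vh <- rep(0, length(zc)); Vh[15] <- Inf
  rh <- transition_rates(dp, pmf_profile(zc, Vh), d = 5)
  bad <- which(!is.finite(rh$V))
  expect_true(all(rh$up[bad] == 0 & rh$dn[bad] == 0))
  expect_true(all(rh$up[bad - 1] == 0))
  expect_true(all(rh$dn[bad + 1] == 0))
})

test_that("flat-PMF first passage matches the closed form and conserves mass", {
  D0 <- 1000
  z <- seq(-650, 250, by = 10)
  pmf <- pmf_profile(z, 0)
  dp <- diffusivity_profile(data.frame(z = z, A = 100), D0 = D0,
                            model = "constant")
  fpt <- solve_fpt(transition_rates(dp, pmf, d = 2), z_start = -200)
  tau_exact <- (800^2 - 400^2) / (2 * D0)      # (L^2 - x0^2) / 2D
  expect_lt(abs(fpt$tau - tau_exact) / tau_exact, 0.01)
  expect_lt(fpt$solver$max_drift, 1e-6)
  expect_lt(fpt$residual, 1e-3)
  expect_true(all(fpt$g >= 0))
  # g integrates to 1 - residual
  expect_equal(sum(fpt$g) * diff(fpt$t)[1], 1 - fpt$residual,
               tolerance = 1e-6)
  # doubling D0 halves tau exactly (same dimensionless chain)
  dp2 <- diffusivity_profile(data.frame(z = z, A = 100), D0 = 2 * D0,
                             model = "constant")
  fpt2 <- solve_fpt(transition_rates(dp2, pmf, d = 2), z_start = -200)
  expect_equal(fpt2$tau * 2, fpt$tau, tolerance = 1e-9)
  # grid refinement: halving d moves tau by < 0.5%
  fpt_h <- solve_fpt(transition_rates(dp, pmf, d = 1), z_start = -200)
  expect_lt(abs(fpt_h$tau - fpt$tau) / fpt$tau, 0.005)
})

test_that("escape over a high plateau barrier is Arrhenius", {
  z <- seq(-40, 40, by = 1)
  dp <- diffusivity_profile(data.frame(z = z, A = 100), D0 = 500,
                            model = "constant")
  Hs <- c(8, 9, 10)
  # barrier escape is asymptotically single-exponential, so stepping stops
  # at 2% survival and the fitted tail supplies the remaining mass
  taus <- vapply(Hs, function(H) {
    rates <- transition_rates(dp, plateau_pmf(H), d = 2, z_min = -30,
                              z_max = 30)
    solve_fpt(rates, z_start = -25, tol_resid = 0.02)$tau
  }, numeric(1))
  slope <- coef(stats::lm(log(taus) ~ Hs))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("solver agrees with the Brownian-dynamics oracle on random PMFs", {
  set.seed(43)
  D0 <- 800
  z <- seq(-650, 250, by = 5)
  dpz <- data.frame(z = z, A = 100)
  for (rep in 1:3) {
    centers <- runif(2, -350, 0)
    amps <- runif(2, 0.5, 1.8)
    V <- amps[1] * exp(-(z - centers[1])^2 / (2 * 60^2)) +
         amps[2] * exp(-(z - centers[2])^2 / (2 * 40^2))
    pmf <- pmf_profile(z, V)
    dp <- diffusivity_profile(dpz, D0 = D0, model = "constant")
    tau_fd <- solve_fpt(transition_rates(dp, pmf, d = 2), z_start = -200)$tau
    bd <- bd_oracle_mfpt(pmf, dp, n_walkers = 1500, step_length = 2.5,
                         seed = 100 + rep)
    expect_lt(abs(tau_fd - bd$tau), 2 * bd$sem + 0.02 * tau_fd)
  }
  # fixed-seed reproducibility of the oracle
  zf <- seq(-650, 250, by = 10)
  pmf0 <- pmf_profile(zf, 0)
  dp0 <- diffusivity_profile(data.frame(z = zf, A = 100), D0 = D0,
                             model = "constant")
  b1 <- bd_oracle_mfpt(pmf0, dp0, n_walkers = 200, seed = 7)
  b2 <- bd_oracle_mfpt(pmf0, dp0, n_walkers = 200, seed = 7)
  expect_identical(b1$durations, b2$durations)
})

test_that("swapping the local diffusion model changes tau by a bounded factor", {
  # entropic channel: varying area, no energetic barrier
  z <- seq(-650, 250, by = 5)
  A <- 500 - 420 * exp(-z^2 / (2 * 50^2))
  pmfA <- pmf_profile(z, -log(A / 500))
  taus <- vapply(c("reguera_rubi", "zwanzig"), function(m) {
    dp <- diffusivity_profile(data.frame(z = z, A = A), D0 = 600, model = m)
    solve_fpt(transition_rates(dp, pmfA, d = 2), z_start = -200)$tau
  }, numeric(1))
  fac <- taus[["zwanzig"]] / taus[["reguera_rubi"]]
  expect_gte(fac, 1)        # zwanzig diffuses slower through the neck
  expect_lt(fac, 1.5)       # ... but the choice has little influence
})

test_that("the free-diffusion FPT density has the right mode and unit mass", {
  l <- 400; D <- 100
  tg <- seq(0.5, 2000, by = 0.5)
  P <- free_diffusion_fpt_density(l, D, tg)
  expect_equal(tg[which.max(P)], l^2 / (6 * D), tolerance = 1e-2)
  expect_true(all(P >= 0))
  # normalisation: integrate the density over (0, Inf)
  mass <- stats::integrate(function(t) free_diffusion_fpt_density(l, D, t),
                           0, Inf, rel.tol = 1e-6)$value
  expect_equal(mass, 1, tolerance = 1e-4)
  expect_error(free_diffusion_fpt_density(-1, D, tg), "positive")
})
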