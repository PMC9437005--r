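#' Position-dependent diffusivity from an accessible-area profile
#'
#' Fick-Jacobs reduction of diffusion in a channel of varying cross-section
#' `A(z) = pi w(z)^2`: the local diffusion coefficient is reduced where the
#' effective half-width `w(z)` changes,
#' `D = D0 / sqrt(1 + (dw/dz)^2)` (Reguera-Rubi) or
#' `D = D0 / (1 + (dw/dz)^2 / 2)` (Zwanzig); `"constant"` keeps `D = D0`.
#' `dw/dz` is evaluated by central differences (one-sided at the ends).
#'
#' @param area data frame with columns `z` (Å) and `A` (Å^2), or an
#'   [ensemble_average_occupancy()] profile (then `A = h l_c^2`).
#' @param D0 bulk diffusivity (Å^2/us).
#' @param model `"reguera_rubi"`, `"zwanzig"` or `"constant"`.
#' @return Object of class `diffusivity_profile`: data frame `z`, `w`,
#'   `dwdz`, `D` with attributes `D0` and `model`.
#' @export
diffusivity_profile <- function(area, D0,
                                model = c("reguera_rubi", "zwanzig", "constant")) {
  model <- match.arg(model)
  if (!"A" %in% names(area)) {
    l_c <- attr(area, "l_c")
    if (is.null(l_c) || is.null(area$h)) stop("need columns z and A (or h with l_c)")
    area <- data.frame(z = area$z, A = area$h * l_c^2)
  }
  stopifnot(D0 > 0)
  if (any(area$A <= 0))
    stop("nonpositive accessible area inside the solver domain (hard wall)")
  z <- area$z
  w <- sqrt(area$A / pi)
  n <- length(z)
  dwdz <- numeric(n)
  if (n > 2) dwdz[2:(n - 1)] <- (w[3:n] - w[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
  if (n > 1) {
    dwdz[1] <- (w[2] - w[1]) / (z[2] - z[1])
    dwdz[n] <- (w[n] - w[n - 1]) / (z[n] - z[n - 1])
  }
  D <- switch(model,
    reguera_rubi = D0 / sqrt(1 + dwdz^2),
    zwanzig = D0 / (1 + 0.5 * dwdz^2),
    constant = rep(D0, n))
  out <- data.frame(z = z, w = w, dwdz = dwdz, D = D)
  attr(out, "D0") <- D0
  attr(out, "model") <- model
  class(out) <- c("diffusivity_profile", "data.frame")
  out
}

# linear interpolation helpers that respect hard walls / fall back to defaults
.interp_V <- function(pmf, zout) {
  fin <- is.finite(pmf$F)
  V <- if (sum(fin) >= 2)
    approx(pmf$z[fin], pmf$F[fin], xout = zout, rule = 2)$y
  else rep(0, length(zout))
  V[zout < min(pmf$z) - 1e-9 | zout > max(pmf$z) + 1e-9] <- 0  # far field
  if (any(!fin)) {
    hardz <- pmf$z[!fin]
    dz <- if (length(pmf$z) > 1) min(diff(sort(pmf$z))) else 1
    for (hz in hardz) V[abs(zout - hz) <= dz / 2] <- Inf
  }
  V
}

.interp_D <- function(dprof, zout) {
  D <- approx(dprof$z, dprof$D, xout = zout, rule = 2)$y
  D0 <- attr(dprof, "D0")
  D[zout < min(dprof$z) - 1e-9 | zout > max(dprof$z) + 1e-9] <- D0
  D
}

#' Nearest-neighbour transition rates of the discretised Smoluchowski equation
#'
#' Discretises the axial coordinate as `z_n = z_min + n d`, n = 0..N+1, with
#' `z_0` reflecting and `z_{N+1}` absorbing, and computes the hopping rates
#' `k_{n->m} = (D_n + D_m) / (2 d^2) exp(-(V_m - V_n)/2)` (V in kBT), which
#' satisfy detailed balance by construction.  Outside the supplied profiles
#' the PMF is 0 and the diffusivity D0 (the far field).  Hard-wall nodes
#' (infinite PMF) get zero in- and out-rates.
#'
#' @param dprof a [diffusivity_profile()].
#' @param pmf a [pmf_profile()] (kBT).
#' @param d node spacing (Å).
#' @param z_min reflecting boundary position (Å).
#' @param z_max absorbing boundary position (Å).
#' @return Object of class `transition_rates`: interior node positions `z`,
#'   rate vectors `up` (`k_{n->n+1}`, the last entry being the absorption
#'   rate) and `dn` (`k_{n->n-1}`, first entry 0), spacing `d`, and the
#'   interior `V` and `D` samples.
#' @export
transition_rates <- function(dprof, pmf, d = 0.5, z_min = -600, z_max = 200) {
  stopifnot(d > 0, z_max > z_min)
  zg <- seq(z_min, z_max, by = d)
  if (abs(tail(zg, 1) - z_max) > 1e-9)
    stop("(z_max - z_min) must be an integer multiple of d")
  V <- .interp_V(pmf, zg)
  D <- .interp_D(dprof, zg)
  M <- length(zg)                      # M = N + 2 points
  rate <- function(a, b) {             # a -> b, indices into zg
    out <- (D[a] + D[b]) / (2 * d^2) * exp(-(V[b] - V[a]) / 2)
    out[!is.finite(V[a]) | !is.finite(V[b])] <- 0
    out
  }
  int <- 2:(M - 1)                     # interior nodes z_1..z_N
  up <- rate(int, int + 1)
  dn <- rate(int, int - 1)
  dn[1] <- 0                           # reflecting end: k_{1->0} = k_{0->1} = 0
  structure(list(z = zg[int], up = up, dn = dn, d = d,
                 V = V[int], D = D[int],
                 z_min = z_min, z_max = z_max),
            class = "transition_rates")
}

#' Solve the first-passage problem by explicit Euler stepping
#'
#' Propagates a delta-function initial density at `z_start` through the
#' master equation with reflecting/absorbing ends until the survival
#' probability drops below `tol_resid` (or `max_steps` is hit, in which case
#' the partial result is returned with the residual flagged).  The
#' first-passage-time density g(t) is accumulated from absorbed-mass
#' increments (algebraically identical to differentiating the total interior
#' mass, numerically stabler); the MFPT adds an exponential tail correction
#' from the terminal survival decay.
#'
#' @param rates a [transition_rates()] object.
#' @param z_start initial position (Å).
#' @param dt Euler time step (us); default `0.4 / max(up + dn)`, which obeys
#'   the stability requirement `D dt / d^2 < 1`.  Larger user values are
#'   reduced automatically with a warning.
#' @param tol_resid terminal survival probability.
#' @param max_steps hard step cap.
#' @param out_stride steps aggregated per output bin of g(t).
#' @return Object of class `fpt_result`: `t` (bin centres, us), `g` (FPT
#'   density, 1/us), `survival`, `tau` (MFPT, us), `tau_tail` (tail
#'   correction included in `tau`), `residual`, and `solver` parameters.
#' @export
solve_fpt <- function(rates, z_start = -200, dt = NULL, tol_resid = 1e-3,
                      max_steps = 2e8, out_stride = 64) {
  start <- which.min(abs(rates$z - z_start))
  if (!is.finite(rates$V[start]))
    stop("start position lies on a hard-wall node")
  kmax <- max(rates$up + rates$dn)
  dt_stable <- 0.4 / kmax
  if (is.null(dt)) dt <- dt_stable
  else if (dt > dt_stable) {
    warning(sprintf("dt = %g exceeds the stability bound; reduced to %g",
                    dt, dt_stable))
    dt <- dt_stable
  }
  res <- cpp_solve_fpt(rates$up, rates$dn, start - 1L, dt,
                       as.integer(out_stride), tol_resid, max_steps)
  nb <- length(res$g_mass)
  tb <- (seq_len(nb) - 0.5) * res$bin_dt
  g <- res$g_mass / res$bin_dt
  tau_num <- sum(res$g_mass * tb)
  # exponential tail: fit log-survival over the last stretch of the decay
  surv <- res$survival
  tau_tail <- 0
  if (res$survival_end > 0 && nb >= 10) {
    i0 <- max(1, floor(0.8 * nb))
    sel <- i0:nb
    sel <- sel[surv[sel] > 0]
    if (length(sel) >= 5) {
      ts <- sel * res$bin_dt
      fit <- stats::lm.fit(cbind(1, ts), log(surv[sel]))
      lam <- -unname(fit$coefficients[2])
      if (is.finite(lam) && lam > 0)
        tau_tail <- res$survival_end * (res$t_end + 1 / lam)
    }
  }
  if (res$survival_end > tol_resid)
    warning(sprintf("non-converged: residual survival %g after %g steps",
                    res$survival_end, res$steps))
  structure(list(t = tb, g = g, survival = surv,
                 tau = tau_num + tau_tail, tau_tail = tau_tail,
                 residual = res$survival_end, absorbed = res$absorbed,
                 solver = list(d = rates$d, dt = dt, z_start = rates$z[start],
                               z_min = rates$z_min, z_max = rates$z_max,
                               n_nodes = length(rates$z), steps = res$steps,
                               max_drift = res$max_drift,
                               out_stride = out_stride)),
            class = "fpt_result")
}

#' @export
print.fpt_result <- function(x, ...) {
  cat(sprintf("<fpt_result> tau = %.6g us (tail %.3g), residual %.2g, %g steps\n",
              x$tau, x$tau_tail, x$residual, x$solver$steps))
  invisible(x)
}

#' First-passage-time density of free 1D diffusion over a fixed distance
#'
#' `P(t) = l / sqrt(4 pi D t^3) exp(-l^2 / (4 D t))`: the inverse-Gaussian
#' density of the time to first travel a distance `l` by free diffusion with
#' open/absorbing ends.  Its mode is at `t* = l^2 / (6 D)`.
#'
#' @param l travel distance (Å); the NPC channel corresponds to 400 Å.
#' @param D diffusion constant (Å^2/us).
#' @param t_grid times at which to evaluate (us).
#' @return Density values (1/us).
#' @export
free_diffusion_fpt_density <- function(l, D, t_grid) {
  if (l <= 0 || D <= 0) stop("l and D must be positive")
  ifelse(t_grid > 0,
         l / sqrt(4 * pi * D * t_grid^3) * exp(-l^2 / (4 * D * t_grid)),
         0)
}

#' Brownian-dynamics oracle for the mean first-passage time
#'
#' Independent stochastic cross-check of [solve_fpt()]: overdamped
#' Euler-Maruyama walkers on the same PMF and diffusivity profile, with the
#' spurious-drift term `dD/dz` required for position-dependent D, a
#' reflecting wall at `z_min` and absorption at `z_max`.
#'
#' @param pmf a [pmf_profile()] (finite over the domain).
#' @param dprof a [diffusivity_profile()].
#' @param n_walkers number of walkers.
#' @param z_start,z_min,z_max geometry (Å), matching the solver defaults.
#' @param step_length target RMS step (Å); sets `dt = step_length^2 / (2 max D)`.
#' @param seed optional integer seed.
#' @param max_time per-walker time cap (us).
#' @return List with `tau`, `sem`, `n_absorbed` and the walker `durations`.
#' @export
bd_oracle_mfpt <- function(pmf, dprof, n_walkers = 2000, z_start = -200,
                           z_min = -600, z_max = 200, step_length = 2,
                           seed = NULL, max_time = Inf) {
  if (!is.null(seed)) set.seed(seed)
  dz <- 1
  zg <- seq(z_min - 5, z_max + 5, by = dz)
  V <- .interp_V(pmf, zg)
  if (any(!is.finite(V)))
    stop("BD oracle requires a finite PMF over the domain")
  D <- .interp_D(dprof, zg)
  n <- length(zg)
  dVdz <- c(V[2] - V[1], (V[3:n] - V[1:(n - 2)]) / 2, V[n] - V[n - 1]) / dz
  dDdz <- c(D[2] - D[1], (D[3:n] - D[1:(n - 2)]) / 2, D[n] - D[n - 1]) / dz
  drift <- -D * dVdz + dDdz
  dt <- step_length^2 / (2 * max(D))
  amax <- max(abs(drift))
  if (amax > 0) dt <- min(dt, step_length / amax)
  max_steps <- if (is.finite(max_time)) max_time / dt else 1e9
  durs <- cpp_bd_mfpt(drift, D, zg[1], dz, z_start, z_min, z_max, dt,
                      as.integer(n_walkers), max_steps)
  ok <- durs > 0
  if (!any(ok)) stop("no walker absorbed; increase max_time")
  list(tau = mean(durs[ok]), sem = sd(durs[ok]) / sqrt(sum(ok)),
       n_absorbed = sum(ok), durations = durs[ok])
}

#' Equilibrium Brownian-dynamics trace on a 1D PMF
#'
#' Generates a position trace by overdamped dynamics with reflecting walls at
#' both ends; used to close the loop between void-derived PMFs and
#' trace-derived PMFs, and to produce telegraph-style test traces.
#'
#' @inheritParams bd_oracle_mfpt
#' @param z_lo,z_hi reflecting walls (Å).
#' @param n_samples number of samples returned.
#' @param sample_every time between samples (us).
#' @return Object of class `trace_series`: data frame `t` (us), `z` (Å).
#' @export
bd_trace <- function(pmf, dprof, z_start = 0, z_lo = -600, z_hi = 600,
                     n_samples = 100000, sample_every = NULL,
                     step_length = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dz <- 1
  zg <- seq(z_lo - 5, z_hi + 5, by = dz)
  V <- .interp_V(pmf, zg)
  if (any(!is.finite(V))) stop("bd_trace requires a finite PMF")
  D <- .interp_D(dprof, zg)
  n <- length(zg)
  dVdz <- c(V[2] - V[1], (V[3:n] - V[1:(n - 2)]) / 2, V[n] - V[n - 1]) / dz
  dDdz <- c(D[2] - D[1], (D[3:n] - D[1:(n - 2)]) / 2, D[n] - D[n - 1]) / dz
  drift <- -D * dVdz + dDdz
  dt <- step_length^2 / (2 * max(D))
  amax <- max(abs(drift))
  if (amax > 0) dt <- min(dt, step_length / amax)
  stride <- if (is.null(sample_every)) 10L
            else max(1L, as.integer(round(sample_every / dt)))
  zs <- cpp_bd_trace(drift, D, zg[1], dz, z_start, z_lo, z_hi, dt,
                     as.numeric(n_samples) * stride, stride)
  trace_series(t = seq_along(zs) * dt * stride, z = zs)
}
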