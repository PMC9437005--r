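#' Fit the MFPT scaling law
#'
#' Fits `tau(R_p) = tau0 * R_p * exp(((R_p + 3 Å) / R0)^alpha)` to a table of
#' mean first-passage times versus probe radius.  The pre-exponential
#' `tau0 R_p` is the Stokes-Einstein cost of finding the pore
#' (`D_eff ~ 1/R_p`); the stretched-exponential term is the effective barrier
#' `H_eff = ((R_p + 3 Å)/R0)^alpha`, the 3 Å offset accounting for the
#' physical size of the mesh residues (held fixed, not fitted).  Least
#' squares is performed on `ln tau` (multiplicative noise model), with
#' `ln tau0` profiled out and a 5-point jittered multi-start over
#' `(ln R0, ln alpha)` to avoid local minima.
#'
#' @param radii probe radii (Å), at least 4 distinct values.
#' @param taus mean first-passage times (us).
#' @param weights optional least-squares weights on `ln tau`.
#' @param offset the fixed additive radius offset (Å).
#' @param alpha_fixed optionally pin alpha (e.g. 2 for a gaussian-barrier
#'   nested model) and fit only tau0 and R0.
#' @return Object of class `scaling_fit`: `tau0` (us/Å), `R0` (Å), `alpha`,
#'   `offset`, `covariance` (of `(ln tau0, ln R0, ln alpha)`), `residuals`
#'   (on `ln tau`), `sse` and the data.
#' @export
fit_scaling_law <- function(radii, taus, weights = NULL, offset = 3,
                            alpha_fixed = NULL) {
  stopifnot(length(radii) == length(taus), all(taus > 0), all(radii > 0))
  if (length(unique(radii)) < 4)
    stop("need at least 4 distinct radii spanning the crossover")
  w <- if (is.null(weights)) rep(1, length(radii)) else weights
  lt <- log(taus) - log(radii)          # ln tau0 + ((R+offset)/R0)^alpha
  obj <- function(theta) {
    R0 <- exp(theta[1])
    alpha <- if (is.null(alpha_fixed)) exp(theta[2]) else alpha_fixed
    H <- ((radii + offset) / R0)^alpha
    if (any(!is.finite(H))) return(1e12)
    r <- lt - H
    lntau0 <- sum(w * r) / sum(w)
    sum(w * (r - lntau0)^2)
  }
  init0 <- c(log(median(radii)), log(2))
  npar <- if (is.null(alpha_fixed)) 2 else 1
  best <- NULL
  set.seed_local <- function(k) c(init0[1] + 0.4 * ((k %% 3) - 1),
                                  init0[2] + 0.3 * ((k %/% 3) - 1))
  for (k in 0:4) {
    ini <- set.seed_local(k)[seq_len(npar)]
    o1 <- if (npar == 1)
      optim(ini, obj, method = "Brent", lower = log(0.5), upper = log(500))
    else
      optim(ini, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-14))
    o2 <- if (npar == 1) o1
          else tryCatch(optim(o1$par, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-14)),
                        error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  theta <- best$par
  R0 <- exp(theta[1])
  alpha <- if (is.null(alpha_fixed)) exp(theta[2]) else alpha_fixed
  lntau0 <- {
    H <- ((radii + offset) / R0)^alpha
    sum(w * (lt - H)) / sum(w)
  }
  # Gauss-Newton polish with the analytic jacobian: optim's finite-difference
  # gradients stop near sqrt(eps); this drives the optimum to machine
  # precision (and makes the fit exactly scale-equivariant in tau)
  p <- c(lntau0, log(R0), if (is.null(alpha_fixed)) log(alpha))
  sse_of <- function(p) {
    al <- if (is.null(alpha_fixed)) exp(p[3]) else alpha_fixed
    H <- ((radii + offset) / exp(p[2]))^al
    sum(w * (lt - p[1] - H)^2)
  }
  cur <- sse_of(p)
  for (it in 1:100) {
    al <- if (is.null(alpha_fixed)) exp(p[3]) else alpha_fixed
    R0c <- exp(p[2])
    H <- ((radii + offset) / R0c)^al
    r <- lt - p[1] - H
    J <- cbind(-1, al * H,
               if (is.null(alpha_fixed)) -al * H * log((radii + offset) / R0c))
    step <- tryCatch(solve(crossprod(J, w * J), crossprod(J, w * r)),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      pn <- p - lam * as.numeric(step)
      nsse <- sse_of(pn)
      if (is.finite(nsse) && nsse <= cur + 1e-15) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (lam < 1e-8) break
    moved <- max(abs(pn - p))
    p <- pn; cur <- nsse
    if (moved < 1e-14) break
  }
  lntau0 <- p[1]; R0 <- exp(p[2])
  if (is.null(alpha_fixed)) alpha <- exp(p[3])
  H <- ((radii + offset) / R0)^alpha
  resid <- lt - lntau0 - H
  sse <- sum(w * resid^2)
  # covariance of (ln tau0, ln R0, ln alpha) from the gauss-newton jacobian
  J <- cbind(1, alpha * H, if (is.null(alpha_fixed)) H * log((radii + offset) / R0) * alpha)
  covm <- tryCatch({
    sigma2 <- sse / max(length(radii) - ncol(J), 1)
    sigma2 * solve(crossprod(J * sqrt(w)))
  }, error = function(e) matrix(NA_real_, ncol(J), ncol(J)))
  structure(list(tau0 = exp(lntau0), R0 = R0, alpha = alpha, offset = offset,
                 covariance = covm, residuals = resid, sse = sse,
                 radii = radii, taus = taus),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> tau0 = %.4g us/Å, R0 = %.4g Å, alpha = %.4g (offset %g Å)\n",
              x$tau0, x$R0, x$alpha, x$offset))
  cat(sprintf("  residual SS (ln tau): %.4g over %d points\n",
              x$sse, length(x$radii)))
  invisible(x)
}

#' Predicted MFPT of a scaling fit
#' @param object a [scaling_fit()].
#' @param radii probe radii (Å).
#' @param ... unused.
#' @export
predict.scaling_fit <- function(object, radii, ...) {
  object$tau0 * radii * exp(((radii + object$offset) / object$R0)^object$alpha)
}

#' Soft-to-hard barrier crossover radius
#'
#' The exponential term of the scaling law dominates once `ln(R_p)` falls
#' below `((R_p + 3 Å)/R0)^alpha`; the crossover radius is the upper root of
#' `ln R = ((R + offset)/R0)^alpha`, located by bracketed root-finding.
#' Below it the MFPT grows like a power law (soft barrier), above it
#' exponentially (hard barrier).
#'
#' @param fit a [scaling_fit()]; alternatively give `R0` and `alpha` directly.
#' @param R0,alpha,offset explicit parameters (used when `fit` is missing).
#' @param interval search interval (Å).
#' @param tol root tolerance (Å).
#' @return The crossover radius (Å), with attribute `regimes` naming the two
#'   scaling regions.
#' @export
crossover_radius <- function(fit = NULL, R0 = NULL, alpha = NULL, offset = 3,
                             interval = c(1, 200), tol = 1e-6) {
  if (!is.null(fit)) {
    R0 <- fit$R0; alpha <- fit$alpha; offset <- fit$offset
  }
  stopifnot(!is.null(R0), !is.null(alpha), R0 > 0, alpha > 0)
  f <- function(R) log(R) - ((R + offset) / R0)^alpha
  grid <- seq(interval[1], interval[2], length.out = 2048)
  fg <- f(grid)
  sc <- which(fg[-length(fg)] > 0 & fg[-1] <= 0)  # + -> - : upper root
  if (!length(sc))
    stop("no soft-to-hard crossover root in (", interval[1], ", ",
         interval[2], ") Å")
  j <- tail(sc, 1)
  root <- uniroot(f, c(grid[j], grid[j + 1]), tol = tol)$root
  structure(root, regimes = c(below = "power-law", above = "exponential"))
}

#' Mass-radius interpolation table
#'
#' Monotone anchors mapping protein molecular mass to the equivalent
#' spherical probe radius; interpolation is linear in log-log space (so the
#' inverse map is exactly consistent).  The default anchors are the three
#' reference proteins aprotinin (6.5 kDa, 12.75 Å), thioredoxin (11.7 kDa,
#' 15.71 Å) and hemoglobin (64.5 kDa, 30.04 Å).
#'
#' @param mass anchor masses (Da), strictly increasing.
#' @param radius anchor radii (Å), strictly increasing.
#' @return Object of class `mass_radius_table`.
#' @export
mass_radius_table <- function(mass = c(6511, 11700, 64500),
                              radius = c(12.75, 15.71, 30.04)) {
  stopifnot(length(mass) == length(radius), length(mass) >= 2)
  if (any(diff(mass) <= 0) || any(diff(radius) <= 0))
    stop("mass-radius table must be strictly increasing in both columns")
  structure(list(mass = mass, radius = radius), class = "mass_radius_table")
}

.loglog_interp <- function(x0, y0, x) {
  lx0 <- log(x0); ly0 <- log(y0); lx <- log(x)
  n <- length(lx0)
  slope_lo <- (ly0[2] - ly0[1]) / (lx0[2] - lx0[1])
  slope_hi <- (ly0[n] - ly0[n - 1]) / (lx0[n] - lx0[n - 1])
  ly <- approx(lx0, ly0, xout = lx, rule = 2)$y
  below <- lx < lx0[1]; above <- lx > lx0[n]
  ly[below] <- ly0[1] + slope_lo * (lx[below] - lx0[1])
  ly[above] <- ly0[n] + slope_hi * (lx[above] - lx0[n])
  list(y = exp(ly), extrapolated = below | above)
}

#' Convert protein mass to probe radius (and back)
#'
#' @param mass molecular mass(es), Da.
#' @param table a [mass_radius_table()].
#' @return Radius (Å); extrapolation outside the anchor hull is performed
#'   with the boundary log-log slope and flagged with a warning.
#' @export
mass_to_radius <- function(mass, table = mass_radius_table()) {
  out <- .loglog_interp(table$mass, table$radius, mass)
  if (any(out$extrapolated))
    warning("mass outside the table hull; log-log extrapolation used")
  out$y
}

#' @rdname mass_to_radius
#' @param radius probe radius (Å).
#' @export
radius_to_mass <- function(radius, table = mass_radius_table()) {
  out <- .loglog_interp(table$radius, table$mass, radius)
  if (any(out$extrapolated))
    warning("radius outside the table hull; log-log extrapolation used")
  out$y
}
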