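#' Potential of mean force profile container
#'
#' PMFs are stored in units of kBT (`F`), on a 1D z grid along the pore axis.
#' Slabs with zero mean occupancy are hard walls and carry `+Inf`.
#'
#' @param z axial coordinates (Å).
#' @param F free energy (kBT).
#' @param source `"void"` or `"trace"`.
#' @param stderr optional per-point standard error (kBT).
#' @return Object of class `pmf_profile` (a data frame).
#' @export
pmf_profile <- function(z, F, source = "void", stderr = NULL) {
  out <- data.frame(z = z, F = F)
  if (!is.null(stderr)) out$stderr <- stderr
  attr(out, "source") <- source
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Convert kBT to kcal/mol (T = 298.15 K)
#' @param x energy in kBT.
#' @export
kbt_to_kcal <- function(x) x * .kBT_kcal

#' Convert kcal/mol to kBT (T = 298.15 K)
#' @param x energy in kcal/mol.
#' @export
kcal_to_kbt <- function(x) x / .kBT_kcal

#' PMF from ensemble-averaged void occupancy
#'
#' Boltzmann-inverts the mean available-cell count per slab:
#' `F(z_i) = -kBT ln<h(z_i)> + kBT ln(A_c / l_c^2)`.  The additive constant
#' (the fully open confinement cross-section, in cells) makes the PMF zero
#' far from the pore where the whole cylinder is accessible.  Slabs with
#' `<h> = 0` are hard walls (`+Inf`).
#'
#' @param mean_h an [ensemble_average_occupancy()] result, a single
#'   [occupancy_profile()], or a data frame with columns `z` and `h`.
#' @param A_c confinement cross-section (Å^2); taken from the profile
#'   attributes when absent.
#' @param l_c void-cell edge (Å); likewise.
#' @return A [pmf_profile()] (`source = "void"`), with per-point standard
#'   errors propagated from `h_sem` when available.
#' @export
pmf_from_occupancy <- function(mean_h, A_c = NULL, l_c = NULL) {
  A_c <- A_c %||% attr(mean_h, "A_c")
  l_c <- l_c %||% attr(mean_h, "l_c")
  if (is.null(A_c) || is.null(l_c)) stop("A_c and l_c must be available")
  if (A_c <= 0 || l_c <= 0) stop("A_c and l_c must be positive")
  h <- mean_h$h
  if (any(h < 0)) stop("negative occupancy")
  F <- ifelse(h > 0, -log(h) + log(A_c / l_c^2), Inf)
  se <- if (!is.null(mean_h$h_sem)) ifelse(h > 0, mean_h$h_sem / h, NA_real_)
  pmf_profile(mean_h$z, F, source = "void", stderr = se)
}

#' PMF by Boltzmann inversion of a positional trace
#'
#' Histograms the z samples of a centre-of-mass trace and returns
#' `-ln P(z)`, offset so the profile averages to zero over the far-field
#' window.  Empty bins inside the sampled range are flagged (attribute
#' `flagged_bins`) and carry `+Inf` rather than being interpolated.
#'
#' @param z_samples z coordinates (Å), at least 1000 samples.
#' @param bin_width histogram bin width (Å).
#' @param zero_window `|z|` interval (Å) whose mean is taken as the zero of
#'   energy; defaults to 450-550 Å (far outside the pore); when the samples
#'   do not reach it, the outermost covered 10 percent of bins is used.
#' @return A [pmf_profile()] (`source = "trace"`) with binomial per-bin
#'   standard errors.
#' @export
pmf_from_trace <- function(z_samples, bin_width = 10,
                           zero_window = c(450, 550)) {
  n <- length(z_samples)
  if (n < 1000) stop("need at least 1000 samples")
  lo <- floor(min(z_samples) / bin_width) * bin_width
  hi <- ceiling(max(z_samples) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (length(breaks) < 3) stop("trace spans fewer than two bins")
  cnt <- .weighted_tabulate(findInterval(z_samples, breaks,
                                         rightmost.closed = TRUE),
                            rep(1, n), length(breaks) - 1)
  z <- breaks[-length(breaks)] + bin_width / 2
  P <- cnt / (n * bin_width)
  F <- ifelse(cnt > 0, -log(P), Inf)
  se <- ifelse(cnt > 0, sqrt(pmax(1 - cnt / n, 0) / cnt), NA_real_)
  inside <- seq(which(cnt > 0)[1], tail(which(cnt > 0), 1))
  flagged <- inside[cnt[inside] == 0]
  win <- abs(z) >= zero_window[1] & abs(z) <= zero_window[2] & is.finite(F)
  if (!any(win)) {
    k <- max(1, ceiling(0.1 * length(z)))
    win <- rank(-abs(z), ties.method = "first") <= k & is.finite(F)
  }
  F <- F - mean(F[win])
  out <- pmf_profile(z, F, source = "trace", stderr = se)
  attr(out, "flagged_bins") <- z[flagged]
  if (length(flagged))
    warning(length(flagged), " empty bin(s) inside the sampled range")
  out
}

#' Symmetrise a PMF about the pore midplane
#'
#' Averaging is done on probabilities, not free energies:
#' `P_sym(z) = (P(z) + P(-z)) / 2`, then re-inverted, which conserves total
#' probability mass exactly.  The `asymmetry` attribute is the mean
#' point-by-point difference `|F(z) - F(-z)|` over `0 < |z| < asym_half_width`
#' of the unsymmetrised profile (a sampling-quality measure, also used as
#' the barrier uncertainty).
#'
#' @param profile a [pmf_profile()] on a z grid symmetric about 0.
#' @param asym_half_width window for the asymmetry statistic (Å).
#' @return The symmetrised [pmf_profile()] with attribute `asymmetry` (kBT).
#' @export
symmetrize_pmf <- function(profile, asym_half_width = 500) {
  z <- profile$z
  ord <- order(z)
  zr <- z[ord]
  if (max(abs(zr + rev(zr))) > 1e-6 * max(abs(zr), 1))
    stop("z grid is not symmetric about 0")
  Fo <- profile$F[ord]
  P <- exp(-Fo)
  Ps <- (P + rev(P)) / 2
  Fs <- ifelse(Ps > 0, -log(Ps), Inf)
  win <- abs(zr) > 1e-9 & abs(zr) < asym_half_width
  dF <- abs(Fo - rev(Fo))[win]
  asym <- mean(dF[is.finite(dF)])
  out <- profile
  out$F[ord] <- Fs
  attr(out, "asymmetry") <- asym
  attr(out, "source") <- attr(profile, "source")
  out
}

#' PMF barrier height
#'
#' The barrier is the mean PMF over `|z| < half_width` (5 nm about the pore
#' midplane); its uncertainty is the profile's asymmetry statistic (computed
#' on the fly for unsymmetrised profiles).
#'
#' @param profile a [pmf_profile()] covering `|z| < half_width`.
#' @param half_width averaging half-width (Å).
#' @return List with `value` and `uncertainty` (kBT).
#' @export
barrier_height <- function(profile, half_width = 50) {
  sel <- abs(profile$z) < half_width
  if (!any(sel)) stop("profile does not cover |z| < ", half_width)
  if (max(profile$z) < half_width - 1e-9 || min(profile$z) > -half_width + 1e-9)
    stop("profile does not span the barrier window")
  unc <- attr(profile, "asymmetry")
  if (is.null(unc)) {
    unc <- tryCatch(attr(symmetrize_pmf(profile), "asymmetry"),
                    error = function(e) NA_real_)
  }
  list(value = mean(profile$F[sel]), uncertainty = unc)
}

#' Write a PMF as TSV with a JSON metadata sidecar
#' @param profile a [pmf_profile()].
#' @param path output TSV path.
#' @param meta extra metadata fields for the sidecar.
#' @export
write_pmf_tsv <- function(profile, path, meta = list()) {
  df <- data.frame(z = profile$z, F_kBT = profile$F,
                   F_kcal = kbt_to_kcal(profile$F),
                   stderr = if (!is.null(profile$stderr)) profile$stderr
                            else NA_real_)
  write_profile_tsv(df, path,
                    meta = c(list(source = attr(profile, "source"),
                                  asymmetry = attr(profile, "asymmetry")),
                             meta))
}
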