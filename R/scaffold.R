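#' Radial pair-potential table for scaffold interactions
#'
#' Tabulated radial potentials `K_XY(r)` between a mesh bead of residue type X
#' and a scaffold bead of residue type Y.  Kernels are symmetric
#' (`K_XY = K_YX`) and vanish beyond the cutoff.  The default is a single
#' soft-core repulsion `K(r) = eps (1 - r/sigma)^2` for `r < sigma` applied to
#' every ordered pair; species-specific tables can be supplied as a named list
#' with `"X|Y"` keys.
#'
#' @param type_ids character vector of residue-type labels.
#' @param kernels either a single `list(r =, K =)` radial table used for all
#'   pairs, or a named list of such tables with names `"X|Y"`.
#' @param cutoff interaction cutoff (Å); kernels are forced to 0 beyond it.
#' @return An object of class `pair_potential_table`.
#' @export
pair_potential_table <- function(type_ids = .aa1, kernels = NULL, cutoff = 50) {
  stopifnot(cutoff > 0)
  if (is.null(kernels)) {
    r <- seq(0, cutoff, by = 0.5)
    eps <- 2; sigma <- 8
    kernels <- list(r = r, K = ifelse(r < sigma, eps * (1 - r / sigma)^2, 0))
  }
  single <- !is.null(kernels$r)
  chk <- function(k) {
    stopifnot(is.numeric(k$r), is.numeric(k$K), length(k$r) == length(k$K))
    k$K[k$r >= cutoff] <- 0
    k
  }
  kernels <- if (single) chk(kernels) else lapply(kernels, chk)
  structure(list(type_ids = type_ids, kernels = kernels, cutoff = cutoff,
                 single = single),
            class = "pair_potential_table")
}

.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# radial kernel K_XY as a function usable on a distance vector
.kernel_fun <- function(table, X, Y) {
  k <- if (table$single) table$kernels else {
    key1 <- paste(X, Y, sep = "|"); key2 <- paste(Y, X, sep = "|")
    if (!is.null(table$kernels[[key1]])) table$kernels[[key1]]
    else if (!is.null(table$kernels[[key2]])) table$kernels[[key2]]
    else stop("no kernel for pair ", key1)
  }
  function(r) {
    out <- approx(k$r, k$K, xout = r, rule = 2)$y
    out[r >= table$cutoff] <- 0
    out
  }
}

#' Scaffold interaction potential by kernel-density convolution
#'
#' Builds the grid potential felt by a mesh bead of residue type X from a set
#' of scaffold beads: the number density of each scaffold residue type Y
#' (beads binned to voxel centres) convolved with the radial pair kernel
#' `K_XY`, summed over Y.  The convolution is evaluated by zero-padded FFT;
#' `method = "direct"` performs the equivalent explicit sum over beads (the
#' slow reference path).
#'
#' @param beads data frame with columns `x`, `y`, `z` (Å) and `type`
#'   (residue-type label).
#' @param residue_type the probe residue type X.
#' @param kernels a [pair_potential_table()].
#' @param gspec grid geometry from [grid_spec()].
#' @param method `"fft"` or `"direct"`.
#' @return A `scalar_grid` in kcal/mol.
#' @export
build_scaffold_potential <- function(beads, residue_type, kernels, gspec,
                                     method = c("fft", "direct")) {
  method <- match.arg(method)
  g <- scalar_grid(gspec$origin, gspec$spacing, gspec$dim, unit = "kcal/mol")
  if (nrow(beads) == 0) return(g)
  types <- unique(as.character(beads$type))
  if (!kernels$single) {
    for (ty in types) .kernel_fun(kernels, residue_type, ty)  # errors if missing
  }
  d <- g$dim
  # snap beads to voxel indices
  ijk <- sweep(sweep(as.matrix(beads[, c("x", "y", "z")]), 2, g$origin, "-"),
               2, g$spacing, "/")
  ijk <- floor(ijk)
  if (any(ijk < 0) || any(sweep(ijk, 2, d, ">=")))
    stop("scaffold beads outside the grid")
  if (method == "direct") {
    cm <- voxel_center_matrix(g)
    acc <- numeric(nrow(cm))
    centre <- sweep(sweep(ijk + 0.5, 2, g$spacing, "*"), 2, g$origin, "+")
    for (b in seq_len(nrow(beads))) {
      kf <- .kernel_fun(kernels, residue_type, as.character(beads$type[b]))
      dist <- sqrt((cm[, 1] - centre[b, 1])^2 + (cm[, 2] - centre[b, 2])^2 +
                   (cm[, 3] - centre[b, 3])^2)
      acc <- acc + kf(dist)
    }
    g$values <- array(acc, d)
    return(g)
  }
  # FFT path: pad so the cutoff-wide kernel cannot wrap around
  kr <- pmin(ceiling(kernels$cutoff / g$spacing), d)
  P <- vapply(d + kr + 1, nextn, integer(1), factors = c(2, 3, 5))
  offs <- lapply(1:3, function(a) {
    ix <- c(0:kr[a], -(rev(seq_len(P[a] - kr[a] - 1))))
    ix * g$spacing[a]
  })
  dist_arr <- sqrt(outer(outer(offs[[1]]^2, offs[[2]]^2, "+"), offs[[3]]^2, "+"))
  acc <- array(0, P)
  for (ty in types) {
    kf <- .kernel_fun(kernels, residue_type, ty)
    kern <- array(kf(as.numeric(dist_arr)), P)
    sel <- beads$type == ty
    dens <- array(0, P)
    idx1 <- ijk[sel, , drop = FALSE] + 1
    cnt <- tapply(rep(1, sum(sel)),
                  (idx1[, 3] - 1) * P[1] * P[2] + (idx1[, 2] - 1) * P[1] + idx1[, 1],
                  sum)
    dens[as.integer(names(cnt))] <- as.numeric(cnt)
    acc <- acc + Re(fft(fft(dens) * fft(kern), inverse = TRUE)) / prod(P)
  }
  g$values <- array(acc[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])], d)
  g
}
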