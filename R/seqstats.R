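# Sequence descriptors of disordered nup fragments.

# Per-residue net charge at neutral pH (K, R +1; H +0.5; D, E -1) and the
# Kyte-Doolittle hydropathy index rescaled to [0, 1]; both pinned here so the
# charge-to-hydrophobicity statistic is reproducible.
.charge_table <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
                   H = 0.5, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
                   T = 0, W = 0, Y = 0, V = 0)
.kd_raw <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
             E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
             M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
             Y = -1.3, V = 4.2)
.kd_norm <- (.kd_raw + 4.5) / 9

#' Charge-to-hydrophobicity ratio of a sequence
#'
#' `|mean net charge per residue| / mean normalised hydrophobicity`, a
#' composition-only statistic (Uversky-style): net charge +1 for K/R, +0.5
#' for H, -1 for D/E; hydrophobicity is the Kyte-Doolittle index rescaled to
#' `[0, 1]`.  Disordered FG-nup fragments typically score below 0.3.
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @return Dimensionless ratio.
#' @export
charge_hydrophobicity_ratio <- function(sequence) {
  aa <- if (length(sequence) == 1) strsplit(sequence, "")[[1]] else sequence
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), names(.charge_table))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  q <- abs(mean(.charge_table[aa]))
  h <- mean(.kd_norm[aa])
  if (h == 0) return(Inf)
  q / h
}

#' The pinned hydrophobicity/charge scale
#' @return Data frame with one row per amino acid: `charge`, `kd`,
#'   `hydrophobicity` (normalised).
#' @export
residue_scales <- function() {
  data.frame(aa = names(.charge_table), charge = unname(.charge_table),
             kd = unname(.kd_raw), hydrophobicity = unname(.kd_norm))
}
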