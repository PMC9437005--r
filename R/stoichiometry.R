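#' FG-nup stoichiometry specification
#'
#' A stoichiometry lists the disordered chain species of an NPC model: copy
#' number, inclusive residue range of the disordered fragment, which terminus
#' is anchored to the scaffold (`"N"`, `"C"`, or `"both"` for flexible linker
#' segments restrained at both ends) and, optionally, per-copy anchor
#' coordinates.  When no anchors are given they are generated by
#' [anchor_layout()] at ensemble-build time.
#'
#' @param species data frame with columns `name`, `copies`, `first`, `last`,
#'   `anchor_end`, and optionally `sequence` (one-letter amino-acid string).
#' @param anchors optional named list: per species a `copies`-by-3 matrix of
#'   anchor coordinates (Å); species anchored at both ends additionally take a
#'   `copies`-by-3 matrix in `targets`.
#' @param targets optional named list of second-anchor coordinates for
#'   `"both"`-ended species.
#' @param name label for the stoichiometry.
#' @return An object of class `stoichiometry`.
#' @export
stoichiometry <- function(species, anchors = NULL, targets = NULL,
                          name = "custom") {
  species <- as.data.frame(species)
  need <- c("name", "copies", "first", "last", "anchor_end")
  if (!all(need %in% names(species)))
    stop("species must have columns: ", paste(need, collapse = ", "))
  if (!"sequence" %in% names(species)) species$sequence <- NA_character_
  species$copies <- as.integer(species$copies)
  if (any(species$copies <= 0)) stop("copy numbers must be positive")
  species$length <- abs(species$last - species$first) + 1L
  sl <- !is.na(species$sequence)
  if (any(sl & nchar(species$sequence) < species$length))
    stop("sequence shorter than residue range")
  if (!is.null(anchors)) {
    for (sp in names(anchors))
      if (nrow(anchors[[sp]]) != species$copies[species$name == sp])
        stop("anchor count must equal copy number for ", sp)
  }
  structure(list(name = name, species = species, anchors = anchors,
                 targets = targets),
            class = "stoichiometry")
}

# Disordered-fragment listings of the three built-in NPC models.
.builtin_stoich <- function(name) {
  sp <- switch(name,
    lin2016 = data.frame(
      name   = c("Nup145N", "Nic96", "Nsp1", "Nup49", "Nup57"),
      copies = c(32L, 32L, 32L, 32L, 32L),
      first  = c(1L, 1L, 1L, 1L, 1L),
      last   = c(732L, 139L, 467L, 245L, 77L),
      anchor_end = "C"),
    kim2018 = data.frame(
      name   = c("Nsp1", "Nup159", "Nup116", "Nup100", "Nup49",
                 "Nup57", "Nup145N", "Nup1", "Nup60"),
      copies = c(48L, 16L, 16L, 16L, 32L, 32L, 16L, 8L, 16L),
      first  = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
      last   = c(620L, 760L, 760L, 560L, 220L, 220L, 220L, 720L, 120L),
      anchor_end = "C"),
    kim2018plus = data.frame(
      name   = c("Nsp1", "Nup159", "Nup116", "Nup100", "Nup49", "Nup57",
                 "Nup145N", "Nup1", "Nup60", "Nup42", "Nup2",
                 "Nup116_linker", "Nup100_linker", "Nup145N_linker"),
      copies = c(48L, 16L, 16L, 16L, 32L, 32L, 16L, 8L, 16L, 8L, 16L,
                 16L, 16L, 16L),
      first  = c(1L, 382L, 1L, 1L, 1L, 1L, 1L, 357L, 420L, 1L, 1L,
                 561L, 761L, 221L),
      last   = c(620L, 1141L, 760L, 560L, 220L, 220L, 220L, 1076L, 539L,
                 382L, 720L, 815L, 965L, 458L),
      anchor_end = c("N", "N", "N", "N", "N", "N", "N", "C", "C", "N", "N",
                     "both", "both", "both")),
    stop("unknown stoichiometry: ", name))
  stoichiometry(sp, name = name)
}

#' Load a stoichiometry by name or from a YAML/JSON file
#'
#' Built-in names: `"lin2016"` (160 chains: 32 copies each of Nup145N, Nic96,
#' Nsp1, Nup49, Nup57), `"kim2018"` (200 chains, 9 yeast species) and
#' `"kim2018plus"` (kim2018 plus Nup42, Nup2 and the Nup116/Nup100/Nup145N
#' linker segments; about 30 percent more residues).  A file must contain a
#' `species` table (list of records) and may carry `anchors`.
#'
#' @param name built-in name or path to a `.yaml`/`.yml`/`.json` file.
#' @return A [stoichiometry()].
#' @export
load_stoichiometry <- function(name) {
  if (name %in% c("lin2016", "kim2018", "kim2018plus"))
    return(.builtin_stoich(name))
  if (!file.exists(name)) stop("unknown stoichiometry name or missing file: ", name)
  spec <- if (grepl("\\.ya?ml$", name)) yaml::read_yaml(name)
          else jsonlite::read_json(name, simplifyVector = TRUE)
  species <- as.data.frame(do.call(rbind, lapply(spec$species, function(s)
    as.data.frame(s, stringsAsFactors = FALSE))))
  if (is.data.frame(spec$species)) species <- spec$species
  anchors <- if (!is.null(spec$anchors))
    lapply(spec$anchors, function(a) matrix(unlist(a), ncol = 3, byrow = TRUE))
  targets <- if (!is.null(spec$targets))
    lapply(spec$targets, function(a) matrix(unlist(a), ncol = 3, byrow = TRUE))
  stoichiometry(species, anchors = anchors, targets = targets,
                name = spec$name %||% basename(name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chain and residue totals of a stoichiometry
#' @param spec a [stoichiometry()].
#' @return Named numeric vector `c(n_chains =, n_residues =)`.
#' @export
chain_and_residue_totals <- function(spec) {
  c(n_chains = sum(spec$species$copies),
    n_residues = sum(spec$species$copies * spec$species$length))
}

#' Remove one species from a stoichiometry
#'
#' Used to build deletion variants of an NPC model (the mesh minus one
#' FG-nup species).
#'
#' @param spec a [stoichiometry()].
#' @param species_name name of the species to drop.
#' @export
delete_species <- function(spec, species_name) {
  if (!species_name %in% spec$species$name)
    stop("no such species: ", species_name)
  keep <- spec$species$name != species_name
  stoichiometry(spec$species[keep, , drop = FALSE],
                anchors = spec$anchors[setdiff(names(spec$anchors), species_name)],
                targets = spec$targets[setdiff(names(spec$targets), species_name)],
                name = paste0(spec$name, "-d", species_name))
}

# z level (Å) at which each built-in species is tethered; channel nups sit at
# the inner ring, adaptor/outer species towards the outer rings.
.builtin_anchor_z <- c(
  Nsp1 = 15, Nup49 = 0, Nup57 = -15, Nic96 = 35, Nup145N = 85,
  Nup159 = 70, Nup116 = 55, Nup100 = -55, Nup1 = -85, Nup60 = -70,
  Nup42 = 60, Nup2 = -60,
  Nup116_linker = 55, Nup100_linker = -55, Nup145N_linker = 85)

#' Generate anchor coordinates on scaffold rings
#'
#' Places the copies of each species evenly on a circle of the given radius,
#' split between mirror-symmetric +z/-z rings at a species-specific tether
#' height (built-in table; unknown species alternate through generic levels).
#' For `"both"`-ended linker species the second anchor is placed one half
#' angular step away on the same ring.
#'
#' @param spec a [stoichiometry()].
#' @param ring_radius anchor-ring radius (Å).
#' @param z_levels optional named vector overriding the per-species tether z.
#' @param mirror place half the copies at -z (default TRUE; species with a
#'   negative built-in level keep their sign).
#' @return The stoichiometry with `anchors` (and `targets`) populated.
#' @export
anchor_layout <- function(spec, ring_radius = 220, z_levels = NULL,
                          mirror = TRUE) {
  generic <- c(20, -20, 50, -50, 80, -80)
  anchors <- list(); targets <- list()
  for (i in seq_len(nrow(spec$species))) {
    sp <- spec$species[i, ]
    z0 <- if (!is.null(z_levels) && sp$name %in% names(z_levels))
      z_levels[[sp$name]]
    else if (sp$name %in% names(.builtin_anchor_z)) .builtin_anchor_z[[sp$name]]
    else generic[(i - 1) %% length(generic) + 1]
    n <- sp$copies
    ang <- 2 * pi * (seq_len(n) - 1) / n + 2 * pi * (i - 1) / (8 * nrow(spec$species))
    zz <- rep(z0, n)
    if (mirror && n %% 2 == 0) zz[seq(2, n, by = 2)] <- -z0
    anchors[[sp$name]] <- cbind(ring_radius * cos(ang),
                                ring_radius * sin(ang), zz)
    if (sp$anchor_end == "both") {
      ang2 <- ang + pi / n
      targets[[sp$name]] <- cbind(ring_radius * cos(ang2),
                                  ring_radius * sin(ang2), zz)
    }
  }
  spec$anchors <- anchors
  spec$targets <- targets
  spec
}
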