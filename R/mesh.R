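#' Bead-per-residue disordered chain
#'
#' @param xyz n-by-3 coordinate matrix (Å), one bead per residue, in growth
#'   order starting from the anchored bead.
#' @param species species label.
#' @param anchor_index index of the restrained bead (1: grown from the anchor).
#' @param bead_radius bead radius (Å).
#' @param residue_types optional per-bead one-letter amino-acid labels.
#' @param anchor_end which terminus the first bead represents
#'   (`"N"`, `"C"`, `"both"`).
#' @return An object of class `bead_chain`.
#' @export
bead_chain <- function(xyz, species = "chain", anchor_index = 1L,
                       bead_radius = 3, residue_types = NULL,
                       anchor_end = "C") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  structure(list(species = species, xyz = xyz,
                 anchor_index = as.integer(anchor_index),
                 bead_radius = bead_radius, residue_types = residue_types,
                 anchor_end = anchor_end),
            class = "bead_chain")
}

#' One instantaneous mesh configuration
#'
#' @param chains list of [bead_chain()] objects.
#' @param frame_id integer frame label (unique within an ensemble).
#' @param box optional periodic extents (Å); connectivity and void analysis
#'   treat the lattice as non-periodic regardless.
#' @return An object of class `mesh_config`.
#' @export
mesh_config <- function(chains, frame_id = 1L, box = NULL) {
  structure(list(chains = chains, frame_id = as.integer(frame_id), box = box),
            class = "mesh_config")
}

#' All bead coordinates of a mesh as a matrix
#' @param mesh a [mesh_config()].
#' @return List with `xyz` (n-by-3), `chain` (integer id per bead), `species`
#'   (label per bead).
#' @export
mesh_coords <- function(mesh) {
  xyz <- do.call(rbind, lapply(mesh$chains, `[[`, "xyz"))
  nb <- vapply(mesh$chains, function(ch) nrow(ch$xyz), integer(1))
  list(xyz = xyz,
       chain = rep(seq_along(mesh$chains), nb),
       species = rep(vapply(mesh$chains, `[[`, character(1), "species"), nb))
}

#' @export
print.mesh_config <- function(x, ...) {
  nb <- sum(vapply(x$chains, function(ch) nrow(ch$xyz), integer(1)))
  cat(sprintf("<mesh_config> frame %d: %d chains, %d beads\n",
              x$frame_id, length(x$chains), nb))
  invisible(x)
}

.placement_failure <- function(index, species = NULL) {
  stop(structure(class = c("placement_failure", "error", "condition"),
                 list(message = sprintf(
                   "chain growth stalled at residue %d%s", index,
                   if (is.null(species)) "" else paste0(" (", species, ")")),
                   call = NULL, fail_index = index)))
}

#' Grow one anchored self-avoiding chain
#'
#' Generates a bead-per-residue chain as a self-avoiding random walk grown
#' from the anchor: consecutive beads exactly `bond` apart, no bead within
#' `clash` of a bead of another chain, non-bonded beads of the same chain at
#' least `intra` apart, and beads at least `anchor_skip` residues from the
#' anchor keeping `scaffold_clearance` away from every excluded voxel of the
#' steric grids (summarised by a clearance grid, see [build_clearance_grid()]).
#' With a `target`, growth is conditioned on terminating exactly at the
#' second anchor (flexible linker segments).
#'
#' @param anchor length-3 anchor coordinate (Å).
#' @param length number of residues (beads).
#' @param obstacles optional n-by-3 matrix of beads of other chains.
#' @param clearance optional clearance grid: a `scalar_grid` whose values are
#'   the distance (Å) to the nearest sterically excluded voxel.
#' @param target optional length-3 coordinate of the second anchor.
#' @param bond bond length (Å).
#' @param clash inter-chain clash distance (Å).
#' @param intra intra-chain excluded-volume distance for non-bonded beads (Å);
#'   defaults to twice the bead radius.
#' @param bead_radius bead radius (Å).
#' @param scaffold_clearance minimum distance to excluded voxels (Å).
#' @param anchor_skip residues within this of the anchor are exempt from the
#'   scaffold clearance.
#' @param species species label for the returned chain.
#' @param max_trials direction draws per bead before backtracking.
#' @param max_backtrack total backtracking steps before signalling a
#'   placement failure.
#' @param seed optional integer; when given the chain is a deterministic
#'   function of it.
#' @return A [bead_chain()].
#' @export
generate_chain <- function(anchor, length, obstacles = NULL, clearance = NULL,
                           target = NULL, bond = 3.8, clash = 8,
                           intra = NULL, bead_radius = 3,
                           scaffold_clearance = 8, anchor_skip = 3,
                           species = "chain", max_trials = 80,
                           max_backtrack = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(intra)) intra <- 2 * bead_radius
  if (is.null(obstacles)) obstacles <- matrix(numeric(0), ncol = 3)
  obstacles <- matrix(as.numeric(obstacles), ncol = 3)
  cg <- if (!is.null(clearance))
    list(origin = clearance$origin, spacing = clearance$spacing,
         dim = clearance$dim, values = as.numeric(clearance$values))
  res <- cpp_saw_chain(as.numeric(anchor), target, as.integer(length),
                       bond, clash, intra, obstacles, cg,
                       scaffold_clearance, as.integer(anchor_skip),
                       as.integer(max_trials), as.integer(max_backtrack))
  if (res$status != "ok") .placement_failure(res$fail_index, species)
  bead_chain(res$coords, species = species, bead_radius = bead_radius)
}

#' Clearance grid from steric exclusion grids
#'
#' Combines one or more potential grids into a single grid holding the
#' distance (Å) from each voxel centre to the nearest voxel where any of the
#' potentials exceeds `threshold` (the excluded set).  Voxels of the excluded
#' set get distance 0.  Used both by the chain generator (scaffold clearance)
#' and by the void analysis.
#'
#' @param grids list of `scalar_grid` potentials sharing one geometry.
#' @param threshold exclusion threshold; any value above it marks a voxel
#'   excluded.
#' @return A `scalar_grid` of distances (Å), `Inf` when nothing is excluded.
#' @export
build_clearance_grid <- function(grids, threshold = 1e-9) {
  stopifnot(length(grids) >= 1)
  g0 <- grids[[1]]
  mask <- Reduce(`|`, lapply(grids, function(g) {
    stopifnot(all(g$dim == g0$dim))
    as.numeric(g$values) > threshold
  }))
  d2 <- cpp_edt_sq(mask, g0$dim, g0$spacing)
  vals <- sqrt(d2)
  vals[d2 >= 1e29] <- Inf
  out <- scalar_grid(g0$origin, g0$spacing, g0$dim, array(vals, g0$dim),
                     unit = "angstrom")
  attr(out, "excluded") <- array(mask, g0$dim)
  out
}

# deterministic per-chain seed derived from the ensemble seed, the frame and
# the chain identity (so deletion variants reuse identical streams)
.chain_seed <- function(seed, frame, species, copy) {
  h <- sum(utf8ToInt(species) * seq_along(utf8ToInt(species)))
  (seed * 7919 + frame * 104729 + h * 131 + copy * 17) %% 2147483000L
}

#' Build a synthetic mesh ensemble
#'
#' Draws `n_frames` independent mesh configurations for a stoichiometry:
#' every chain is regenerated per frame as an anchored self-avoiding walk
#' (optionally followed by excluded-volume crankshaft relaxation), species in
#' listed order, chains avoiding all previously placed beads.  Each chain
#' consumes a private seed derived from `seed`, the frame and its identity,
#' so rebuilding a stoichiometry minus its last-listed species regenerates
#' the remaining chains identically.
#'
#' @param spec a [stoichiometry()]; anchors are generated by [anchor_layout()]
#'   when absent.
#' @param grids list of steric `scalar_grid` potentials (envelope, scaffold);
#'   chains keep [generate_chain()]'s scaffold clearance from their excluded
#'   voxels.  May be empty.
#' @param n_frames number of configurations.
#' @param relax_steps crankshaft Monte-Carlo moves applied to each frame
#'   after growth (0 = pure self-avoiding-walk frames).
#' @param seed integer ensemble seed.
#' @param ring_radius anchor-ring radius passed to [anchor_layout()].
#' @param chain_retries reseeded regrowth attempts before a placement failure
#'   propagates.
#' @inheritParams generate_chain
#' @return List of [mesh_config()] objects.
#' @export
build_mesh_ensemble <- function(spec, grids = list(), n_frames = 1,
                                relax_steps = 0, seed = 1,
                                ring_radius = 220, bond = 3.8, clash = 8,
                                bead_radius = 3, scaffold_clearance = 8,
                                chain_retries = 25) {
  if (is.null(spec$anchors)) spec <- anchor_layout(spec, ring_radius)
  clearance <- if (length(grids)) build_clearance_grid(grids)
  intra <- 2 * bead_radius
  lapply(seq_len(n_frames), function(f) {
    chains <- list()
    obstacles <- matrix(numeric(0), ncol = 3)
    for (i in seq_len(nrow(spec$species))) {
      sp <- spec$species[i, ]
      for (k in seq_len(sp$copies)) {
        anchor <- spec$anchors[[sp$name]][k, ]
        target <- if (sp$anchor_end == "both") spec$targets[[sp$name]][k, ]
        ch <- NULL
        for (try in seq_len(chain_retries)) {
          sd <- .chain_seed(seed, f, sp$name, k + (try - 1) * 100003)
          ch <- tryCatch(
            generate_chain(anchor, sp$length, obstacles, clearance,
                           target = target, bond = bond, clash = clash,
                           intra = intra, bead_radius = bead_radius,
                           scaffold_clearance = scaffold_clearance,
                           species = sp$name, seed = sd),
            placement_failure = function(e) e)
          if (!inherits(ch, "condition")) break
        }
        if (inherits(ch, "condition")) stop(ch)
        if (!is.na(sp$sequence) && nzchar(sp$sequence))
          ch$residue_types <- strsplit(substr(sp$sequence, 1, sp$length), "")[[1]]
        ch$anchor_end <- sp$anchor_end
        chains[[length(chains) + 1]] <- ch
        obstacles <- rbind(obstacles, ch$xyz)
      }
    }
    mesh <- mesh_config(chains, frame_id = f)
    if (relax_steps > 0) mesh <- relax_mesh(mesh, grids, relax_steps,
                                            clash = clash,
                                            scaffold_clearance = scaffold_clearance,
                                            seed = seed + f)
    mesh
  })
}

#' Excluded-volume crankshaft relaxation of a mesh
#'
#' Applies bond-preserving crankshaft rotations to random non-anchored beads,
#' accepting any move that keeps all clash, excluded-volume and scaffold
#' constraints satisfied (athermal hard-core Monte Carlo).
#'
#' @param mesh a [mesh_config()].
#' @param grids steric grids as in [build_mesh_ensemble()].
#' @param steps number of attempted moves.
#' @inheritParams build_mesh_ensemble
#' @param anchor_skip see [generate_chain()].
#' @param seed optional integer seed.
#' @return The relaxed [mesh_config()].
#' @export
relax_mesh <- function(mesh, grids = list(), steps = 1000, clash = 8,
                       scaffold_clearance = 8, anchor_skip = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mc <- mesh_coords(mesh)
  anchor_flag <- integer(nrow(mc$xyz))
  anchor_dist <- integer(nrow(mc$xyz))
  off <- 0L
  for (ch in mesh$chains) {
    n <- nrow(ch$xyz)
    anchor_flag[off + ch$anchor_index] <- 1L
    if (identical(ch$anchor_end, "both")) anchor_flag[off + n] <- 1L
    anchor_dist[off + seq_len(n)] <- abs(seq_len(n) - ch$anchor_index)
    off <- off + n
  }
  clearance <- if (length(grids)) build_clearance_grid(grids)
  cg <- if (!is.null(clearance))
    list(origin = clearance$origin, spacing = clearance$spacing,
         dim = clearance$dim, values = as.numeric(clearance$values))
  intra <- 2 * mesh$chains[[1]]$bead_radius
  new_xyz <- cpp_relax_mesh(mc$xyz, mc$chain, anchor_flag, clash, intra,
                            cg, scaffold_clearance, anchor_dist,
                            as.integer(anchor_skip), as.integer(steps))
  off <- 0L
  for (i in seq_along(mesh$chains)) {
    n <- nrow(mesh$chains[[i]]$xyz)
    mesh$chains[[i]]$xyz <- new_xyz[off + seq_len(n), , drop = FALSE]
    off <- off + n
  }
  mesh
}

#' Fraction of chains making at least one inter-chain contact
#'
#' A contact is two residues of different chains within `cutoff` of one
#' another.  Cell-list accelerated.
#'
#' @param mesh a [mesh_config()] with at least two chains.
#' @param cutoff contact distance (Å).
#' @return List with `by_species` (named fractions) and `overall`.
#' @export
interchain_contact_fraction <- function(mesh, cutoff = 8) {
  if (length(mesh$chains) < 2) stop("need at least two chains")
  mc <- mesh_coords(mesh)
  hit <- cpp_interchain_contact(mc$xyz, mc$chain, cutoff)
  chain_hit <- tapply(hit, mc$chain, any)
  chain_species <- vapply(mesh$chains, `[[`, character(1), "species")
  by_species <- tapply(as.numeric(chain_hit), chain_species, mean)
  list(by_species = by_species[unique(chain_species)],
       overall = mean(chain_hit))
}

#' Radius of gyration of a chain
#' @param chain a [bead_chain()] (or n-by-3 matrix).
#' @return Rg (Å).
#' @export
radius_of_gyration <- function(chain) {
  xyz <- if (inherits(chain, "bead_chain")) chain$xyz else chain
  sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz), "-")^2)))
}
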