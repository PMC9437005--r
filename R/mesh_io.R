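# Ensemble I/O.  Per-frame extended XYZ is the primary on-disk ensemble
# format (species and chain id columns survive the round trip); single
# configurations can also be written as CA-style PDB through bio3d, with the
# chain id stored in the B-factor column and the species table in REMARKs.

#' Write a mesh ensemble as extended XYZ frames
#'
#' One block per frame: bead count, a `frame=<id>` comment, then
#' `species chain_index x y z` records.
#'
#' @param ensemble list of [mesh_config()] (or a single one).
#' @param path output path.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  if (inherits(ensemble, "mesh_config")) ensemble <- list(ensemble)
  con <- file(path, "wt")
  on.exit(close(con))
  for (mesh in ensemble) {
    mc <- mesh_coords(mesh)
    writeLines(c(sprintf("%d", nrow(mc$xyz)),
                 sprintf("frame=%d", mesh$frame_id)), con)
    writeLines(sprintf("%s %d %.6f %.6f %.6f", mc$species, mc$chain,
                       mc$xyz[, 1], mc$xyz[, 2], mc$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a mesh ensemble from extended XYZ frames
#' @param path input path.
#' @param bead_radius bead radius to attach (Å).
#' @return List of [mesh_config()].
#' @export
read_ensemble_xyz <- function(path, bead_radius = 3) {
  lines <- readLines(path)
  out <- list(); i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    fid <- as.integer(sub(".*frame=", "", lines[i + 1]))
    rec <- strsplit(trimws(lines[i + 1 + seq_len(n)]), "[ \t]+")
    species <- vapply(rec, `[[`, character(1), 1)
    chain <- as.integer(vapply(rec, `[[`, character(1), 2))
    xyz <- matrix(as.numeric(t(vapply(rec, function(r) r[3:5], character(3)))),
                  ncol = 3)
    chains <- lapply(unique(chain), function(cid) {
      sel <- chain == cid
      bead_chain(xyz[sel, , drop = FALSE], species = species[sel][1],
                 bead_radius = bead_radius)
    })
    out[[length(out) + 1]] <- mesh_config(chains, frame_id = fid)
    i <- i + 2 + n
  }
  out
}

#' Write one mesh configuration as a CA-style PDB file
#'
#' One CA atom per bead through [bio3d::write.pdb()]; the chain index is
#' stored in the B-factor column and the chain-to-species map in REMARK 300
#' lines (species labels exceed the fixed-width PDB fields).
#'
#' @param mesh a [mesh_config()].
#' @param path output path.
#' @export
write_mesh_pdb <- function(mesh, path) {
  mc <- mesh_coords(mesh)
  n <- nrow(mc$xyz)
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = as.numeric(t(mc$xyz)),
                   resno = unlist(lapply(mesh$chains,
                                         function(ch) seq_len(nrow(ch$xyz)))),
                   resid = rep("GLY", n), elety = rep("CA", n),
                   chain = rep(LETTERS[(seq_along(mesh$chains) - 1) %% 26 + 1],
                               vapply(mesh$chains, function(ch) nrow(ch$xyz),
                                      integer(1))),
                   b = mc$chain, o = rep(1, n))
  sp <- vapply(mesh$chains, `[[`, character(1), "species")
  remarks <- sprintf("REMARK 300 CHAIN %d SPECIES %s FRAME %d",
                     seq_along(mesh$chains), sp, mesh$frame_id)
  writeLines(c(remarks, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

#' Read a CA-style PDB mesh written by [write_mesh_pdb()]
#' @param path input path.
#' @param bead_radius bead radius to attach (Å).
#' @return A [mesh_config()].
#' @export
read_mesh_pdb <- function(path, bead_radius = 3) {
  raw <- readLines(path)
  rem <- raw[grepl("^REMARK 300 CHAIN", raw)]
  spmap <- NULL; fid <- 1L
  if (length(rem)) {
    parts <- strsplit(rem, "[ \t]+")   # REMARK 300 CHAIN <i> SPECIES <s> FRAME <f>
    spmap <- setNames(vapply(parts, `[[`, character(1), 6),
                      vapply(parts, `[[`, character(1), 4))
    fid <- as.integer(parts[[1]][8])
  }
  pdb <- bio3d::read.pdb(path)
  cid <- pdb$atom$b
  xyz <- as.matrix(pdb$atom[, c("x", "y", "z")])
  chains <- lapply(sort(unique(cid)), function(ci) {
    sel <- cid == ci
    sp <- if (!is.null(spmap)) spmap[[as.character(as.integer(ci))]] else "chain"
    bead_chain(xyz[sel, , drop = FALSE], species = sp,
               bead_radius = bead_radius)
  })
  mesh_config(chains, frame_id = fid)
}
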