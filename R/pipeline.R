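#' Stokes-Einstein bulk diffusivity of a spherical probe
#'
#' `D0 = kB T / (6 pi eta R)` in Å^2/us.  An approximation standing in for
#' bead-model hydrodynamics calculations; real proteins diffuse 10-30 percent
#' slower than the equivalent sphere.
#'
#' @param radius probe radius (Å).
#' @param temperature K.
#' @param viscosity solvent viscosity (Pa s).
#' @export
stokes_einstein_D0 <- function(radius, temperature = 298.15,
                               viscosity = 8.9e-4) {
  stopifnot(all(radius > 0))
  kB <- 1.380649e-23
  (kB * temperature / (6 * pi * viscosity * radius * 1e-10)) * 1e14
}

#' MFPT of one probe radius from an averaged occupancy profile
#'
#' Convenience wrapper chaining [pmf_from_occupancy()],
#' [diffusivity_profile()], [transition_rates()] and [solve_fpt()].  Slabs
#' with zero mean occupancy block the channel completely; the MFPT is then
#' infinite and returned as `Inf` without running the solver.
#'
#' @param avg an [ensemble_average_occupancy()] result.
#' @param D0 bulk diffusivity (Å^2/us).
#' @param model local diffusion model, see [diffusivity_profile()].
#' @param d solver node spacing (Å).
#' @param z_min,z_max,z_start solver geometry (Å).
#' @param tol_resid terminal survival.
#' @param ... passed to [solve_fpt()].
#' @return List with `tau`, `fpt` (the [solve_fpt()] result or NULL), `pmf`
#'   and `dprof`.
#' @export
mfpt_from_occupancy <- function(avg, D0, model = "reguera_rubi", d = 2,
                                z_min = -600, z_max = 200, z_start = -200,
                                tol_resid = 1e-3, ...) {
  # slabs outside the solver domain play no role; keep only the covered part
  # (outside the profile the solver falls back to the far field V = 0, D0)
  keep <- avg$z >= z_min - 1e-9 & avg$z <= z_max + 1e-9
  acov <- attr(avg, "A_c"); lcov <- attr(avg, "l_c")
  avg <- avg[keep, , drop = FALSE]
  attr(avg, "A_c") <- acov; attr(avg, "l_c") <- lcov
  pmf <- pmf_from_occupancy(avg)
  if (any(avg$h <= 0))
    return(list(tau = Inf, fpt = NULL, pmf = pmf, dprof = NULL))
  dprof <- diffusivity_profile(avg, D0 = D0, model = model)
  rates <- transition_rates(dprof, pmf, d = d, z_min = z_min, z_max = z_max)
  fpt <- solve_fpt(rates, z_start = z_start, tol_resid = tol_resid, ...)
  list(tau = fpt$tau, fpt = fpt, pmf = pmf, dprof = dprof)
}

.default_config <- function() {
  list(
    stoichiometry = "toy8",
    ring_radius = 60,
    n_frames = 4,
    seed = 1,
    relax_steps = 0,
    confinement = list(radius = 100, height = 500, spring_k = 0.01),
    envelope = NULL,                 # list(B=, flatten_z=,...) to enable
    void = list(voxel_size = 4, z_half = 220, slab_height = 4,
                profile_radius = NULL),
    percolation = list(voxel_size = 3, source_z = 200, sink_z = -200,
                       connectivity = 6),
    probe_radii = c(4, 8, 12, 16, 20, 24, 28),
    transport = list(model = "reguera_rubi", d = 2, z_min = -600,
                     z_max = 200, z_start = -200, tol_resid = 1e-3),
    outdir = "npcvoid-out")
}

# small built-in stoichiometry for pipeline smoke runs: 8 chains of 60
# residues anchored on one ring
.toy_stoich <- function() {
  stoichiometry(data.frame(name = "ToyNup", copies = 8L, first = 1L,
                           last = 60L, anchor_end = "C"), name = "toy8")
}

#' Run the full void-percolation-transport pipeline
#'
#' Configuration-driven orchestration: builds the steric grids and a
#' synthetic mesh ensemble, runs void analysis over a probe-radius sweep,
#' derives occupancy-averaged PMFs and Fick-Jacobs MFPTs, estimates the
#' percolation curve on a finer lattice, fits the scaling law and writes
#' every artifact (TSV/JSON) plus a checksummed manifest.  Identical
#' configuration and seeds yield identical outputs.
#'
#' @param config a named list (merged over the defaults) or the path of a
#'   YAML/JSON file containing one.  Main fields: `stoichiometry` (name,
#'   path, or `"toy8"`), `n_frames`, `seed`, `probe_radii`, `confinement`
#'   (radius/height/spring_k), `void` (voxel_size, z_half, slab_height),
#'   `percolation` (voxel_size, source_z, sink_z, connectivity),
#'   `transport` (model, d, z_min, z_max, z_start), `outdir`.
#' @return The manifest, invisibly: a list with `files` (path, md5), the
#'   evaluated `config`, `results` (tau table, scaling fit, percolation
#'   radius) and the package version.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(.default_config(), config)
  # ---- validation before any compute ----
  spec <- if (identical(cfg$stoichiometry, "toy8")) .toy_stoich()
          else load_stoichiometry(cfg$stoichiometry)
  stopifnot(cfg$n_frames >= 1, length(cfg$probe_radii) >= 1,
            is.numeric(cfg$seed))
  if (is.null(cfg$void$profile_radius))
    cfg$void$profile_radius <- cfg$confinement$radius
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)

  # ---- stage: grids ----
  stage <- "grids"
  conf_spec <- confinement_spec(cfg$confinement$radius, cfg$confinement$height,
                                cfg$confinement$spring_k)
  ext <- cfg$confinement$radius + 40
  vgs <- void_grid_spec(lower = c(-ext, -ext, -cfg$void$z_half),
                        upper = c(ext, ext, cfg$void$z_half),
                        voxel_size = cfg$void$voxel_size,
                        slab_height = cfg$void$slab_height,
                        profile_radius = cfg$void$profile_radius)
  gsp <- list(origin = vgs$origin, spacing = vgs$spacing, dim = vgs$dim)
  grids <- list(confinement = build_confinement_grid(conf_spec, gsp))
  if (!is.null(cfg$envelope))
    grids$envelope <- build_envelope_grid(do.call(envelope_spec, cfg$envelope),
                                          gsp)

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- stage: mesh ----
  ensemble <- run_stage("mesh", {
    build_mesh_ensemble(spec, grids = grids, n_frames = cfg$n_frames,
                        relax_steps = cfg$relax_steps, seed = cfg$seed,
                        ring_radius = cfg$ring_radius)
  })
  xyz_path <- file.path(cfg$outdir, "ensemble.xyz")
  write_ensemble_xyz(ensemble, xyz_path); emit(xyz_path)

  # ---- stage: void analysis + PMF + MFPT per radius ----
  taus <- rep(NA_real_, length(cfg$probe_radii))
  run_stage("void", {
    rmaps <- lapply(ensemble, compute_rmax, exclusion_grids = grids,
                    spec = vgs)
    for (j in seq_along(cfg$probe_radii)) {
      rp <- cfg$probe_radii[j]
      profs <- lapply(rmaps, function(rm)
        occupancy_profile(classify_voids(rm, rp), vgs))
      avg <- ensemble_average_occupancy(profs)
      occ_path <- file.path(cfg$outdir, sprintf("occupancy_rp%05.1f.tsv", rp))
      write_profile_tsv(as.data.frame(avg), occ_path,
                        meta = list(probe_radius = rp,
                                    n_frames = length(profs),
                                    A_c = attr(avg, "A_c"),
                                    l_c = attr(avg, "l_c")))
      emit(occ_path)
      mf <- mfpt_from_occupancy(avg, D0 = stokes_einstein_D0(rp),
                                model = cfg$transport$model,
                                d = cfg$transport$d,
                                z_min = cfg$transport$z_min,
                                z_max = cfg$transport$z_max,
                                z_start = cfg$transport$z_start,
                                tol_resid = cfg$transport$tol_resid)
      taus[j] <- mf$tau
      pmf_path <- file.path(cfg$outdir, sprintf("pmf_rp%05.1f.tsv", rp))
      write_pmf_tsv(mf$pmf, pmf_path, meta = list(probe_radius = rp))
      emit(pmf_path)
    }
  })
  tau_df <- data.frame(probe_radius = cfg$probe_radii, tau = taus,
                       D0 = stokes_einstein_D0(cfg$probe_radii))
  tau_path <- file.path(cfg$outdir, "mfpt.tsv")
  write_profile_tsv(tau_df, tau_path); emit(tau_path)

  # ---- stage: scaling fit ----
  fit <- run_stage("fit", {
    ok <- is.finite(taus) & taus > 0
    if (sum(ok) >= 4) fit_scaling_law(cfg$probe_radii[ok], taus[ok]) else NULL
  })
  cross <- if (!is.null(fit))
    tryCatch(as.numeric(crossover_radius(fit)), error = function(e) NA_real_)
    else NA_real_

  # ---- stage: percolation ----
  perc <- run_stage("percolation", {
    pg <- cfg$percolation
    pvgs <- void_grid_spec(lower = c(-ext, -ext, -cfg$void$z_half),
                           upper = c(ext, ext, cfg$void$z_half),
                           voxel_size = pg$voxel_size,
                           slab_height = cfg$void$slab_height,
                           profile_radius = cfg$void$profile_radius)
    percolation_curve(ensemble, cfg$probe_radii, pvgs,
                      exclusion_grids = grids,
                      source_z = pg$source_z, sink_z = pg$sink_z,
                      connectivity = pg$connectivity)
  })
  perc_path <- file.path(cfg$outdir, "percolation.tsv")
  write_percolation_curve(perc, perc_path)
  emit(perc_path); emit(paste0(perc_path, ".json"))

  results <- list(
    tau = tau_df,
    scaling = if (!is.null(fit))
      list(tau0 = fit$tau0, R0 = fit$R0, alpha = fit$alpha,
           crossover_radius = cross),
    percolation_radius = attr(perc, "percolation_radius"),
    percolation_bracket = attr(perc, "bracket"))
  fit_path <- file.path(cfg$outdir, "scaling_fit.json")
  jsonlite::write_json(results[c("scaling", "percolation_radius",
                                 "percolation_bracket")],
                       fit_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  emit(fit_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("npcvoid")),
    seed = cfg$seed,
    config_hash = .hash_config(cfg),
    files = data.frame(path = files, md5 = unname(tools::md5sum(files)),
                       row.names = NULL),
    results = results)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

.hash_config <- function(cfg) {
  cfg$outdir <- NULL                 # the artifact location is not content
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Convert between the package's on-disk formats
#'
#' Supported pairs: `mrc <-> dx` (volumetric grids), `pdb <-> xyz` (bead
#' configurations; xyz may hold several frames, pdb one per file) and
#' `tsv -> json` (profiles).  Formats are inferred from file extensions when
#' not given.
#'
#' @param input input path.
#' @param output output path.
#' @param from,to format names (`"mrc"`, `"dx"`, `"pdb"`, `"xyz"`, `"tsv"`,
#'   `"json"`); inferred from the extensions when `NULL`.
#' @return `output`, invisibly.
#' @export
convert_file <- function(input, output, from = NULL, to = NULL) {
  ext <- function(p) tolower(sub(".*\\.", "", p))
  from <- from %||% ext(input)
  to <- to %||% ext(output)
  pair <- paste(from, to, sep = "->")
  switch(pair,
    "mrc->dx" = write_dx(read_mrc(input), output),
    "dx->mrc" = write_mrc(read_dx(input), output),
    "mrc->mrc" = write_mrc(read_mrc(input), output),
    "dx->dx" = write_dx(read_dx(input), output),
    "pdb->xyz" = write_ensemble_xyz(read_mesh_pdb(input), output),
    "xyz->pdb" = {
      frames <- read_ensemble_xyz(input)
      if (length(frames) > 1)
        warning("xyz holds ", length(frames), " frames; writing the first")
      write_mesh_pdb(frames[[1]], output)
    },
    "tsv->json" = {
      df <- read_profile_tsv(input)
      jsonlite::write_json(df, output, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
      output
    },
    stop("unsupported conversion: ", pair))
  invisible(output)
}
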