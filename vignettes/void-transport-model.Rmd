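---
title: "A void-statistics model of passive transport through the nuclear pore"
author: "npcvoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A void-statistics model of passive transport through the nuclear pore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(npcvoid)
```

## The model

The permeability barrier of the nuclear pore complex (NPC) is a dense,
disordered mesh of FG-nucleoporin chains. `npcvoid` implements a theory in
which the energetics and kinetics of *passive* protein transport follow
entirely from the statistics of transient voids in that mesh — no transport
simulation is required once an equilibrium ensemble of mesh configurations is
available.

The chain of reasoning, and the package modules that implement it:

1. **Void analysis** (`compute_rmax()`, `classify_voids()`).  Space is
   partitioned into cubic voxels of edge $l_c$.  For each voxel centre we
   compute $R_{\max}$, the distance to the nearest obstacle surface — either
   a mesh bead (3 Å radius) or a voxel where any steric grid potential
   (scaffold, nuclear envelope, confinement) is non-zero.  A voxel can host
   a spherical probe of radius $R_p$ iff $R_{\max} \ge R_p$.

2. **Occupancy → PMF** (`occupancy_profile()`, `pmf_from_occupancy()`).
   With only hard steric probe–mesh interactions, the configurational
   integral over the probe's transverse coordinates reduces to the
   accessible cross-section area $\mathcal{A}(z)$, so the potential of mean
   force along the pore axis is a Boltzmann inversion of the
   ensemble-averaged available-cell count $\langle h(z_i)\rangle$:
   $$F(z_i) = -k_BT\,\ln\langle h(z_i)\rangle + k_BT\,
   \ln(\mathcal{A}_c / l_c^2),$$
   where $\mathcal{A}_c$ is the cross-section of the cylindrical confinement;
   the additive constant makes $F \to 0$ far from the pore, where the whole
   cylinder is accessible.

3. **Fick–Jacobs diffusivity** (`diffusivity_profile()`).  A narrowing
   channel not only costs entropy but slows local diffusion.  With effective
   half-width $w(z) = \sqrt{\mathcal{A}(z)/\pi}$, the package implements the
   Reguera–Rubi closure $D = D_0/[1 + (w')^2]^{1/2}$ (default) and the
   Zwanzig closure $D = D_0/[1 + (w')^2/2]$.  Swapping them changes toy MFPTs
   by well under a factor of 1.5 (tested), so the choice is not load-bearing.

4. **First-passage kinetics** (`transition_rates()`, `solve_fpt()`).  The 1D
   Smoluchowski equation is discretised on nodes $z_n = z_0 + nd$ with
   hopping rates
   $$k_{n\to m} = \frac{D_n + D_m}{2d^2}\,
     e^{-\beta\,(V_m - V_n)/2},$$
   which satisfy detailed balance exactly.  A reflecting node at
   $z_0 = -600$ Å and an absorbing node at $+200$ Å, with the probe started
   at $-200$ Å, reproduce the geometry in which a first passage is defined
   (entry into $|z| < 200$ Å, exit on the opposite side).  Explicit Euler
   stepping gives the first-passage-time density from absorbed-mass
   increments and the MFPT by time-weighted integration.

5. **Scaling law and crossover** (`fit_scaling_law()`,
   `crossover_radius()`).  Over a probe-radius sweep the MFPT follows
   $$\tau(R_p) = \tau_0 R_p\, e^{\left((R_p + 3\,\text{Å})/R_0\right)^{\alpha}},$$
   the $\tau_0 R_p$ prefactor being the Stokes–Einstein cost of finding the
   pore and the stretched exponential an effective barrier; the 3 Å offset
   is the physical radius of mesh residues and is held fixed.  The
   exponential term dominates above the root of
   $\ln R = ((R+3)/R_0)^\alpha$: for the reference 50-nm-confinement
   parameter set ($R_0 = 19.8$ Å, $\alpha = 1.89$) this crossover is at 35.9 Å.

6. **Percolation** (`label_components()`, `open_path_exists()`,
   `percolation_curve()`).  The physical origin of the crossover: accessible
   voxels are partitioned by union-find; an open path exists when one
   component touches both a source layer ($z = +200$ Å) and a sink layer
   ($-200$ Å).  The fraction of configurations with an open path drops from
   1 toward 0 over a narrow probe-radius window — a percolation transition —
   and the MFPT crossover falls inside that window (tested end-to-end on the
   synthetic fixture).

## The synthetic mesh generator

Production NPC analyses consume millisecond coarse-grained trajectories;
this package ships a generator (`build_mesh_ensemble()`) that emulates the
*initialisation* protocol of such models and produces independent frames:

* one bead per residue, consecutive beads exactly 3.8 Å apart;
* chains grown from their anchor as self-avoiding random walks, no bead of
  one chain within 8 Å of another chain's beads;
* beads three or more residues from the anchor keep 8 Å clearance from any
  sterically excluded voxel (scaffold/envelope grids);
* anchors placed exactly (the dynamics-time harmonic anchor restraint has no
  meaning for independent draws);
* linker species (`anchor_end = "both"`) grown under a reachability
  constraint so the last bead lands exactly on the second anchor;
* optional bond-preserving crankshaft moves (`relax_steps`) for
  excluded-volume relaxation.

Downstream machinery is force-field-agnostic, so independent SAW frames are
a valid test ensemble: every property the tests assert (oracle equivalence,
monotone accessibility, percolation transition, MFPT growth) is a property
of the *analysis*, not of the ensemble's dynamics.  What the generator does
**not** emulate — and what passing tests therefore do not show about real
NPCs — is cohesive FG–FG interaction (our SAW frames forbid inter-chain
approaches below 8 Å, so `interchain_contact_fraction()` at the 8 Å contact
definition is near zero by construction, unlike equilibrated cohesive
meshes), sequence-specific density patterning, and temporal correlation
between frames.  Quantities that depend on mesh *density only at the level
of geometry* transfer; quantities that depend on mesh cohesion do not.

Built-in stoichiometries `lin2016` (5 species × 32 copies = 160 chains),
`kim2018` (9 species, 200 chains) and `kim2018plus` (adds Nup42, Nup2 and
three both-end-restrained linker segments; 29.1% more residues than
`kim2018`) carry the experimentally derived copy numbers and disordered-fragment residue
ranges.  `kim2018plus` does not restate a Nup1 copy number in its source, so
it inherits 8 copies from `kim2018`; only explicitly changed entries are
overridden, and this choice reproduces the expected ~30% residue
increase.  Anchor coordinates are not part of the stoichiometry
tables; `anchor_layout()` places copies uniformly on mirror-symmetric rings
(default radius 220 Å, matching a ~44 nm inner-ring diameter) at
species-specific tether heights.  Users with real anchor coordinates supply
them in the `stoichiometry()` object.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `voxel_size` ($l_c$) | 6 (PMF), 1–3 (connectivity) | Å | void-analysis cell edge |
| bead radius | 3 | Å | mesh residue radius in $R_{\max}$ |
| probe radius $R_p$ | sweep | Å | protein size; mass via `mass_to_radius()` |
| `slab_height` | 6 | Å | occupancy cylinder segment height |
| `profile_radius` | 500 / 250 | Å | confinement radius (50 / 25 nm studies) |
| `source_z`, `sink_z` | ±200 | Å | NPC volume boundary for paths/passages |
| solver `d` | 0.5 | Å | Smoluchowski node spacing |
| solver domain | −600 … +200 | Å | reflecting … absorbing node |
| start $z'$ | −200 | Å | first-passage initial condition |
| `D0` | Stokes–Einstein | Å²/µs | bulk diffusivity of the probe |
| scaling offset | 3 (fixed) | Å | residue radius added to $R_p$ |

`D0` from `stokes_einstein_D0()` is an approximation: production workflows
take rigid-body diffusion tensors from bead-model hydrodynamics tools, and
real proteins diffuse somewhat slower than the equivalent sphere.  Since
$\tau \propto 1/D_0$ exactly in this solver (tested to $10^{-9}$), any
better $D_0$ simply rescales MFPTs.

## Numerical choices

* **Voxel convention.**  Voxel $(i,j,k)$ has its centre at
  `origin + (i-1/2, j-1/2, k-1/2) * spacing`.  Distances to excluded voxels
  are centre-to-centre, treating the excluded voxel as a point; surface
  offsets differ by at most $l_c$ and vanish under refinement.
* **$R_{\max}$ sign.**  $R_{\max}$ is negative inside bead volumes and takes
  $-l_c/2$ at excluded voxels, so a point probe ($R_p = 0$) is correctly
  barred from obstacle interiors while `classify_voids()` remains a pure
  threshold.  Where nothing excludes, $R_{\max} = +\infty$; infinities are
  clamped when maps are written to MRC/DX files.
* **Exclusion threshold.**  Any grid value above $10^{-9}$ marks a voxel
  excluded (tolerance for float grids holding an exact zero elsewhere).
* **Connectivity.**  6-connectivity (face adjacency) is the default: a
  spherical probe cannot pass through an edge or corner contact.
  26-connectivity is available for sensitivity checks.
* **Percolation radius.**  Open-path probability is naturally a curve, not a scalar; the
  package defines a point estimate at $p_{\text{open}} = 0.5$ by linear
  interpolation between bracketing radii, reported with its bracket.
* **Symmetrisation** averages probabilities $P(z), P(-z)$ and re-inverts,
  which conserves probability mass exactly; the asymmetry statistic (mean
  point-by-point $|F(z) - F(-z)|$ over $|z| < 500$ Å) doubles as the barrier
  uncertainty.
* **Trace PMFs** are zeroed on the $|z| \in [450, 550]$ Å far-field window
  (falling back to the outermost covered bins); empty bins inside the
  sampled range are flagged, never silently interpolated.
* **Solver stability.**  The Euler step defaults to $0.4/\max_n(k^+_n +
  k^-_n)$, the discrete analogue of the $D\,\Delta t/d^2 < 1$ requirement.
  Because $\Delta t \propto 1/D_0$, the solved chain is dimensionless in
  $D_0$.  Stepping stops when survival drops below $10^{-3}$; the MFPT adds
  an exponential tail correction fitted to the terminal survival decay.
* **Hard walls.**  Slabs with zero mean occupancy carry $+\infty$ PMF; the
  rate builder gives such nodes zero in- and out-rates, and a fully blocking
  slab inside the solver domain yields $\tau = \infty$ rather than a huge
  float.
* **Scaling fit.**  Least squares on $\ln\tau$ (a multiplicative noise
  model, which also keeps the power-law and exponential regimes
  commensurate), $\ln\tau_0$ profiled out, 5 jittered starts over
  $(\ln R_0, \ln\alpha)$ followed by BFGS polish.  The crossover root-finder
  takes the *upper* sign change of $\ln R - ((R+3)/R_0)^\alpha$ (the lower
  one, below 2 Å, is an artifact of $\ln R \to -\infty$).
* **Envelope surface.**  The flattened branch of the envelope equation mixes
  Å and Å² additively; it is implemented exactly in that form (flagged here
  for users).  The membrane is rendered as a bounded repulsive wall,
  `wall_height * exp(-(dist/wall_softness)^2)` about the mid-surface
  (defaults 15 kcal/mol, 10 Å), reproducing the documented 0–15 kcal/mol
  range without an all-atom membrane.
* **Scaffold potentials.**  Grid potentials follow the kernel–density
  convolution (FFT with zero padding, beads binned to voxel centres; the
  direct-sum path is retained as an oracle).  Residue-pair
  kernel tables belong to specific coarse-grained force fields outside this
  package's scope, so the default is a single soft-core repulsion
  ($2\,$kcal/mol, 8 Å range) for all pairs; users may load custom tables.
* **Charge-to-hydrophobicity.**  No single standard definition accompanies the
  0.3 disorder threshold, so the package pins one: net charge (K,R: +1; H: +0.5;
  D,E: −1) over Kyte–Doolittle hydropathy rescaled to [0, 1]
  (`residue_scales()`).  Absolute values may differ from other conventions.
* **SAW clash scope.**  The 8 Å growth rule applies between separate chains;
  intra-chain self-avoidance therefore uses the 6 Å excluded-volume
  diameter (2 × bead radius) for non-bonded beads instead.

## Problem sizes

The test-suite and acceptance fixtures run at desk scale, chosen so the full
suite completes in minutes on one core: toy meshes of 8–12 chains × 40–50
residues in a 10 nm-radius confinement, void lattices of $\le 120^3$ voxels
at 3–6 Å, ensembles of 4–8 frames, 1500–2000 Brownian walkers, and solver
sweeps at $d = 2$ Å (with the flat-PMF closed-form check run at the
production $d = 0.5$ Å).  Headline ensemble statistics of millisecond
production trajectories (65% connected chains, ~60 mg/mL densities, the
fitted $\tau_0, R_0, \alpha$ themselves) require that data and are out of
scope; what is reproduced analytically is the crossover-radius calculation
and the structural bookkeeping of the stoichiometries.

## Known limitations

* Probes are spheres; non-spherical probes would need a modified void
  search.  Probe rotational degrees of freedom are ignored.
* The 1D reduction assumes transverse equilibration; polymer entanglement
  and probe–mesh binding are outside the model.
* Independent SAW frames carry no kinetics of the mesh itself: mesh
  rearrangement times, and any coupling between mesh motion and probe
  motion, are not represented.
* MRC/DX I/O supports the orthogonal-axis, mode-2 subset the package
  writes.
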