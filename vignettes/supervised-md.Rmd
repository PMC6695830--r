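---
title: "Supervised molecular dynamics on a coarse-grained binding funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised molecular dynamics on a coarse-grained binding funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumd)
```

## The method

Supervised molecular dynamics (SuMD) samples ligand-binding pathways by
steering *when* dynamics is kept, never *how* it moves. The simulation is cut
into short unbiased windows (200 ps for fast-diffusing ions, 600 ps for small
organic molecules). Within each window the distance between the ligand's
center of mass and the mass-weighted center of a chosen set of binding-site
residues is sampled at regular intervals and fitted to a straight line by
ordinary least squares. A window whose slope is negative — the ligand is, on
average, approaching — is kept and the next window continues from its final
state. Any other window is discarded: the system is rewound to the window's
starting positions and clock, and only the velocities are redrawn from the
Maxwell–Boltzmann distribution at the thermostat temperature. Once a window
ends with the distance below a hand-off threshold (5 Å by default) the
supervision is switched off and plain MD continues, so the bound state
relaxes under unperturbed dynamics.

Because every kept window is ordinary, unbiased Langevin dynamics, the method
introduces no biasing force and no reweighting problem; it is an
accept/reject scheme on trajectory segments. The price is that the kept
trajectory is conditioned on approach, so kinetic observables must be read
from the supervised clock with that in mind.

Three classification rules matter and are worth stating precisely:

* a window whose **final** sampled distance is below the threshold is
  classified `bound` even if its slope is non-negative — the stop rule is on
  distance, not slope, and a window that achieved the goal should not be
  discarded;
* a slope of exactly zero is a rejection: a flat window makes no progress
  (`fit_slope()` uses the covariance form of least squares, so an exactly
  constant series yields an exact zero rather than rounding noise);
* rejection restores the full pre-window state — positions and time — and
  only the velocities change. The dynamics noise stream continues past the
  discarded window, while restart velocity draws come from a separate seeded
  sub-stream, so the accept/reject sequence never perturbs the thermostat
  noise of the segments that are kept.

Two safeguards guarantee termination: a cap on consecutive rejections
(default 40) and a cap on total attempted windows (default 500). Both are
practical safeguards of this implementation, exposed in
`supervision_config()`.

## The built-in system

The package ships a deliberately simple coarse-grained receptor–ligand
system (`build_receptor_model()`) so the whole control loop and analysis
stack can be exercised end-to-end on one CPU. It is invented plumbing — a
stand-in for a prepared all-atom receptor — and is labelled as such; what it
must emulate is (i) a ligand diffusing in from the bulk, (ii) at least one
metastable off-pathway site, and (iii) a target site whose occupancy defines
binding.

Geometry (defaults; units Å, kcal/mol):

* a funnel of frozen repulsive beads (soft spheres,
  `eps = 0.5`, `sigma = 3`): five rings from radius 5 at z = −10 to radius
  13 at z = +6, plus a 9-bead floor cap closing the pocket from below;
* an **orthosteric well**: an isotropic Gaussian of depth 8 and width 3 at
  the funnel base, the global minimum;
* a **steering term**: a broad (width 10), shallow (depth 1.5) Gaussian
  co-centered on the orthosteric well. This mimics the long-range
  electrostatic attraction a charged pocket (the buried-aspartate analog)
  exerts on an approaching ion; without it the toy ligand feels no force
  until it is already deep inside the funnel, which no electrostatically
  driven ion-binding site would show;
* a **meta well** of depth 3 at the funnel-mouth rim — a solvent-exposed
  vestibular site that can transiently hold the ligand off-pathway;
* a cubic box of edge 80 with reflecting walls (no periodicity: minimum-image
  bookkeeping adds nothing to a single-pocket model);
* a single ligand bead starting in the bulk at (0, 0, 30), about 40 Å from
  the pocket.

The ligand bead has an effective mass of 1900 amu. This is the one place the
model compensates for its implicit solvent: with the production thermostat
friction of 1 ps⁻¹, a bare ion mass would give a diffusion constant two
orders of magnitude above that of a solvated ion. Choosing the mass so that
`D = kB*T/(m*friction) ≈ 0.135 Å²/ps` reproduces realistic ionic diffusion
at 310 K, which in turn makes the window length meaningful: a 200 ps window
gives a root-mean-square displacement of roughly 12 Å, large enough to show
a trend, small enough that the distance series is not pure noise.

Receptor flexibility is emulated, not integrated: `funnel_scale > 1` widens
the bead rings, standing in for the more flexible receptor state whose
orthosteric volume inflates; the supervision loop itself remains the object
under test. Site definitions follow the residue-triad convention: three
base-ring beads define the orthosteric center, three rim beads nearest the
meta well define the vestibular site.

## The engine

`run_segment()` integrates NVT Langevin dynamics with the BAOAB splitting at
a 2 fs timestep, 310 K, friction 1 ps⁻¹ (all defaults of
`engine_config()`), with frames saved every 20 ps. BAOAB gives accurate
configurational sampling at this timestep without constraint algorithms —
the toy ligand has no constrained bonds. With friction 0 and the thermostat
off it reduces to velocity Verlet; the test suite verifies total-energy
drift below 1e−4 (relative) over 10⁴ steps, equipartition within 5%, and
free diffusion against the Einstein relation within 30%.

Reproducibility contract: a segment consumes R's RNG stream and stores the
stream state in its end state, so running 40 ps then 60 ps is bit-identical
to running 100 ps, and a whole `run_sumd()` is bit-reproducible for a fixed
seed. Restart velocity draws use private seeded streams derived from the
master seed, separate from the thermostat noise.

The repulsion is capped at 10³ kcal/mol so the potential stays finite at
bead centers; inside the capped plateau the force is zero by construction,
which is why gradient checks exclude points closer than ~1.6 Å to a bead.

## Analysis stack

* `kabsch_superpose()` / `rmsd_series()`: SVD-based least-squares rigid
  superposition (proper rotation enforced); per-frame RMSD of a measured
  selection after fitting on another (receptor-frame convention), with
  `rmsd_min` reported as in binding-pose tables.
* `pairwise_rmsd_matrix()`: the nf × nf matrix of inter-frame RMSDs. For a
  single-particle ligand this is the Euclidean distance matrix; multi-atom
  frames are compared without re-superposition because positions are already
  in the receptor frame after trajectory superposition.
* `dbscan_cluster()`: standard DBSCAN (core point: ≥ `min_samples`
  neighbours within `eps` including itself; clusters are density-connected
  components; border points attach; the rest is noise, label −1). Defaults
  `eps = 1.5` Å, `min_samples = 5` are this package's choices — sensible for
  clustering ion positions saved every 20 ps — and are exposed as flags.
  Written in R because no installed package was to hand; it is verified
  against an independent brute-force density-reachability implementation.
  Border points equidistant to two clusters may legitimately attach to
  either; tests therefore compare core-point partitions strictly and border
  status loosely.
* `pocket_volume()` / `volume_series()`: POVME-style grid count inside a
  spherical inclusion region (default radius 9 Å, centered on the ligand
  centroid or a fixed site center) excluding padded van der Waals spheres.
  Grid spacing 1.0 Å and padding 1.09 Å (a hydrogen-probe value) are
  defaults, both configurable; vdW radii come from a built-in Bondi table
  with a per-atom override column. Discretization error scales with the
  occlusion surface area times the spacing; tests bound it against a
  Monte-Carlo oracle.
* `contact_frequencies()`: a residue contacts the ligand in a frame iff any
  heavy-atom pair is within the cutoff (default 4.5 Å, our choice); counts
  over frames drive polar-diagram-style cumulative contact maps.
* `nonbonded_energy()`: toy ligand–receptor interaction split into a Coulomb
  term (332.0636·q₁q₂/(ε·r)) and the well+repulsion term; the two sum
  exactly to `potential_energy()`.
* `coordination_count()`: element-filtered neighbour count around a point,
  e.g. the five oxygens coordinating a crystallographic sodium ion. Offline,
  the package exercises it on a synthetic five-oxygen site fixture; pointing
  it at a downloaded crystal structure via `read_pdb()` is a one-liner.

## Study conditions and problem sizes

The reference speed-up experiment (also what `scripts/acceptance.R` runs)
uses the default system and engine, 20 paired seeds, and an attempted-time
budget of 75 windows (15 ns) per run. For each seed one supervised run and
one plain-MD run of the full budget length are compared on (i) the fraction
of runs whose ligand comes within 5 Å of the orthosteric center and (ii)
mean first-binding time, censoring unbound runs at the budget — a
conservative convention that understates the true speed-up, since an unbound
plain-MD run would need far longer than the budget to bind. Under these
conditions supervision typically binds in well over half the seeds within a
few ns of supervised time while plain MD essentially never binds within the
budget, and the censored mean ratio exceeds 2.

These sizes (20 seeds, 15 ns budget, a single-bead ligand, an 80-bead
receptor) are the package's chosen reference conditions: large enough for a
two-proportion comparison with a binomial test, small enough to run
anywhere.

## What the generator does and does not emulate

It emulates: diffusion-limited approach from bulk at realistic ionic
diffusivity, a funnel-shielded target with both short-range binding and
long-range steering, an off-pathway metastable site, hand-off to unbiased
MD, and the bookkeeping of accepted/attempted time. It does **not** emulate:
receptor flexibility (beads are frozen; widening is a static switch),
explicit solvent or friction anisotropy, multi-atom ligand internal degrees
of freedom (ligand beads are independent particles with no internal forces),
electrostatics beyond the optional Coulomb term, or membrane context.
Passing tests on this system therefore validate the *control algorithm and
analysis arithmetic*, not force-field realism: conclusions about any real
receptor still require the real structures and an all-atom engine behind
the same `run_segment()` contract.

## Numerical choices and degenerate inputs

* Units: Å, ps, amu, kcal/mol, K; `kB = 0.0019872041` kcal/(mol·K); the
  (kcal/mol)/amu → Å²/ps² conversion is 418.4.
* Distance samples per window: window/10 (20 ps for the ion preset), a
  choice this package fixes since only "regular intervals" is conventionally
  specified; 10 points give a stable slope without oversampling.
* A ligand already below the threshold classifies window 1 as `bound` and
  the run degenerates to plain MD — useful as a degenerate-threshold check.
* Ties: slope exactly 0 rejects; a final distance exactly equal to the
  threshold is not bound (strict `<`).
* Collinear point sets are rejected by the superposition (no unique
  rotation); fewer than two distance samples or zero time variance are
  errors, not NA slopes.
* The pairwise-RMSD matrix of nf frames is O(nf²) memory; at the default
  20 ps stride a 15 ns trajectory is 750 frames — a 4.5 MB matrix.

## Known limitations

* The accepted trajectory's time axis is the supervised clock; wall-clock
  kinetics (rates) cannot be read off it directly.
* Supervision can stall at the funnel mouth when the remaining approach
  requires threading a narrow channel whose progress per window is small
  compared with diffusion noise; runs then end at the window cap. This
  mirrors the unproductive-replicate phenomenology of the method rather
  than a defect of the implementation.
* `run_sumd()` supervises a single site; multi-site supervision and
  adaptive window lengths are out of scope, as is unbinding supervision
  (plain `run_segment()` covers unbinding observation).
* The DCD binary trajectory format is not implemented; XYZ (with a JSON
  provenance sidecar) is the interchange format.
```{r example, eval = FALSE}
sys <- build_receptor_model(seed = 1)
res <- run_sumd(sys, engine_config(), supervision_config(), seed = 1)
res
head(res$window_log)
```
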