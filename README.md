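# sumd

Supervised molecular dynamics (SuMD) sampling of ligand-binding pathways,
with the trajectory-analysis stack used to characterise them — as an R
package that runs end-to-end on one CPU.

## The problem and the algorithm

Watching a ligand find its binding site in unbiased MD routinely takes
hundreds of nanoseconds to microseconds, because most of the time is spent
diffusing in the bulk. SuMD shortens that to nanoseconds without adding any
biasing force: dynamics is run in short unbiased windows, and a tabu-like
rule decides which windows to keep.

For each window of length `w` (200 ps for ions, 600 ps for small
molecules), the distance `d(t)` between the ligand center of mass and the
mass-weighted center of the binding-site residues is sampled at regular
intervals and fitted by ordinary least squares,

    d(t) ≈ a + m·t .

If `m < 0` (the ligand approaches) the window is kept and the next one
continues from its end state. Otherwise the window is discarded: positions
and clock are rewound to the window start and the atomic velocities are
redrawn from the Maxwell–Boltzmann distribution at the thermostat
temperature. When a window ends with `d < 5` Å the supervision is disabled
and plain MD continues. Every kept segment is ordinary NVT Langevin dynamics
(BAOAB, 2 fs timestep, 310 K, friction 1 ps⁻¹).

The package provides:

* `build_receptor_model()` — a built-in coarse-grained receptor: a funnel of
  repulsive beads around a deep orthosteric Gaussian well (with a broad
  shallow electrostatic-steering term), a metastable vestibular site at the
  funnel mouth, and a ligand bead with solvated-ion diffusivity;
* `run_segment()` / `engine_config()` — the Langevin engine (any engine
  honouring the same segment contract can replace it);
* `run_sumd()` / `supervision_config()` — the supervision loop, with full
  window logs and accepted/attempted time bookkeeping;
* analysis: `kabsch_superpose()`, `rmsd_series()`, `pairwise_rmsd_matrix()`,
  `dbscan_cluster()`, `pocket_volume()` / `volume_series()` (POVME-style
  spherical inclusion region, 9 Å default radius),
  `contact_frequencies()`, `nonbonded_energy()`, `coordination_count()`;
* I/O and CLI: PDB (via bio3d), XYZ trajectories with JSON provenance
  sidecars, YAML run configuration, and a `sumd` command-line wrapper
  (`inst/cli/sumd.R`) with `generate-system`, `run-sumd` and `analyze`
  subcommands.

## Worked example

```r
library(sumd)

sys <- build_receptor_model(seed = 1)       # funnel receptor + bulk ligand
res <- run_sumd(sys, engine_config(), supervision_config(), seed = 42)
res
#> SuMD run (seed 42): bound
#>   windows: 12 attempted, 6 accepted
#>   supervised time: 1200 ps of 2400 ps attempted
#>   first below threshold at 1140 ps

head(res$window_log[, c("index", "slope", "decision", "final_distance")], 4)
#>   index        slope decision final_distance
#> 1     1 -0.054268359   accept       26.74020
#> 2     2  0.057463344   reject       33.84916
#> 3     3 -0.027959905   accept       22.14518
#> 4     4  0.008574632   reject       22.51998

# cluster the ligand positions of the accepted trajectory
pts <- t(res$trajectory$coords[nrow(res$trajectory$topology), , ])
dbscan_cluster(pts, eps = 1.5, min_samples = 5)$n_clusters
#> [1] 1

# grid-based orthosteric pocket volume (9 A inclusion sphere)
pocket_volume(sys$receptor, site_center(sys, sys$sites$orthosteric))
#> [1] 430
```

The ligand reached the orthosteric site after 1.2 ns of kept ("supervised")
time out of 2.4 ns attempted; rejected windows (positive or zero slope) were
rewound and restarted with fresh velocities. The single position cluster is
the bound pose; the pocket volume is the lattice count inside the 9 Å sphere
that falls outside the padded bead radii.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/sumd.R generate-system --seed 1 --out system
Rscript inst/cli/sumd.R run-sumd --seed 42 --threshold-A 5 --out run
Rscript inst/cli/sumd.R analyze volume --traj run.xyz --topology system.pdb
```

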