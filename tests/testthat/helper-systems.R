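# Small fixtures built in code.

# Minimal mobile-particle system on a bare potential (no receptor beads
# unless given); used to probe the integrator away from the full funnel.
make_well_system <- function(wells = data.frame(x = 0, y = 0, z = 0,
                                                depth = 8, width = 2),
                             beads = NULL, bead_eps = 0, bead_sigma = 3,
                             start = c(0, 0, 10), mass = 100, box = 200,
                             n_ligand = 1) {
  starts <- matrix(rep(start, each = n_ligand), n_ligand, 3)
  lig <- atom_records(serial = seq_len(n_ligand), name = "NA",
                      resname = "LIG", resid = 1000L + seq_len(n_ligand),
                      chain = "L", x = starts[, 1], y = starts[, 2],
                      z = starts[, 3], mass = mass)
  rec <- if (is.null(beads)) {
    atom_records(integer(0), character(0), character(0), integer(0),
                 character(0), numeric(0), numeric(0), numeric(0))
  } else {
    atom_records(serial = 9000L + seq_len(nrow(beads)), name = "BD",
                 resname = "FUN", resid = 9000L + seq_len(nrow(beads)),
                 chain = "R", x = beads[, 1], y = beads[, 2], z = beads[, 3],
                 mass = 100, vdw = bead_sigma)
  }
  structure(list(receptor = rec, ligand = lig, sites = list(),
                 box = rep(box, 3),
                 potential = potential_spec(wells,
                                            bead_positions = if (is.null(beads))
                                              NULL else as.matrix(beads),
                                            bead_eps = bead_eps,
                                            bead_sigma = bead_sigma)),
            class = "toy_system")
}

# Kinetic energy in kcal/mol for velocities in A/ps.
kinetic_energy <- function(vel, mass) {
  sum(0.5 * mass * rowSums(vel^2)) / sumd_constants$akma
}

# A static trajectory from a list of coordinate matrices.
make_traj <- function(topology, frames, stride = 20) {
  arr <- array(NA_real_, c(nrow(topology), 3, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  trajectory(topology, arr, stride * seq_along(frames), stride = stride)
}

# Independent brute-force DBSCAN by explicit density-reachability:
# core points, BFS over the eps-graph restricted to cores, borders attached
# to the first reachable core cluster.
brute_dbscan <- function(D, eps, min_samples) {
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- sapply(nb, length) >= min_samples
  labels <- rep(-1L, n)
  k <- 0L
  for (i in which(core)) {
    if (labels[i] != -1L) next
    k <- k + 1L
    comp <- i
    repeat {
      grow <- unique(unlist(nb[comp[core[comp]]]))
      grow <- grow[core[grow]]
      new <- setdiff(grow, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    labels[comp] <- k
  }
  for (i in which(!core & labels == -1L)) {
    reach <- nb[[i]]
    reach <- reach[core[reach]]
    if (length(reach)) labels[i] <- labels[reach[1]]
  }
  labels
}

# TRUE iff two labelings agree up to a permutation of cluster ids
# (noise = -1 must match exactly).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}
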