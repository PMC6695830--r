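#' Trajectory container
#'
#' Ordered frames over a fixed topology. Coordinates are stored as an
#' natoms x 3 x nframes array in Angstrom; `window` carries per-frame
#' supervision provenance (attempted-window index, NA for the unsupervised
#' tail).
#'
#' @param topology an [atom_records()] table.
#' @param coords natoms x 3 x nframes array, A.
#' @param times frame times, ps (strictly increasing).
#' @param stride nominal frame spacing, ps.
#' @param window optional per-frame integer window index.
#' @return A `sumd_trajectory`.
#' @export
trajectory <- function(topology, coords, times, stride = NULL, window = NULL) {
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an natoms x 3 x nframes array")
  if (dim(coords)[1] != nrow(topology))
    stop("frame atom count does not match topology")
  if (dim(coords)[3] != length(times))
    stop("times must have one entry per frame")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = times,
                 stride = stride %||% (if (length(times) > 1) times[2] - times[1] else NA_real_),
                 window = window %||% rep(NA_integer_, length(times))),
            class = "sumd_trajectory")
}

#' @export
print.sumd_trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3], "frames,", nrow(x$topology),
      "atoms, stride", x$stride, "ps\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Select atoms from a topology
#'
#' @param atoms an [atom_records()] table.
#' @param resid,name,chain,resname optional filters (values are OR-ed within
#'   a filter, filters are AND-ed).
#' @return Integer atom indices.
#' @export
select_atoms <- function(atoms, resid = NULL, name = NULL, chain = NULL,
                         resname = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(resid)) keep <- keep & atoms$resid %in% resid
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  which(keep)
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid-body superposition of `mobile` onto
#' `reference` (proper rotation, determinant +1). Row-vector convention:
#' the fitted coordinates are `mobile %*% rotation + translation`.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not all
#'   collinear.
#' @param weights optional per-point weights (e.g. masses).
#' @return List with `rotation` (3 x 3), `translation` (3-vector) and
#'   `rmsd` (A, weighted).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as_position_matrix(mobile); reference <- as_position_matrix(reference)
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("point counts differ")
  if (n < 3) stop("need at least 3 points for superposition")
  w <- if (is.null(weights)) rep(1, n) else rep_len(weights, n)
  w <- w / sum(w)
  mu_m <- colSums(mobile * w); mu_r <- colSums(reference * w)
  A <- sweep(mobile, 2, mu_m); B <- sweep(reference, 2, mu_r)
  if (qr(A)$rank < 2 || qr(B)$rank < 2)
    stop("degenerate (collinear) configuration")
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(mu_r - mu_m %*% R), rmsd = rmsd)
}

#' RMSD series against a reference structure
#'
#' For every frame: superpose on `fit_selection` (e.g. receptor backbone
#' beads), then report the RMSD of `measure_selection` (e.g. the ligand) to
#' the reference, together with the minimum over frames (RMSD_min).
#'
#' @param traj a [trajectory()].
#' @param reference natoms x 3 reference coordinates matching the topology.
#' @param fit_selection,measure_selection integer atom indices (see
#'   [select_atoms()]); defaults: all atoms.
#' @param weights optional weights for the fit (length of fit selection).
#' @param reference_label label stored on the result.
#' @return An `rmsd_series`: `values`, `rmsd_min`, `argmin_frame`, `times`.
#' @export
rmsd_series <- function(traj, reference, fit_selection = NULL,
                        measure_selection = NULL, weights = NULL,
                        reference_label = "reference") {
  reference <- as_position_matrix(reference)
  if (nrow(reference) != nrow(traj$topology))
    stop("reference does not match topology atom count")
  fit <- fit_selection %||% seq_len(nrow(reference))
  meas <- measure_selection %||% seq_len(nrow(reference))
  if (!length(fit) || !length(meas)) stop("empty selection")
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(k) {
    fr <- matrix(traj$coords[, , k], ncol = 3)
    sup <- kabsch_superpose(fr[fit, , drop = FALSE],
                            reference[fit, , drop = FALSE], weights)
    moved <- fr[meas, , drop = FALSE] %*% sup$rotation +
      matrix(sup$translation, length(meas), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - reference[meas, , drop = FALSE])^2)))
  }, numeric(1))
  structure(list(values = vals, rmsd_min = min(vals),
                 argmin_frame = which.min(vals), times = traj$times,
                 reference_label = reference_label),
            class = "rmsd_series")
}

#' Pairwise RMSD matrix between frames
#'
#' For single-particle input (an nf x 3 matrix of positions) this is the
#' Euclidean distance matrix between frames; for multi-atom input (an
#' natoms x 3 x nf array, already superposed into the receptor frame) it is
#' the coordinate RMSD without re-superposition.
#'
#' @param points nf x 3 matrix or natoms x 3 x nf array, A.
#' @return Symmetric nf x nf matrix with zero diagonal, A.
#' @export
pairwise_rmsd_matrix <- function(points) {
  if (length(dim(points)) == 3) {
    m <- dim(points)[1]; nf <- dim(points)[3]
    flat <- t(apply(points, 3, as.numeric))
    dim(flat) <- c(nf, 3 * m)
  } else {
    flat <- as_position_matrix(points)
    m <- 1; nf <- nrow(flat)
  }
  if (nf < 2) stop("need at least 2 frames")
  as.matrix(stats::dist(flat)) / sqrt(m)
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples`
#' neighbours within `eps` (counting itself); clusters are the
#' density-connected components of core points with border points attached;
#' everything else is noise (label -1). Clusters are numbered 1..k.
#'
#' @param x nf x d point matrix, or a precomputed symmetric distance matrix
#'   with `precomputed = TRUE` (e.g. a [pairwise_rmsd_matrix()]).
#' @param eps neighbourhood radius, A.
#' @param min_samples core-point threshold (neighbours within eps, incl.
#'   self).
#' @param precomputed interpret `x` as a distance matrix.
#' @return A `cluster_result`: `labels` (-1 = noise), `n_clusters`, `eps`,
#'   `min_samples`, `cluster_centroids` (k x d, or NULL for precomputed
#'   input).
#' @export
dbscan_cluster <- function(x, eps, min_samples = 5, precomputed = FALSE) {
  if (eps <= 0) stop("eps must be positive")
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (precomputed) {
    D <- as.matrix(x); pts <- NULL
  } else {
    pts <- as.matrix(x); D <- as.matrix(stats::dist(pts))
  }
  n <- nrow(D)
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(0L, n)  # 0 = unassigned
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    k <- k + 1L
    labels[i] <- k
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- k          # noise -> border
      if (labels[j] != 0L) next
      labels[j] <- k
      if (core[j]) queue <- c(queue, nb[[j]])
    }
  }
  labels[labels == 0L] <- -1L
  centroids <- NULL
  if (!is.null(pts) && k > 0) {
    centroids <- t(vapply(seq_len(k), function(cl)
      colMeans(pts[labels == cl, , drop = FALSE]), numeric(ncol(pts))))
  }
  structure(list(labels = labels, n_clusters = k, eps = eps,
                 min_samples = as.integer(min_samples),
                 cluster_centroids = centroids),
            class = "cluster_result")
}

#' Grid-based pocket volume with a spherical inclusion region
#'
#' POVME-style estimate: count cubic-lattice points (spacing `grid_spacing`)
#' that fall inside the inclusion sphere and outside every occluding atom's
#' padded van der Waals sphere; volume = count * spacing^3.
#'
#' @param atoms occluding atoms: an [atom_records()] table (uses its `vdw`
#'   column) or an n x 3 matrix plus `vdw` vector. May be empty.
#' @param center inclusion-sphere center 3-vector, A.
#' @param radius inclusion-sphere radius, A (default 9).
#' @param grid_spacing lattice spacing, A (default 1; must be in
#'   (0, radius)).
#' @param atom_padding probe padding added to each vdw radius, A (default
#'   1.09, a hydrogen-probe value).
#' @param vdw per-atom radii when `atoms` is a bare matrix.
#' @return Volume, A^3.
#' @export
pocket_volume <- function(atoms, center, radius = 9, grid_spacing = 1.0,
                          atom_padding = 1.09, vdw = NULL) {
  if (radius <= 0) stop("radius must be positive")
  if (grid_spacing <= 0 || grid_spacing >= radius)
    stop("grid_spacing must be in (0, radius)")
  if (is.data.frame(atoms)) {
    xyz <- atom_xyz(atoms); vdw <- atoms$vdw
  } else if (is.null(atoms) || nrow(as.matrix(atoms)) == 0) {
    xyz <- matrix(0, 0, 3); vdw <- numeric(0)
  } else {
    xyz <- as.matrix(atoms)
    if (is.null(vdw)) stop("vdw radii required for matrix input")
    vdw <- rep_len(vdw, nrow(xyz))
  }
  g1 <- seq(-radius, radius, by = grid_spacing)
  grid <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
  grid <- grid[rowSums(grid^2) <= radius^2, , drop = FALSE]
  grid <- sweep(grid, 2, -as.numeric(center))
  keep <- rep(TRUE, nrow(grid))
  for (a in seq_len(nrow(xyz))) {
    r2 <- (vdw[a] + atom_padding)^2
    d2 <- (grid[, 1] - xyz[a, 1])^2 + (grid[, 2] - xyz[a, 2])^2 +
      (grid[, 3] - xyz[a, 3])^2
    keep <- keep & d2 > r2
    if (!any(keep)) break
  }
  sum(keep) * grid_spacing^3
}

#' Pocket-volume time series
#'
#' Maps [pocket_volume()] over trajectory frames. The inclusion sphere is
#' centered either on the per-frame ligand centroid (the moving-agonist
#' convention) or on a fixed point such as a site center.
#'
#' @param traj a [trajectory()].
#' @param ligand_selection integer indices of ligand atoms (excluded from
#'   occlusion; define the centroid in `"ligand"` mode).
#' @param center_mode `"ligand"` or `"fixed"`.
#' @param center fixed center 3-vector when `center_mode = "fixed"`.
#' @inheritParams pocket_volume
#' @return A `volume_series`: `values` (A^3), `times`, parameters.
#' @export
volume_series <- function(traj, ligand_selection,
                          center_mode = c("ligand", "fixed"), center = NULL,
                          radius = 9, grid_spacing = 1.0, atom_padding = 1.09) {
  center_mode <- match.arg(center_mode)
  if (center_mode == "fixed" && is.null(center))
    stop("center required for fixed mode")
  topo <- traj$topology
  occ <- setdiff(seq_len(nrow(topo)), ligand_selection)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- matrix(traj$coords[, , k], ncol = 3)
    ctr <- if (center_mode == "ligand")
      colMeans(fr[ligand_selection, , drop = FALSE]) else center
    pocket_volume(fr[occ, , drop = FALSE], ctr, radius, grid_spacing,
                  atom_padding, vdw = topo$vdw[occ])
  }, numeric(1))
  structure(list(values = vals, times = traj$times, center_mode = center_mode,
                 radius = radius, grid_spacing = grid_spacing,
                 atom_padding = atom_padding),
            class = "volume_series")
}

#' Ligand--residue contact frequencies
#'
#' A residue is in contact with the ligand in a frame iff any atom pair
#' (residue atom, ligand atom) is closer than `cutoff`. Frequencies are
#' contact frames / total frames; the cumulative counts drive polar-diagram
#' style contact maps.
#'
#' @param traj a [trajectory()].
#' @param ligand_selection integer ligand atom indices.
#' @param residues residue ids to score; default: all non-ligand residues.
#' @param cutoff contact cutoff, A (default 4.5).
#' @return A `contact_table` data.frame: `resid`, `resname`, `count`,
#'   `frequency`; attributes `cutoff`, `n_frames`.
#' @export
contact_frequencies <- function(traj, ligand_selection, residues = NULL,
                                cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!length(ligand_selection)) stop("empty ligand selection")
  topo <- traj$topology
  rec_rows <- setdiff(seq_len(nrow(topo)), ligand_selection)
  if (is.null(residues)) residues <- sort(unique(topo$resid[rec_rows]))
  nf <- n_frames(traj)
  counts <- setNames(integer(length(residues)), residues)
  for (k in seq_len(nf)) {
    fr <- matrix(traj$coords[, , k], ncol = 3)
    lig <- fr[ligand_selection, , drop = FALSE]
    for (ri in seq_along(residues)) {
      rows <- rec_rows[topo$resid[rec_rows] == residues[ri]]
      if (!length(rows)) stop("residue id not present: ", residues[ri])
      d2 <- outer(rowSums(fr[rows, , drop = FALSE]^2), rowSums(lig^2), "+") -
        2 * fr[rows, , drop = FALSE] %*% t(lig)
      if (min(d2) < cutoff^2) counts[ri] <- counts[ri] + 1L
    }
  }
  resname <- topo$resname[match(residues, topo$resid)]
  out <- data.frame(resid = residues, resname = resname,
                    count = as.integer(counts),
                    frequency = as.numeric(counts) / nf)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Toy nonbonded interaction energy
#'
#' Decomposes the ligand--receptor toy interaction into an electrostatic
#' term (pairwise Coulomb, 332.0636 q1 q2 / (dielectric r)) and a
#' "vdW-like" term (the potential's Gaussian wells plus capped soft-sphere
#' repulsion). Their sum equals [potential_energy()].
#'
#' @param spec a [potential_spec()].
#' @param position ligand coordinates (3-vector or n x 3 matrix), A.
#' @param charge per-ligand-atom charges, e.
#' @return List with `electrostatic` and `vdw`, kcal/mol.
#' @export
nonbonded_energy <- function(spec, position, charge = 0) {
  pos <- as_position_matrix(position)
  q <- rep_len(as.numeric(charge), nrow(pos))
  elec <- 0
  if (isTRUE(spec$use_coulomb) && any(q != 0)) {
    for (i in seq_len(nrow(pos))) {
      r <- sqrt(colSums((t(spec$beads) - pos[i, ])^2))
      elec <- elec + sum(sumd_constants$coulomb * q[i] * spec$bead_charge /
                           (spec$dielectric * r))
    }
  }
  neutral <- spec
  neutral$use_coulomb <- FALSE
  vdw <- potential_energy(neutral, pos, charge = 0)
  list(electrostatic = elec, vdw = vdw)
}

#' Count coordinating atoms around a point
#'
#' Counts atoms of a given element within a cutoff of a center — e.g. the
#' oxygen atoms coordinating a bound sodium ion.
#'
#' @param atoms an [atom_records()] table.
#' @param center 3-vector, A (e.g. the ion position).
#' @param element element symbol to count (guessed from atom names).
#' @param cutoff coordination cutoff, A (default 3.0).
#' @return Integer count.
#' @export
coordination_count <- function(atoms, center, element = "O", cutoff = 3.0) {
  el <- guess_element(atoms$name)
  xyz <- atom_xyz(atoms)
  d <- sqrt(colSums((t(xyz) - as.numeric(center))^2))
  sum(el == toupper(element) & d <= cutoff)
}
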