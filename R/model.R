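#' Atom record table
#'
#' Builds the canonical atom table used throughout the package: one row per
#' atom with serial, name, residue, chain, coordinates (A), mass (amu),
#' charge (e) and van der Waals radius (A). Masses and radii default to the
#' built-in element table (Bondi radii) keyed on the element guessed from the
#' atom name.
#'
#' @param serial integer atom serials (unique).
#' @param name atom names.
#' @param resname residue names.
#' @param resid integer residue ids.
#' @param chain single-character chain ids.
#' @param x,y,z coordinates in Angstrom.
#' @param mass atomic masses in amu; defaults from the element table.
#' @param charge charges in elementary units; default 0.
#' @param vdw van der Waals radii in Angstrom; defaults from the element table.
#' @return A `data.frame` of class `sumd_atoms`.
#' @export
atom_records <- function(serial, name, resname, resid, chain, x, y, z,
                         mass = NULL, charge = 0, vdw = NULL) {
  n <- length(serial)
  if (anyDuplicated(serial)) stop("atom serials must be unique")
  if (!all(is.finite(c(x, y, z)))) stop("atom coordinates must be finite")
  el <- guess_element(name)
  mass <- if (is.null(mass)) element_mass(el) else rep_len(mass, n)
  vdw <- if (is.null(vdw)) element_vdw(el) else rep_len(vdw, n)
  if (any(mass <= 0)) stop("atom masses must be positive")
  if (any(vdw <= 0)) stop("van der Waals radii must be positive")
  out <- data.frame(serial = as.integer(serial), name = name,
                    resname = resname, resid = as.integer(resid),
                    chain = chain, x = x, y = y, z = z, mass = mass,
                    charge = rep_len(charge, n), vdw = vdw,
                    stringsAsFactors = FALSE)
  class(out) <- c("sumd_atoms", "data.frame")
  out
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Analytic toy potential specification
#'
#' The toy potential acting on each mobile ligand atom is a sum of isotropic
#' Gaussian wells, U_well = -depth * exp(-|r - c|^2 / (2 width^2)), a
#' soft-sphere repulsion eps*(sigma/|r - b|)^12 from every receptor bead
#' (capped at 1e3 kcal/mol so it stays finite at bead centers), and an
#' optional Coulomb term q_i q_b * 332.0636 / (dielectric * r).
#'
#' @param wells data.frame with columns `x`, `y`, `z` (A), `depth`
#'   (kcal/mol, > 0) and `width` (A, > 0); one row per attractive well.
#' @param bead_positions numeric matrix (n x 3) of receptor bead centers, A.
#' @param bead_eps soft-sphere epsilon, kcal/mol (0 disables repulsion).
#' @param bead_sigma soft-sphere sigma, A.
#' @param bead_charge optional per-bead charges (e); enables the Coulomb term.
#' @param dielectric relative dielectric constant for the Coulomb term.
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(wells, bead_positions = NULL, bead_eps = 0,
                           bead_sigma = 3.0, bead_charge = NULL,
                           dielectric = 1.0) {
  if (is.null(bead_positions)) bead_positions <- matrix(0, 0, 3)
  bead_positions <- as.matrix(bead_positions)
  if (ncol(bead_positions) != 3) stop("bead_positions must have 3 columns")
  wells <- as.data.frame(wells)
  if (nrow(wells) > 0) {
    stopifnot(all(c("x", "y", "z", "depth", "width") %in% names(wells)))
    if (any(wells$depth <= 0)) stop("well depths must be positive")
    if (any(wells$width <= 0)) stop("well widths must be positive")
  } else {
    wells <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        depth = numeric(0), width = numeric(0))
  }
  if (bead_eps < 0) stop("bead_eps must be non-negative")
  if (bead_sigma <= 0) stop("bead_sigma must be positive")
  use_coulomb <- !is.null(bead_charge)
  if (use_coulomb && length(bead_charge) != nrow(bead_positions))
    stop("bead_charge must have one value per bead")
  if (dielectric <= 0) stop("dielectric must be positive")
  structure(list(wells = wells, beads = bead_positions, eps = bead_eps,
                 sigma = bead_sigma, use_coulomb = use_coulomb,
                 bead_charge = bead_charge, dielectric = dielectric),
            class = "potential_spec")
}

# Internal: list form consumed by the C++ kernels.
pot_cpp <- function(spec) {
  list(wells = unname(as.matrix(spec$wells[, c("x", "y", "z", "depth", "width")])),
       beads = unname(spec$beads), eps = spec$eps, sigma = spec$sigma,
       use_coulomb = isTRUE(spec$use_coulomb),
       bead_charge = if (isTRUE(spec$use_coulomb)) as.numeric(spec$bead_charge) else numeric(0),
       dielectric = spec$dielectric)
}

as_position_matrix <- function(position) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3, byrow = TRUE)
  position <- as.matrix(position)
  if (ncol(position) != 3) stop("positions must be 3-vectors")
  if (!all(is.finite(position))) stop("positions must be finite")
  position
}

#' Toy potential energy
#'
#' Evaluates the potential at one or more ligand-atom positions (kcal/mol);
#' rows of a matrix are treated as independent atoms and summed.
#'
#' @param spec a [potential_spec()].
#' @param position a 3-vector or an n x 3 matrix, A.
#' @param charge per-atom charges (e); default 0.
#' @return Total energy, kcal/mol.
#' @export
potential_energy <- function(spec, position, charge = 0) {
  pos <- as_position_matrix(position)
  cpp_potential_energy(pos, rep_len(as.numeric(charge), nrow(pos)), pot_cpp(spec))
}

#' Toy potential forces
#'
#' Analytic force -grad U on each ligand atom, kcal/(mol A).
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix of forces (a plain 3-vector input returns a 1 x 3
#'   matrix).
#' @export
potential_forces <- function(spec, position, charge = 0) {
  pos <- as_position_matrix(position)
  cpp_potential_forces(pos, rep_len(as.numeric(charge), nrow(pos)), pot_cpp(spec))
}

#' Build the coarse-grained funnel receptor system
#'
#' Constructs the built-in bead-model receptor: a funnel of repulsive beads
#' around a deep "orthosteric" Gaussian well at the funnel base, a shallower
#' metastable "meta" well at the funnel mouth rim (emulating a solvent-exposed
#' vestibular site), a floor cap closing the pocket from below, and a single
#' mobile ligand bead starting in the bulk. Receptor beads are frozen; the
#' `funnel_scale` switch widens the funnel (emulating the more flexible,
#' larger-volume receptor state) without integrating receptor motion.
#'
#' @param n_beads total receptor beads (>= 24; default 80).
#' @param pocket_depth orthosteric well depth, kcal/mol (> meta_site_depth).
#' @param meta_site_depth metastable-site well depth, kcal/mol.
#' @param seed integer seed controlling the (small) bead jitter.
#' @param funnel_scale multiplier on funnel ring radii (default 1; > 1 widens
#'   the pocket mouth).
#' @param box cubic box edge length, A (reflecting walls at +/- box/2).
#' @param bead_eps,bead_sigma soft-sphere repulsion parameters.
#' @param ligand_start 3-vector starting position of the ligand bead, A.
#' @param steering_depth depth (kcal/mol) of a broad (10 A) Gaussian term
#'   co-centered on the orthosteric well, mimicking the long-range
#'   electrostatic steering of a charged pocket; 0 disables it.
#' @param ligand_mass effective ligand bead mass, amu. The default (1900)
#'   makes the bead diffuse like a solvated monovalent ion
#'   (D = kB*T/(m*friction) ~ 0.13 A^2/ps at 310 K and 1 ps^-1 friction),
#'   standing in for the hydrodynamic drag an implicit-solvent bead lacks.
#' @return A `toy_system`: list with `receptor`, `ligand` (atom tables),
#'   `sites` (named residue-id lists), `box`, and `potential`.
#' @export
build_receptor_model <- function(n_beads = 80, pocket_depth = 8,
                                 meta_site_depth = 3, seed = 1,
                                 funnel_scale = 1, box = 80,
                                 bead_eps = 0.5, bead_sigma = 3.0,
                                 ligand_start = c(0, 0, 30),
                                 ligand_mass = 1900, steering_depth = 1.5) {
  if (pocket_depth <= 0 || meta_site_depth <= 0)
    stop("well depths must be positive")
  if (pocket_depth <= meta_site_depth)
    stop("pocket_depth must exceed meta_site_depth (the target site is the global minimum)")
  if (n_beads < 24)
    stop("n_beads too small to form a funnel (need at least 24)")
  if (funnel_scale <= 0) stop("funnel_scale must be positive")

  ortho_center <- c(0, 0, -12)
  ring_z <- c(-10, -6, -2, 2, 6)
  ring_r <- (5 + 2 * (seq_along(ring_z) - 1)) * funnel_scale
  mouth_r <- ring_r[length(ring_r)]
  meta_center <- c(mouth_r + 4, 0, 6)

  # floor cap: 1 center bead + ring of 8 below the orthosteric well
  n_floor <- 9L
  n_rest <- n_beads - n_floor
  alloc <- pmax(3L, floor(n_rest * ring_r / sum(ring_r)))
  while (sum(alloc) > n_rest) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_rest) alloc[which.max(ring_r / alloc)] <- alloc[which.max(ring_r / alloc)] + 1L

  coords <- with_private_seed(seed, {
    pts <- list(matrix(c(0, 0, -15.5), 1, 3))
    th <- seq(0, 2 * pi, length.out = 9)[-9]
    pts[[2]] <- cbind(3.5 * cos(th), 3.5 * sin(th), -14.5)
    for (k in seq_along(ring_z)) {
      nk <- alloc[k]
      phase <- stats::runif(1, 0, 2 * pi / nk)
      th <- phase + seq(0, 2 * pi, length.out = nk + 1)[-(nk + 1)]
      pts[[k + 2]] <- cbind(ring_r[k] * cos(th), ring_r[k] * sin(th), ring_z[k])
    }
    xyz <- do.call(rbind, pts)
    xyz + matrix(stats::rnorm(length(xyz), 0, 0.25), nrow(xyz), 3)
  })

  nb <- nrow(coords)
  receptor <- atom_records(serial = seq_len(nb), name = "BD", resname = "FUN",
                           resid = seq_len(nb), chain = "R",
                           x = coords[, 1], y = coords[, 2], z = coords[, 3],
                           mass = 100, vdw = bead_sigma)

  # site residues: a triad of base-ring beads (binding-site residue-triad
  # convention) whose
  # mass-weighted centroid sits over the pocket; three mouth beads nearest
  # the meta well for the vestibular site.
  base_idx <- n_floor + seq_len(alloc[1])
  tri <- base_idx[round(seq(1, length(base_idx), length.out = 4))[1:3]]
  mouth_idx <- n_floor + sum(alloc[-length(alloc)]) + seq_len(alloc[length(alloc)])
  d_meta <- sqrt(colSums((t(coords[mouth_idx, , drop = FALSE]) - meta_center)^2))
  meta_res <- mouth_idx[order(d_meta)[1:3]]

  ligand <- atom_records(serial = nb + 1L, name = "NA", resname = "LIG",
                         resid = 1001L, chain = "L",
                         x = ligand_start[1], y = ligand_start[2],
                         z = ligand_start[3], mass = ligand_mass)

  # short-range binding wells plus a broad, shallow term over the pocket
  # that mimics the long-range electrostatic steering a charged pocket
  # (e.g. a buried aspartate) exerts on an approaching ion
  wells <- data.frame(x = c(ortho_center[1], ortho_center[1], meta_center[1]),
                      y = c(ortho_center[2], ortho_center[2], meta_center[2]),
                      z = c(ortho_center[3], ortho_center[3], meta_center[3]),
                      depth = c(pocket_depth, steering_depth, meta_site_depth),
                      width = c(3.0, 10.0, 3.0))
  pot <- potential_spec(wells, bead_positions = coords,
                        bead_eps = bead_eps, bead_sigma = bead_sigma)

  sys <- structure(list(receptor = receptor, ligand = ligand,
                        sites = list(orthosteric = as.integer(tri),
                                     meta = as.integer(meta_res)),
                        box = rep(box, 3), potential = pot),
                   class = "toy_system")
  validate_toy_system(sys)
  sys
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Toy receptor-ligand system\n")
  cat("  receptor beads:", nrow(x$receptor), " ligand atoms:", nrow(x$ligand), "\n")
  cat("  sites:", paste(names(x$sites), collapse = ", "), "\n")
  cat("  box:", paste(x$box, collapse = " x "), "A\n")
  invisible(x)
}

validate_toy_system <- function(sys, threshold = 5) {
  for (s in names(sys$sites)) {
    miss <- setdiff(sys$sites[[s]], sys$receptor$resid)
    if (length(miss))
      stop("site '", s, "' references missing residue id(s): ",
           paste(miss, collapse = ", "))
    ctr <- site_center(sys, sys$sites[[s]])
    lig <- colSums(atom_xyz(sys$ligand) * sys$ligand$mass) / sum(sys$ligand$mass)
    if (sqrt(sum((lig - ctr)^2)) <= threshold)
      stop("ligand starts inside site '", s, "' (distance <= ", threshold, " A)")
  }
  invisible(TRUE)
}

#' Neutralizing counterion count
#'
#' Number of monovalent anions needed to neutralize a system with the given
#' net solute charge after adding `n_cations` monovalent cations (e.g. a
#' receptor of net charge +11 with 100 Na+ requires 111 Cl-).
#'
#' @param net_charge net solute charge, elementary units (may be negative).
#' @param n_cations number of added monovalent cations.
#' @return Integer count of anions.
#' @export
neutralizing_counterions <- function(net_charge, n_cations) {
  n <- as.integer(round(n_cations + net_charge))
  if (n < 0) stop("system cannot be neutralized with anions alone")
  n
}
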