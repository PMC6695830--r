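test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(10)
  ref <- matrix(rnorm(30), 10, 3)
  s <- kabsch_superpose(ref, ref)
  expect_lt(s$rmsd, 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)

  th <- pi / 2
  R90 <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- ref %*% R90 + matrix(c(5, 0, 0), 10, 3, byrow = TRUE)
  s2 <- kabsch_superpose(mob, ref)
  expect_lt(s2$rmsd, 1e-8)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("Kabsch rmsd matches a brute-force quaternion minimizer", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- ref + matrix(rnorm(30, 0, 0.1), 10, 3)
  got <- kabsch_superpose(mob, ref)$rmsd

  quat_rmsd <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                  2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                  2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
                3, 3)
    A <- sweep(mob, 2, colMeans(mob)) %*% R
    B <- sweep(ref, 2, colMeans(ref))
    sqrt(mean(rowSums((A - B)^2)))
  }
  best <- Inf
  for (i in 1:40) {
    q0 <- rnorm(4)
    o <- optim(q0, quat_rmsd, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-6)
})

test_that("rmsd_series is zero on itself and exact on a pure ligand shift", {
  sys <- build_receptor_model(seed = 2, n_beads = 30)
  topo <- rbind(sys$receptor, sys$ligand)
  ref <- atom_xyz(topo)
  frames <- list(ref, ref, ref)
  traj <- make_traj(topo, frames)
  rs <- rmsd_series(traj, ref)
  expect_true(all(rs$values < 1e-10))
  expect_equal(rs$rmsd_min, min(rs$values))

  lig_row <- nrow(topo)
  shifted <- ref
  shifted[lig_row, 1] <- shifted[lig_row, 1] + 1
  traj2 <- make_traj(topo, list(ref, shifted))
  rs2 <- rmsd_series(traj2, ref, fit_selection = seq_len(lig_row - 1),
                     measure_selection = lig_row)
  expect_equal(rs2$values, c(0, 1), tolerance = 1e-8)
  expect_lte(rs2$rmsd_min, min(rs2$values))
})

test_that("pairwise RMSD matrix matches brute-force recomputation", {
  expect_equal(pairwise_rmsd_matrix(rbind(c(0, 0, 0), c(3, 0, 0))),
               matrix(c(0, 3, 3, 0), 2), ignore_attr = TRUE)

  set.seed(12)
  pts <- matrix(rnorm(30), 10, 3)
  M <- pairwise_rmsd_matrix(pts)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  for (i in 1:10) for (j in 1:10)
    expect_equal(M[i, j], sqrt(sum((pts[i, ] - pts[j, ])^2)))

  # multi-atom frames: coordinate RMSD without re-superposition
  arr <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  M2 <- pairwise_rmsd_matrix(arr)
  for (i in 1:4) for (j in 1:4)
    expect_equal(M2[i, j], sqrt(mean(rowSums((arr[, , i] - arr[, , j])^2))))
})

test_that("DBSCAN separates two tight blobs with no noise", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(300, 0, 0.5), 100, 3),
               sweep(matrix(rnorm(300, 0, 0.5), 100, 3), 2, c(-20, 0, 0)))
  cl <- dbscan_cluster(pts, eps = 2, min_samples = 5)
  expect_identical(cl$n_clusters, 2L)
  expect_false(any(cl$labels == -1L))
  expect_equal(dim(cl$cluster_centroids), c(2L, 3L))
  # centroids are the unweighted member means
  for (k in 1:2)
    expect_equal(cl$cluster_centroids[k, ],
                 colMeans(pts[cl$labels == k, , drop = FALSE]))
})

test_that("DBSCAN edge cases: singleton cluster and all-noise", {
  one <- dbscan_cluster(matrix(c(1, 2, 3), 1, 3), eps = 1, min_samples = 1)
  expect_identical(one$n_clusters, 1L)
  expect_identical(one$labels, 1L)

  sparse <- cbind(seq(0, 90, by = 10), 0, 0)
  allnoise <- dbscan_cluster(sparse, eps = 0.5, min_samples = 2)
  expect_identical(allnoise$n_clusters, 0L)
  expect_true(all(allnoise$labels == -1L))
  expect_error(dbscan_cluster(sparse, eps = -1), "eps")
})

test_that("DBSCAN matches brute-force density reachability across settings", {
  for (s in 1:3) {
    set.seed(s)
    pts <- rbind(matrix(rnorm(150, 0, 1), 50, 3),
                 sweep(matrix(rnorm(150, 0, 1.5), 50, 3), 2, c(8, 0, 0)),
                 matrix(runif(60, -15, 15), 20, 3))
    D <- as.matrix(dist(pts))
    for (par in list(c(1.5, 5), c(2.5, 4), c(1.0, 8))) {
      got <- dbscan_cluster(pts, eps = par[1], min_samples = par[2])
      want <- brute_dbscan(D, eps = par[1], min_samples = par[2])
      expect_identical(got$n_clusters, max(0L, max(want)))
      # border points may attach to either adjacent cluster; compare core
      # points strictly and border/noise status loosely
      core <- rowSums(D <= par[1]) >= par[2]
      expect_true(same_partition(got$labels[core], want[core]))
      expect_identical(got$labels[!core] == -1L, want[!core] == -1L)
    }
  }
})

test_that("DBSCAN labels are invariant to point order", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(90, 0, 0.5), 30, 3),
               sweep(matrix(rnorm(90, 0, 0.5), 30, 3), 2, c(10, 0, 0)))
  perm <- sample(nrow(pts))
  a <- dbscan_cluster(pts, eps = 2, min_samples = 5)
  b <- dbscan_cluster(pts[perm, ], eps = 2, min_samples = 5)
  expect_true(same_partition(a$labels[perm], b$labels))
})

test_that("pocket volume reproduces the analytic sphere and full occlusion", {
  v <- pocket_volume(NULL, center = c(0, 0, 0), radius = 9,
                     grid_spacing = 0.5)
  expect_equal(v, 4 / 3 * pi * 9^3, tolerance = 0.02)

  blocked <- pocket_volume(matrix(c(0, 0, 0), 1, 3), center = c(0, 0, 0),
                           radius = 9, grid_spacing = 0.5, atom_padding = 0,
                           vdw = 20)
  expect_identical(blocked, 0)
  expect_error(pocket_volume(NULL, c(0, 0, 0), radius = 9, grid_spacing = 0),
               "grid_spacing")
})

test_that("pocket volume agrees with a Monte-Carlo oracle and is monotone", {
  set.seed(15)
  atoms <- matrix(runif(90, -8, 8), 30, 3)
  vdw <- runif(30, 1.2, 2.2)
  v_grid <- pocket_volume(atoms, c(0, 0, 0), radius = 9, grid_spacing = 0.5,
                          atom_padding = 1.09, vdw = vdw)
  # MC oracle: uniform samples in the sphere
  ns <- 1e6
  smp <- matrix(runif(3 * ns, -9, 9), ns, 3)
  smp <- smp[rowSums(smp^2) <= 81, , drop = FALSE]
  free <- rep(TRUE, nrow(smp))
  for (a in 1:30) {
    d2 <- (smp[, 1] - atoms[a, 1])^2 + (smp[, 2] - atoms[a, 2])^2 +
      (smp[, 3] - atoms[a, 3])^2
    free <- free & d2 > (vdw[a] + 1.09)^2
  }
  v_mc <- mean(free) * 4 / 3 * pi * 9^3
  # grid error is bounded by the occlusion surface area times the spacing
  expect_lt(abs(v_grid - v_mc), 0.08 * 4 / 3 * pi * 9^3)

  # monotone non-increasing under added atoms and under larger padding
  v_fewer <- pocket_volume(atoms[1:10, ], c(0, 0, 0), radius = 9,
                           grid_spacing = 0.5, atom_padding = 1.09,
                           vdw = vdw[1:10])
  expect_gte(v_fewer, v_grid)
  v_padded <- pocket_volume(atoms, c(0, 0, 0), radius = 9, grid_spacing = 0.5,
                            atom_padding = 2.0, vdw = vdw)
  expect_lte(v_padded, v_grid)
  expect_lte(v_grid, 4 / 3 * pi * 9^3)
})

test_that("volume series is constant on static frames and tracks occlusion", {
  sys <- build_receptor_model(seed = 7)
  topo <- rbind(sys$receptor, sys$ligand)
  fr <- atom_xyz(topo)
  traj <- make_traj(topo, list(fr, fr, fr))
  lig <- nrow(topo)
  vs <- volume_series(traj, lig, center_mode = "fixed",
                      center = site_center(sys, sys$sites$orthosteric),
                      grid_spacing = 1)
  expect_true(all(vs$values == vs$values[1]))
  expect_true(all(vs$values <= 4 / 3 * pi * 9^3))
})

test_that("widening the funnel increases the orthosteric pocket volume", {
  narrow <- build_receptor_model(seed = 8, funnel_scale = 1)
  wide <- build_receptor_model(seed = 8, funnel_scale = 1.3)
  vn <- pocket_volume(narrow$receptor,
                      site_center(narrow, narrow$sites$orthosteric))
  vw <- pocket_volume(wide$receptor,
                      site_center(wide, wide$sites$orthosteric))
  expect_gt(vw, vn)
})

test_that("contact frequencies count residue-ligand encounters", {
  rec <- atom_records(serial = 1:2, name = "CA", resname = c("ALA", "TRP"),
                      resid = 1:2, chain = "A", x = c(2, 50), y = 0, z = 0)
  lig <- atom_records(serial = 3L, name = "NA", resname = "LIG",
                      resid = 100L, chain = "L", x = 0, y = 0, z = 0)
  topo <- rbind(rec, lig)
  class(topo) <- c("sumd_atoms", "data.frame")
  fr <- atom_xyz(topo)
  traj <- make_traj(topo, rep(list(fr), 4))
  ct <- contact_frequencies(traj, ligand_selection = 3, cutoff = 4.5)
  expect_equal(ct$frequency[ct$resid == 1], 1.0)
  expect_equal(ct$frequency[ct$resid == 2], 0.0)

  # contact in exactly 5 of 10 frames
  away <- fr; away[3, 1] <- 30
  traj2 <- make_traj(topo, c(rep(list(fr), 5), rep(list(away), 5)))
  ct2 <- contact_frequencies(traj2, 3, cutoff = 4.5)
  expect_equal(ct2$frequency[ct2$resid == 1], 0.5)

  # frame-order invariance
  traj3 <- make_traj(topo, c(rep(list(away), 5), rep(list(fr), 5)))
  expect_equal(contact_frequencies(traj3, 3)$frequency, ct2$frequency)
})

test_that("contact counts equal a brute-force all-pairs recomputation", {
  set.seed(16)
  rec <- atom_records(serial = 1:12, name = "CA",
                      resname = rep(c("ALA", "SER", "PHE"), each = 4),
                      resid = rep(1:3, each = 4), chain = "A",
                      x = runif(12, -6, 6), y = runif(12, -6, 6),
                      z = runif(12, -6, 6))
  lig <- atom_records(serial = 13:14, name = c("C1", "C2"), resname = "LIG",
                      resid = 99L, chain = "L", x = c(0, 1), y = 0, z = 0)
  topo <- rbind(rec, lig)
  class(topo) <- c("sumd_atoms", "data.frame")
  frames <- lapply(1:6, function(k) atom_xyz(topo) + rnorm(42, 0, 2))
  traj <- make_traj(topo, frames)
  ct <- contact_frequencies(traj, 13:14, cutoff = 4.5)
  for (r in 1:3) {
    want <- 0
    for (fr in frames) {
      dmin <- Inf
      for (i in which(topo$resid == r & topo$chain == "A"))
        for (j in 13:14)
          dmin <- min(dmin, sqrt(sum((fr[i, ] - fr[j, ])^2)))
      if (dmin < 4.5) want <- want + 1
    }
    expect_identical(ct$count[ct$resid == r], as.integer(want))
  }
})

test_that("nonbonded energy decomposes into Coulomb and vdW-like terms", {
  spec1 <- potential_spec(data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0), depth = numeric(0),
                                     width = numeric(0)),
                          bead_positions = matrix(c(0, 0, 0), 1, 3),
                          bead_eps = 0, bead_charge = 1, dielectric = 1)
  e <- nonbonded_energy(spec1, c(1, 0, 0), charge = 1)
  expect_equal(e$electrostatic, 332.0636)

  sys <- build_receptor_model(seed = 9)
  en <- nonbonded_energy(sys$potential, c(3, 2, 1), charge = 0)
  expect_identical(en$electrostatic, 0)

  # decomposition consistency against the total potential
  set.seed(17)
  spec2 <- potential_spec(data.frame(x = 0, y = 0, z = -5, depth = 4,
                                     width = 2),
                          bead_positions = matrix(rnorm(30, 0, 5), 10, 3),
                          bead_eps = 0.5, bead_charge = runif(10, -1, 1),
                          dielectric = 4)
  p <- c(2, 2, 2)
  tot <- nonbonded_energy(spec2, p, charge = 0.7)
  expect_equal(tot$electrostatic + tot$vdw,
               potential_energy(spec2, p, charge = 0.7), tolerance = 1e-10)
})

test_that("coordination counting finds the oxygens around an ion", {
  # synthetic sodium-site fixture: 5 coordinating oxygens within 3 A,
  # plus bystander atoms outside the shell
  ion <- c(0, 0, 0)
  ox <- rbind(c(2.3, 0, 0), c(-2.4, 0.3, 0), c(0, 2.2, 0.5),
              c(0.3, -2.5, 0), c(0, 0.4, 2.4))
  far <- rbind(c(5, 0, 0), c(0, 6, 0))
  carbons <- rbind(c(1.5, 1.5, 0))
  atoms <- atom_records(serial = 1:8,
                        name = c(rep("OD1", 5), "OG", "O", "CB"),
                        resname = "ASP", resid = 1:8, chain = "A",
                        x = c(ox[, 1], far[, 1], carbons[, 1]),
                        y = c(ox[, 2], far[, 2], carbons[, 2]),
                        z = c(ox[, 3], far[, 3], carbons[, 3]))
  expect_identical(coordination_count(atoms, ion, "O", cutoff = 3.0), 5L)
  expect_identical(coordination_count(atoms, ion, "C", cutoff = 3.0), 1L)
})
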