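test_that("pure rigid motion between frames is removed exactly", {
  atoms <- backbone_atoms(5)
  f1 <- spread_coords(nrow(atoms), 4)
  f2 <- rigid_move(f1, deg = 37, shift = c(5, -2, 1))
  ens <- ensemble(atoms, rbind(f1, f2))
  beads <- select_beads(ens)
  sup <- superpose(ens, beads, reference_index = 1)
  expect_lt(max(abs(sup$xyz[2, ] - f1)), 1e-9)
  # reference frame untouched by its own fit
  expect_lt(max(abs(sup$xyz[1, ] - f1)), 1e-9)
})

test_that("an already-centred, aligned ensemble is left unchanged", {
  atoms <- backbone_atoms(4)
  base <- spread_coords(nrow(atoms), 5)
  ens <- ensemble(atoms, rbind(base, base, base))
  beads <- select_beads(ens)
  sup <- superpose(ens, beads)
  expect_lt(max(abs(sup$xyz - ens$xyz)), 1e-9)
})

test_that("refitting a fitted ensemble is a no-op", {
  C <- build_correlation_matrix(c(A = 6), intra = 0.3)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 25, seed = 9)
  ens <- randomly_rigid_move(ens, seed = 10)
  beads <- select_beads(ens)
  sup1 <- superpose(ens, beads)
  sup2 <- superpose(sup1, beads)
  expect_lt(max(abs(sup2$xyz - sup1$xyz)), 1e-9)
})

test_that("the Kabsch fit attains the brute-force minimum RMSD", {
  # independent oracle: numeric minimization over Euler angles from many
  # starting points (no SVD involved)
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  Q <- matrix(c(0, 0, 0, 1, 0, 0, 0, -1, 0), ncol = 3, byrow = TRUE)
  rmsd_after <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
    Pc <- sweep(P, 2, colMeans(P))
    Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% (Rz1 %*% Ry %*% Rz2) - Qc)^2)))
  }
  set.seed(42)
  best <- Inf
  for (k in 1:30) {
    o <- optim(runif(3, -pi, pi), rmsd_after, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  atoms <- data.frame(atom_name = "CA", element = "C",
                      residue_number = 1:3, residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  ens <- ensemble(atoms, rbind(as.vector(t(Q)), as.vector(t(P))))
  beads <- select_beads(ens)
  sup <- superpose(ens, beads, reference_index = 1)
  fitted <- matrix(sup$xyz[2, ], ncol = 3, byrow = TRUE)
  ref <- matrix(sup$xyz[1, ], ncol = 3, byrow = TRUE)
  kabsch_rmsd <- sqrt(mean(rowSums((fitted - ref)^2)))
  expect_equal(kabsch_rmsd, best, tolerance = 1e-6)
})

test_that("the fit agrees with bio3d's reference implementation", {
  C <- build_correlation_matrix(c(A = 8), intra = 0.2)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 12, seed = 31)
  ens <- randomly_rigid_move(ens, seed = 32)
  beads <- select_beads(ens)
  sup <- superpose(ens, beads)
  ref_fit <- suppressWarnings(
    bio3d::fit.xyz(ens$xyz[1, ], ens$xyz,
                   fixed.inds = 1:ncol(ens$xyz),
                   mobile.inds = 1:ncol(ens$xyz)))
  expect_lt(max(abs(sup$xyz - ref_fit)), 1e-6)
})

test_that("degenerate bead sets are refused", {
  atoms <- data.frame(atom_name = "CA", element = "C",
                      residue_number = 1:3, residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  collinear <- as.vector(t(cbind(1:3, 0, 0)))
  ens <- ensemble(atoms, rbind(collinear, collinear))
  expect_error(superpose(ens, select_beads(ens)), "collinear")
  two <- ensemble(atoms[1:2, ], spread_coords(2))
  expect_error(superpose(two, suppressWarnings(select_beads(two))),
               "at least 3 beads")
})

test_that("static ensembles give zero RMSF and zero RMSD", {
  atoms <- backbone_atoms(4)
  base <- spread_coords(nrow(atoms), 6)
  ens <- ensemble(atoms, rbind(base, base, base))
  beads <- select_beads(ens)
  prof <- fluctuation_profile(superpose(ens, beads), beads)
  expect_equal(max(prof$rmsf$rmsf_A), 0)
  expect_equal(max(prof$per_frame$rmsd_A), 0)
  expect_true(all(prof$per_frame$rg_A > 0))
  expect_error(fluctuation_profile(superpose(ens, beads), beads, window = 1),
               "2 frames")
})

test_that("isotropic displacements give RMSF = sigma * sqrt(3)", {
  C <- build_correlation_matrix(c(A = 10), intra = 0)
  ens <- sample_gaussian_ensemble(C, stddev = 0.5, n_frames = 20000,
                                  seed = 77, mode = "isotropic")
  beads <- select_beads(ens)
  prof <- fluctuation_profile(as_superposed(ens), beads)
  expect_true(all(abs(prof$rmsf$rmsf_A - 0.5 * sqrt(3)) < 0.02))
})

test_that("RMSF^2 equals the trace of the bead's covariance block", {
  C <- build_correlation_matrix(c(A = 4, B = 4), intra = 0.6, inter = -0.2)
  ens <- sample_gaussian_ensemble(C, 0.8, n_frames = 300, seed = 15)
  beads <- select_beads(ens)
  sup <- as_superposed(ens)
  prof <- fluctuation_profile(sup, beads)
  cv <- covariance(sup, beads, mass_weighted = FALSE)
  tr <- vapply(seq_len(nrow(beads)), function(i)
    sum(diag(cv$matrix[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)])),
    numeric(1))
  expect_equal(prof$rmsf$rmsf_A^2, tr, tolerance = 1e-9)
})

test_that("component RMSF means are bead-count-weighted means over components", {
  C <- build_correlation_matrix(c(A = 3, B = 5), intra = 0.4, inter = 0)
  ens <- sample_gaussian_ensemble(C, c(rep(0.5, 3), rep(1.5, 5)),
                                  n_frames = 500, seed = 4)
  beads <- select_beads(ens, two_block_map(3, 5))
  prof <- fluctuation_profile(as_superposed(ens), beads)
  expect_equal(prof$component_rmsf$mean_rmsf_A[prof$component_rmsf$component == "A"],
               mean(prof$rmsf$rmsf_A[1:3]))
  expect_equal(prof$component_rmsf$n_beads, c(3L, 5L))
})
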