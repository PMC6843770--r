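test_that("covariance matches the hand-computed two-frame example", {
  atoms <- data.frame(atom_name = "CA", element = "C",
                      residue_number = 1:3, residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  atoms$mass <- 12
  # bead 1 moves (0,0,0) -> (2,0,0); others fixed (spread so the fit is sane)
  f1 <- c(0, 0, 0, 5, 5, 0, 9, 0, 3)
  f2 <- c(2, 0, 0, 5, 5, 0, 9, 0, 3)
  ens <- ensemble(atoms, rbind(f1, f2))
  beads <- select_beads(ens)
  cv <- covariance(as_superposed(ens), beads, mass_weighted = TRUE)
  # displacement about the mean is +-1 A in x: <dx^2> = 1; times mass 12
  expect_equal(cv$matrix[1, 1], 12)
  expect_equal(sum(abs(cv$matrix)) , 12)  # everything else is static
  expect_error(covariance(ens, beads), "superpose")
})

test_that("static ensembles give a zero covariance matrix", {
  atoms <- backbone_atoms(3)
  base <- spread_coords(nrow(atoms), 2)
  ens <- ensemble(atoms, rbind(base, base))
  beads <- select_beads(ens)
  cv <- covariance(as_superposed(ens), beads)
  expect_equal(max(abs(cv$matrix)), 0)
})

test_that("mass rescaling scales the covariance but leaves CCij unchanged", {
  C <- build_correlation_matrix(c(A = 4), intra = 0.5)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 60, seed = 12)
  beads <- select_beads(ens)
  sup <- as_superposed(ens)
  cv1 <- covariance(sup, beads)
  beads2 <- beads
  beads2$mass <- beads$mass * 2
  cv2 <- covariance(sup, beads2)
  expect_equal(cv2$matrix, 2 * cv1$matrix, tolerance = 1e-12)
  expect_equal(cross_correlation(cv2)$cc, cross_correlation(cv1)$cc,
               tolerance = 1e-12)
})

test_that("perfectly correlated and anti-correlated beads reach +1 / -1", {
  atoms <- data.frame(atom_name = "CA", element = "C",
                      residue_number = 1:3, residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  set.seed(20)
  n <- 50
  d <- rnorm(n)
  # bead2 mirrors bead1's x-displacement; bead3 negates it
  xyz <- cbind(d, 0, 0, 10 + d, 0, 0, 20 - d, 0, 0)
  ens <- ensemble(atoms, xyz)
  cc <- cross_correlation(covariance(as_superposed(ens), select_beads(ens)))$cc
  expect_equal(cc[1, 2], 1)
  expect_equal(cc[1, 3], -1)
  expect_equal(diag(cc), rep(1, 3))
  expect_true(all(abs(cc) <= 1 + 1e-9))
})

test_that("zero-variance beads error by name, or zero out under the policy", {
  atoms <- data.frame(atom_name = "CA", element = "C",
                      residue_number = 1:3, residue_name = "ALA",
                      chain_id = "A", stringsAsFactors = FALSE)
  set.seed(21)
  d <- rnorm(30)
  xyz <- cbind(d, 0, 0, 10, 5, 0, 20 - d, 0, 0)  # bead 2 immobile
  ens <- ensemble(atoms, xyz)
  cv <- covariance(as_superposed(ens), select_beads(ens))
  expect_error(cross_correlation(cv), "A/2")
  expect_warning(cc <- cross_correlation(cv, zero_policy = "zero"),
                 "immobile")
  expect_equal(cc$cc[2, c(1, 3)], c(0, 0))
  expect_equal(cc$cc[2, 2], 1)
})

test_that("planted block correlations are recovered across the CC matrix", {
  C <- build_correlation_matrix(c(A = 20, B = 20), intra = c(0.9, 0.5),
                                inter = 0)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 20000, seed = 33)
  beads <- select_beads(ens, two_block_map(20, 20))
  cc <- cross_correlation(covariance(as_superposed(ens), beads))$cc
  off_mean <- function(M) mean(M[row(M) != col(M)])
  expect_lt(abs(off_mean(cc[1:20, 1:20]) - 0.9), 3 * (1 - 0.9^2) / sqrt(20000))
  expect_lt(abs(off_mean(cc[21:40, 21:40]) - 0.5), 3 * (1 - 0.5^2) / sqrt(20000))
  expect_lt(abs(mean(cc[1:20, 21:40])), 3 / sqrt(20000))
})

test_that("ensdyn's DCCM agrees with bio3d's implementation", {
  C <- build_correlation_matrix(c(A = 5, B = 5), intra = 0.7, inter = -0.3)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 200, seed = 44)
  beads <- select_beads(ens)
  mine <- cross_correlation(covariance(as_superposed(ens), beads))$cc
  theirs <- bio3d::dccm(ens$xyz, pre.fit = FALSE)
  expect_equal(unname(mine), unname(theirs[,]), tolerance = 1e-6)
})

test_that("correlation scores are block means of CCij", {
  # hand 5x5 CC matrix; A = beads 1-2, B = beads 3-5
  cc <- matrix(c(
    1.0, 0.8, -0.1, -0.2, -0.3,
    0.8, 1.0, -0.4, -0.5, -0.6,
    -0.1, -0.4, 1.0, 0.7, 0.6,
    -0.2, -0.5, 0.7, 1.0, 0.5,
    -0.3, -0.6, 0.6, 0.5, 1.0), 5, 5, byrow = TRUE)
  beads <- data.frame(atom_index = 1:5, atom_name = "CA", chain_id = "A",
                      residue_number = 1:5, residue_name = "ALA",
                      component = c("A", "A", "B", "B", "B"), mass = 12,
                      stringsAsFactors = FALSE)
  ccm <- structure(list(cc = cc, beads = beads),
                   class = "cross_correlation_matrix")
  cs <- correlation_scores(ccm)$cs
  # brute-force double loop
  bf <- 0
  for (i in 1:2) for (j in 3:5) bf <- bf + cc[i, j]
  expect_equal(cs["A", "B"], bf / 6)
  expect_equal(cs["A", "A"], mean(cc[1:2, 1:2]))  # diagonal includes i = j
  expect_equal(cs, t(cs))
  # single-bead components: CS equals the raw CCij
  beads1 <- beads
  beads1$component <- c("x", "unassigned", "y", "unassigned", "unassigned")
  ccm1 <- structure(list(cc = cc, beads = beads1),
                    class = "cross_correlation_matrix")
  expect_equal(correlation_scores(ccm1)$cs["x", "y"], cc[1, 3])
  # constant block: CS equals the constant
  cc2 <- cc; cc2[1:2, 3:5] <- 0.4; cc2[3:5, 1:2] <- 0.4
  ccm2 <- structure(list(cc = cc2, beads = beads),
                    class = "cross_correlation_matrix")
  expect_equal(correlation_scores(ccm2)$cs["A", "B"], 0.4)
})

test_that("the trivial one-component map reduces CS to the grand mean", {
  C <- build_correlation_matrix(c(A = 6, B = 6), intra = 0.5, inter = -0.4)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 100, seed = 3)
  beads <- select_beads(ens, component_map(data.frame(
    component_name = "all", chain_id = "A",
    residue_start = 1, residue_end = 12)))
  ccm <- cross_correlation(covariance(as_superposed(ens), beads))
  cs <- correlation_scores(ccm)$cs
  expect_equal(cs["all", "all"], mean(ccm$cc), tolerance = 1e-12)
})

test_that("display clipping never touches stored correlation scores", {
  csm <- structure(list(cs = matrix(c(1, -0.9, -0.9, 1), 2,
                                    dimnames = list(c("A", "B"), c("A", "B"))),
                        sizes = c(A = 2L, B = 2L)),
                   class = "correlation_score_matrix")
  clipped <- clip_scores(csm)
  expect_equal(clipped["A", "A"], 0.6)
  expect_equal(clipped["A", "B"], -0.6)
  expect_equal(csm$cs["A", "A"], 1)  # untouched
})

test_that("rigid-body ensembles yield no switch regions", {
  atoms <- backbone_atoms(12)
  base <- spread_coords(nrow(atoms), 9)
  frames <- t(vapply(seq_len(30), function(f)
    rigid_move(base, deg = f, shift = c(f / 10, 0, 0)),
    numeric(length(base))))
  ens <- ensemble(atoms, frames + rnorm(length(frames), sd = 1e-4))
  beads <- select_beads(ens, component_map(data.frame(
    component_name = "all", chain_id = "A",
    residue_start = 1, residue_end = 12)))
  sup <- superpose(ens, beads)
  cv <- covariance(sup, beads)
  ccm <- cross_correlation(cv)
  sw <- detect_switch_regions(ccm, pca_modes(cv), "all")
  expect_equal(nrow(sw), 0)
})

test_that("the planted hinge is found as exactly one region containing the pivot", {
  h <- make_hinge_ensemble(30, 30, amplitude = 20, n_frames = 5000, seed = 5)
  beads <- select_beads(h, hinge_component_map(30, 30))
  cv <- covariance(as_superposed(h), beads)
  ccm <- suppressWarnings(cross_correlation(cv, zero_policy = "zero"))
  sw <- detect_switch_regions(ccm, pca_modes(cv), "seg1")
  expect_equal(nrow(sw), 1)
  expect_lte(sw$residue_start, 30)
  expect_gte(sw$residue_end, 30)
  expect_equal(sw$flank_left, "seg1")
  expect_equal(sw$flank_right, "seg2")
  expect_error(detect_switch_regions(ccm, pca_modes(cv), "nope"),
               "unknown probe_block")
})

test_that("a low-amplitude bridge between anticorrelated blocks is localized", {
  # blocks 1-49 and 53-100 anticorrelated; beads 50-52 are a quiet bridge
  blocks <- c(A = 49, bridge = 3, B = 48)
  intra <- c(0.95, 0.05, 0.95)
  inter <- matrix(c(1, 0, -0.9, 0, 1, 0, -0.9, 0, 1), 3, 3)
  C <- build_correlation_matrix(blocks, intra, inter)
  sd_vec <- c(rep(1, 49), rep(0.05, 3), rep(1, 48))
  ens <- sample_gaussian_ensemble(C, sd_vec, n_frames = 20000, seed = 71)
  map <- component_map(data.frame(
    component_name = c("A", "bridge", "B"), chain_id = "A",
    residue_start = c(1, 50, 53), residue_end = c(49, 52, 100)))
  beads <- select_beads(ens, map)
  cv <- covariance(as_superposed(ens), beads)
  ccm <- cross_correlation(cv)
  sw <- detect_switch_regions(ccm, pca_modes(cv), "A")
  expect_equal(nrow(sw), 1)
  expect_gte(sw$residue_start, 49)
  expect_lte(sw$residue_end, 53)
})

test_that("sum of covariance eigenvalues equals its trace", {
  C <- build_correlation_matrix(c(A = 8, B = 8), intra = 0.6, inter = -0.5)
  ens <- sample_gaussian_ensemble(C, 1, n_frames = 150, seed = 55)
  cv <- covariance(as_superposed(ens), select_beads(ens))
  p <- pca_modes(cv)
  expect_equal(sum(p$values), sum(diag(cv$matrix)),
               tolerance = 1e-9)
})
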