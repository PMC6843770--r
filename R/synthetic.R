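# Synthetic conformational ensembles with planted statistical structure.
# These generators define the ground truth every analysis stage is tested
# against: block-correlated Gaussian ensembles (cross-correlation and
# correlation-score recovery), two-segment hinge motions (switch-region and
# RMSF recovery), and donor-H-acceptor geometry series (H-bond occupancy).

# default bead geometry for generated ensembles
.bead_spacing <- 3.8  # Angstrom, typical CA-CA distance

synthetic_atoms <- function(n, chain_id = "A") {
  data.frame(
    atom_name = "CA", element = "C",
    residue_number = seq_len(n), residue_name = "ALA",
    chain_id = chain_id, mass = element_mass(rep("C", n)),
    stringsAsFactors = FALSE
  )
}

#' Build a block-structured correlation matrix
#'
#' The matrix has unit diagonal, the given correlation inside each named
#' block, and the given correlation between each block pair.  Feasibility is
#' checked by eigendecomposition: specs whose implied matrix is not positive
#' semidefinite are rejected.
#'
#' @param blocks named integer vector of block sizes (beads per block).
#' @param intra correlation inside each block; length 1 or `length(blocks)`.
#' @param inter correlation between blocks: a single value, or a symmetric
#'   `K x K` matrix over blocks (diagonal ignored).
#' @return correlation matrix (beads x beads) with attribute `blocks`.
#' @export
build_correlation_matrix <- function(blocks, intra, inter = 0) {
  stopifnot(length(blocks) >= 1, all(blocks >= 1))
  if (is.null(names(blocks))) names(blocks) <- paste0("B", seq_along(blocks))
  K <- length(blocks)
  intra <- rep_len(intra, K)
  if (!is.matrix(inter)) {
    inter <- matrix(rep_len(inter, K * K), K, K)
  }
  if (!isTRUE(all.equal(inter, t(inter))))
    stop("inter-block correlation matrix must be symmetric")
  if (any(abs(intra) > 1) || any(abs(inter) > 1))
    stop("correlations must lie in [-1, 1]")
  lab <- rep(seq_len(K), times = blocks)
  n <- sum(blocks)
  C <- inter[lab, lab]
  for (k in seq_len(K)) C[lab == k, lab == k] <- intra[k]
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "infeasibility error: implied correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
      min(ev)))
  attr(C, "blocks") <- rep(names(blocks), times = blocks)
  C
}

#' Sample a Gaussian ensemble with a planted correlation matrix
#'
#' Frames are i.i.d. Gaussian displacements about `mean_coords`.  In the
#' default `"axial"` mode every bead is displaced along one shared random
#' unit direction with amplitudes drawn from the planted correlation, so the
#' expected displacement-vector cross-correlation CCij equals the planted
#' value exactly.  In `"isotropic"` mode the three coordinates are sampled
#' independently, each with the planted correlation across beads; CCij is
#' again exact in expectation and the per-bead RMSF converges to
#' `stddev * sqrt(3)`.
#'
#' Generated frames share a common laboratory frame: mark the result with
#' [as_superposed()] for covariance analysis (see that help page for why a
#' least-squares refit is deliberately avoided on synthetic ensembles).
#'
#' @param correlation correlation matrix from [build_correlation_matrix()]
#'   (or any PSD correlation matrix).
#' @param stddev per-bead displacement standard deviation in Angstrom
#'   (scalar or one value per bead).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param mean_coords optional N x 3 matrix of mean bead positions; defaults
#'   to an extended chain with 3.8 A spacing.
#' @param mode `"axial"` (default) or `"isotropic"`.
#' @return an [ensemble()] with attributes `planted_correlation`,
#'   `directions` (axial mode) and `seed`.
#' @export
sample_gaussian_ensemble <- function(correlation, stddev, n_frames, seed,
                                     mean_coords = NULL,
                                     mode = c("axial", "isotropic")) {
  mode <- match.arg(mode)
  n <- nrow(correlation)
  stopifnot(ncol(correlation) == n)
  if (n_frames < 2)
    stop("n_frames must be >= 2 (covariance undefined for a single frame)")
  sd_vec <- rep_len(stddev, n)
  if (any(sd_vec < 0)) stop("stddev must be non-negative")
  if (is.null(mean_coords))
    mean_coords <- cbind(.bead_spacing * (seq_len(n) - 1), 0, 0)
  stopifnot(nrow(mean_coords) == n, ncol(mean_coords) == 3)

  set.seed(as.integer(seed))
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))  # shared displacement direction (axial mode)
  draw <- function() {
    if (all(sd_vec == 0)) return(matrix(0, n_frames, n))
    s <- MASS::mvrnorm(n_frames, mu = rep(0, n), Sigma = correlation,
                       tol = 1e-6)
    sweep(s, 2, sd_vec, `*`)
  }
  base <- matrix(rep(as.vector(t(mean_coords)), each = n_frames), n_frames)
  if (mode == "axial") {
    s <- draw()
    disp <- cbind(s * u[1], s * u[2], s * u[3])
    # interleave into x1 y1 z1 x2 ... layout
    ord <- as.vector(t(matrix(seq_len(3 * n), n, 3)))
    xyz <- base + disp[, ord, drop = FALSE]
  } else {
    xyz <- base
    for (axis in 1:3) {
      s <- draw()
      xyz[, seq(axis, 3 * n, by = 3)] <- xyz[, seq(axis, 3 * n, by = 3)] + s
    }
  }
  ens <- ensemble(synthetic_atoms(n), xyz)
  attr(ens, "planted_correlation") <- correlation
  attr(ens, "directions") <- matrix(u, n, 3, byrow = TRUE)
  attr(ens, "seed") <- as.integer(seed)
  attr(ens, "mode") <- mode
  ens
}

#' Generate a two-segment hinge ensemble
#'
#' Two straight rigid segments of beads share a pivot bead.  Per frame the
#' opening angle between the segments is `amplitude * sin(phase)` with phase
#' drawn uniformly on `[0, 2*pi)`; both segments swing symmetrically about
#' the bisector, so the pivot bead is exactly immobile and intra-segment
#' distances are constant to machine precision.  Phases are i.i.d. (no
#' temporal autocorrelation): all analyses in this package are frame-order
#' invariant.
#'
#' @param n1,n2 beads per segment (>= 3 each).  The pivot is bead `n1`
#'   (the inner end of segment 1); segment 2 occupies beads `n1+1 .. n1+n2`.
#' @param amplitude peak opening angle in degrees, in (0, 180).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param hinge_index pivot bead index; must equal `n1` (provided so specs
#'   can state it explicitly).
#' @return an [ensemble()] with attribute `planted_hinge` (the pivot bead
#'   index) and `seed`.
#' @export
make_hinge_ensemble <- function(n1, n2, amplitude, n_frames, seed,
                                hinge_index = n1) {
  stopifnot(n1 >= 3, n2 >= 3, n_frames >= 2)
  if (!(amplitude > 0 && amplitude < 180))
    stop("opening_amplitude must lie in (0, 180) degrees")
  if (hinge_index != n1)
    stop("hinge_index must equal n1: the pivot is the inner end of segment 1")
  n <- n1 + n2
  set.seed(as.integer(seed))
  phase <- runif(n_frames, 0, 2 * pi)
  half <- (amplitude * pi / 180) * sin(phase) / 2
  r1 <- .bead_spacing * ((n1 - 1):0)   # beads 1..n1, pivot at radius 0
  r2 <- .bead_spacing * (1:n2)         # beads n1+1..n
  xyz <- matrix(0, n_frames, 3 * n)
  cx <- cos(half); sx <- sin(half)
  for (i in seq_len(n1)) {
    xyz[, 3 * i - 2] <- r1[i] * cx
    xyz[, 3 * i - 1] <- r1[i] * sx
  }
  for (j in seq_len(n2)) {
    i <- n1 + j
    xyz[, 3 * i - 2] <- r2[j] * cx
    xyz[, 3 * i - 1] <- -r2[j] * sx
  }
  ens <- ensemble(synthetic_atoms(n), xyz)
  attr(ens, "planted_hinge") <- as.integer(hinge_index)
  attr(ens, "seed") <- as.integer(seed)
  ens
}

#' Component map for a hinge ensemble
#'
#' Two components covering the two segments (the pivot bead belongs to
#' segment 1), suitable as input to [detect_switch_regions()].
#'
#' @param n1,n2 segment sizes as in [make_hinge_ensemble()].
#' @param chain_id chain label.
#' @return a [component_map()].
#' @export
hinge_component_map <- function(n1, n2, chain_id = "A") {
  component_map(data.frame(
    component_name = c("seg1", "seg2"),
    chain_id = chain_id,
    residue_start = c(1L, n1 + 1L),
    residue_end = c(n1, n1 + n2),
    stringsAsFactors = FALSE
  ))
}

#' Generate a three-atom hydrogen-bond geometry series
#'
#' A donor (N), its hydrogen, and an acceptor (O).  Each frame is
#' independently in the bound geometry with probability `target_occupancy`;
#' otherwise it takes the unbound geometry.  The realized bound fraction is
#' recorded so detection can be checked for exact agreement.
#'
#' @param target_occupancy fraction in \[0, 1\].
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param bound_geometry,unbound_geometry numeric `c(distance, angle)`:
#'   donor-acceptor heavy distance (Angstrom) and donor-H-acceptor angle
#'   (degrees).  The bound geometry must satisfy `criterion`; the unbound
#'   geometry must violate it.
#' @param criterion an [hbond_criterion()] used to validate the geometries.
#' @return an [ensemble()] of 3 atoms with attributes `bound_frames`
#'   (logical per frame), `realized_occupancy` and `seed`.
#' @export
make_hbond_ensemble <- function(target_occupancy, n_frames, seed,
                                bound_geometry = c(2.8, 170),
                                unbound_geometry = c(4.5, 120),
                                criterion = hbond_criterion()) {
  stopifnot(target_occupancy >= 0, target_occupancy <= 1, n_frames >= 1)
  ok <- function(g) g[1] <= criterion$max_heavy_distance &&
    g[2] >= criterion$angle_threshold
  if (!ok(bound_geometry))
    stop("spec error: bound geometry violates the detection criterion")
  if (ok(unbound_geometry))
    stop("spec error: unbound geometry satisfies the detection criterion")
  atoms <- data.frame(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_number = c(1L, 1L, 2L), residue_name = c("ALA", "ALA", "ALA"),
    chain_id = "A", stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  geom_frame <- function(g) {
    d <- g[1]; theta <- g[2] * pi / 180
    # donor at origin, H at (1,0,0); acceptor in the xy-plane at the
    # prescribed D-H...A angle and D-A distance
    psi <- pi - theta  # angle of H->A from +x (H->D is -x)
    rho <- -cos(psi) + sqrt(cos(psi)^2 - 1 + d^2)
    a <- c(1 + rho * cos(psi), rho * sin(psi), 0)
    c(0, 0, 0, 1, 0, 0, a)
  }
  set.seed(as.integer(seed))
  bound <- runif(n_frames) < target_occupancy
  gb <- geom_frame(bound_geometry)
  gu <- geom_frame(unbound_geometry)
  xyz <- matrix(rep(gu, each = n_frames), n_frames)
  if (any(bound)) xyz[bound, ] <- matrix(rep(gb, each = sum(bound)), sum(bound))
  ens <- ensemble(atoms, xyz)
  attr(ens, "bound_frames") <- bound
  attr(ens, "realized_occupancy") <- mean(bound)
  attr(ens, "seed") <- as.integer(seed)
  ens
}
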