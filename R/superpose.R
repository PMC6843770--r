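#' Superpose every frame onto a reference (Kabsch fit)
#'
#' Each frame receives the optimal rigid rotation + translation minimizing
#' the (optionally mass-weighted) RMSD over the bead selection; the
#' transformation is applied to all atoms of the frame, so analyses needing
#' non-bead atoms (e.g. hydrogen bonds) share the common frame.  The
#' rotation is the classical Kabsch solution: SVD of the weighted covariance
#' of centered coordinates with a determinant correction that excludes
#' reflections.
#'
#' @param ensemble an [ensemble()].
#' @param beads a [select_beads()] selection the fit is computed on.
#' @param reference_index frame used as the fit reference (default 1, the
#'   starting configuration of the analysis window by convention).
#' @param weights `"uniform"` (default) or `"mass"`.
#' @return a `superposed_ensemble`.
#' @export
superpose <- function(ensemble, beads, reference_index = 1L,
                      weights = c("uniform", "mass")) {
  stopifnot(inherits(ensemble, "ensemble"))
  weights <- match.arg(weights)
  nf <- n_frames(ensemble)
  if (reference_index < 1 || reference_index > nf)
    stop("reference_index out of range")
  if (nrow(beads) < 3)
    stop("degenerate-fit error: need at least 3 beads to define a fit")
  w <- if (weights == "mass") beads$mass else rep(1, nrow(beads))
  w <- w / sum(w)
  bc <- xyz_cols(beads$atom_index)
  ref <- matrix(ensemble$xyz[reference_index, bc], ncol = 3, byrow = TRUE)
  cref <- colSums(ref * w)
  refc <- sweep(ref, 2, cref)
  sv <- svd(refc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-30))
    stop("degenerate-fit error: reference beads are collinear")
  out <- ensemble$xyz
  na <- n_atoms(ensemble)
  for (f in seq_len(nf)) {
    P <- matrix(ensemble$xyz[f, bc], ncol = 3, byrow = TRUE)
    cP <- colSums(P * w)
    H <- crossprod(sweep(P, 2, cP) * w, refc)
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    allc <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
    fitted <- sweep(sweep(allc, 2, cP) %*% R, 2, cref, `+`)
    out[f, ] <- as.vector(t(fitted))
  }
  res <- ensemble
  res$xyz <- out
  as_superposed(res, reference_index = reference_index, fit_weights = weights)
}

#' RMSD, radius of gyration and RMSF profiles
#'
#' Per-bead RMSF is computed about the mean structure of the analysis window
#' (not the fit reference): `RMSF_i = sqrt(mean |r_i(t) - <r_i>|^2)`.
#' Per-frame RMSD is measured against the fit reference over the bead
#' selection (unweighted); the radius of gyration is mass-weighted.
#' Component means are plain means over the beads of each named component.
#'
#' @param superposed a `superposed_ensemble` from [superpose()] or
#'   [as_superposed()].
#' @param beads a [select_beads()] selection.
#' @param window integer vector of frame indices (1-based) to analyse, or
#'   `NULL` for all frames; must contain at least 2 frames.
#' @return a list of class `fluctuation_profile` with elements `rmsf`
#'   (per-bead data frame), `per_frame` (frame, rmsd_A, rg_A) and
#'   `component_rmsf` (named-component means).
#' @export
fluctuation_profile <- function(superposed, beads, window = NULL) {
  if (!inherits(superposed, "superposed_ensemble"))
    stop("superpose() the ensemble first")
  if (is.null(window)) window <- seq_len(n_frames(superposed))
  window <- as.integer(window)
  if (length(window) < 2)
    stop("RMSF is undefined for a window of fewer than 2 frames")
  B <- bead_xyz(superposed, beads, window)
  mu <- colMeans(B)
  D <- sweep(B, 2, mu)
  nb <- nrow(beads)
  sq <- colMeans(D^2)                      # per-coordinate variances (pop.)
  rmsf <- sqrt(sq[seq(1, 3 * nb, 3)] + sq[seq(2, 3 * nb, 3)] +
                 sq[seq(3, 3 * nb, 3)])
  ref <- superposed$xyz[superposed$reference_index, xyz_cols(beads$atom_index)]
  dev <- sweep(B, 2, ref)
  rmsd <- sqrt(rowSums(dev^2) / nb)
  rg <- rg_per_frame(B, beads$mass)
  rmsf_df <- cbind(beads[, c("chain_id", "residue_number", "residue_name",
                             "component")],
                   rmsf_A = as.numeric(rmsf))
  named <- rmsf_df$component != "unassigned"
  comp_rmsf <- if (any(named)) {
    agg <- tapply(rmsf_df$rmsf_A[named], rmsf_df$component[named], mean)
    data.frame(component = names(agg), mean_rmsf_A = as.numeric(agg),
               n_beads = as.integer(table(rmsf_df$component[named])[names(agg)]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(component = character(), mean_rmsf_A = numeric(),
               n_beads = integer())
  }
  structure(list(
    rmsf = rmsf_df,
    per_frame = data.frame(frame = window,
                           label = superposed$frame_labels[window],
                           rmsd_A = rmsd, rg_A = rg),
    component_rmsf = comp_rmsf,
    window = window
  ), class = "fluctuation_profile")
}

# mass-weighted radius of gyration per frame from bead coordinates
rg_per_frame <- function(B, mass) {
  n <- length(mass)
  M <- sum(mass)
  xi <- seq(1, 3 * n, 3)
  vapply(seq_len(nrow(B)), function(f) {
    P <- matrix(B[f, ], ncol = 3, byrow = TRUE)
    com <- colSums(P * mass) / M
    sqrt(sum(mass * rowSums(sweep(P, 2, com)^2)) / M)
  }, numeric(1))
}
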