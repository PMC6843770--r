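#' Eigen-decomposition of the covariance matrix (essential dynamics)
#'
#' Modes are sorted by eigenvalue (descending): the leading eigenvectors are
#' the directions of the largest-amplitude collective motions sampled by the
#' ensemble.  Cumulative variance is computed over all 3N eigenvalues even
#' when fewer eigenvectors are returned.  Eigenvector signs are arbitrary;
#' for reproducibility the component with the largest magnitude is forced
#' positive.
#'
#' @param cov a [covariance()] result.
#' @param n_modes number of eigenvectors to return (default
#'   `min(20, 3N)`).
#' @return object of class `pca_modes`: list with `values` (all 3N
#'   eigenvalues, amu A^2 when mass-weighted), `vectors` (3N x n_modes,
#'   orthonormal), `cumulative_variance` (length 3N), `beads`, `window`,
#'   `mass_weighted`.
#' @export
pca_modes <- function(cov, n_modes = NULL) {
  stopifnot(inherits(cov, "covariance_matrix"))
  C <- cov$matrix
  if (!isSymmetric(C, tol = 1e-8)) stop("covariance matrix is not symmetric")
  p <- ncol(C)
  if (is.null(n_modes)) n_modes <- min(20L, p)
  if (n_modes < 1 || n_modes > p) stop("n_modes must lie in 1..3N")
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  tot <- sum(vals)
  cumvar <- if (tot > 0) cumsum(vals) / tot else rep(NA_real_, p)
  V <- e$vectors[, seq_len(n_modes), drop = FALSE]
  for (k in seq_len(n_modes)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(values = vals, vectors = V, cumulative_variance = cumvar,
                 beads = cov$beads, window = cov$window,
                 mass_weighted = cov$mass_weighted),
            class = "pca_modes")
}

#' Per-bead displacement vectors of a mode
#'
#' @param pca a [pca_modes()] result.
#' @param mode mode index (1-based, within the returned vectors).
#' @return N x 3 matrix of the mode's per-bead 3-vectors.
#' @export
mode_displacements <- function(pca, mode = 1L) {
  stopifnot(inherits(pca, "pca_modes"))
  if (mode < 1 || mode > ncol(pca$vectors)) stop("mode out of range")
  matrix(pca$vectors[, mode], ncol = 3, byrow = TRUE)
}

#' Project an ensemble onto a principal component
#'
#' Per frame, the (mass-weighted, matching the covariance) displacement
#' about the window mean is projected onto the chosen eigenvector.  With
#' matching window and weighting, the population variance of the
#' projections equals the mode's eigenvalue.
#'
#' @param superposed the `superposed_ensemble` the PCA was computed from.
#' @param pca a [pca_modes()] result.
#' @param mode mode index (1-based).
#' @return numeric vector of per-frame scalar projections over the PCA
#'   window.
#' @export
project_mode <- function(superposed, pca, mode = 1L) {
  stopifnot(inherits(superposed, "superposed_ensemble"),
            inherits(pca, "pca_modes"))
  if (mode < 1 || mode > ncol(pca$vectors)) stop("mode out of range")
  B <- bead_xyz(superposed, pca$beads, pca$window)
  D <- sweep(B, 2, colMeans(B))
  if (pca$mass_weighted)
    D <- sweep(D, 2, rep(sqrt(pca$beads$mass), each = 3), `*`)
  as.numeric(D %*% pca$vectors[, mode])
}

#' Export modes in NMD (Normal Mode Wizard) format
#'
#' Writes an NMWiz-compatible plain-text file with `atomnames`, `resnames`,
#' `resids`, `chainids`, `coordinates` and one `mode` line per requested
#' mode (index followed by the 3N vector components).  `scale` multiplies
#' the vector components only; coordinates are untouched.
#'
#' @param pca a [pca_modes()] result.
#' @param reference_coords N x 3 matrix of bead coordinates the arrows are
#'   drawn from.
#' @param path output file path.
#' @param modes integer vector of mode indices to export.
#' @param scale scale factor applied to mode components.
#' @param title name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_nmd <- function(pca, reference_coords, path, modes = 1:2, scale = 1,
                      title = "ensdyn modes") {
  stopifnot(inherits(pca, "pca_modes"))
  beads <- pca$beads
  stopifnot(nrow(reference_coords) == nrow(beads), ncol(reference_coords) == 3)
  if (any(modes < 1) || any(modes > ncol(pca$vectors)))
    stop("mode out of range")
  num <- function(x) sprintf("%.9g", x)
  lines <- c(
    paste("name", title),
    paste("atomnames", paste(beads$atom_name, collapse = " ")),
    paste("resnames", paste(beads$residue_name, collapse = " ")),
    paste("resids", paste(beads$residue_number, collapse = " ")),
    paste("chainids", paste(beads$chain_id, collapse = " ")),
    paste("coordinates", paste(num(as.vector(t(reference_coords))),
                               collapse = " "))
  )
  for (k in modes) {
    lines <- c(lines, paste("mode", k,
                            paste(num(pca$vectors[, k] * scale),
                                  collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an NMD file written by [write_nmd()]
#'
#' @param path NMD file path.
#' @return list with `atomnames`, `resnames`, `resids`, `chainids`,
#'   `coordinates` (N x 3) and `modes` (named list of 3N vectors, names are
#'   mode indices).
#' @export
read_nmd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list(modes = list())
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) next
    key <- tok[1]
    if (key == "atomnames") out$atomnames <- tok[-1]
    else if (key == "resnames") out$resnames <- tok[-1]
    else if (key == "resids") out$resids <- as.integer(tok[-1])
    else if (key == "chainids") out$chainids <- tok[-1]
    else if (key == "coordinates")
      out$coordinates <- matrix(as.numeric(tok[-1]), ncol = 3, byrow = TRUE)
    else if (key == "mode")
      out$modes[[tok[2]]] <- as.numeric(tok[-(1:2)])
  }
  out
}
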