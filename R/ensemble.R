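#' Conformational ensemble
#'
#' An ensemble couples a fixed atom table with an ordered set of coordinate
#' frames.  Coordinates are stored in Angstrom in the `bio3d` "xyz" layout:
#' one row per frame, columns `x1, y1, z1, x2, ...`.
#'
#' @param atoms data frame with columns `atom_name`, `element`,
#'   `residue_number`, `residue_name`, `chain_id`, `mass`.  Missing `element`
#'   is inferred from `atom_name`; missing `mass` from `element`.
#' @param xyz numeric matrix of coordinates (frames x 3*atoms), or a numeric
#'   vector for a single frame.  All values must be finite.
#' @param frame_labels optional numeric frame labels (e.g. time in ns);
#'   defaults to `0:(n_frames - 1)`.
#' @return an object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz, frame_labels = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_name", "residue_number", "residue_name", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty-input error: atom table has zero atoms")
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$atom_name)
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be positive and finite")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, residue_number, atom_name): ",
         key[which(duplicated(key))[1]])
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (!is.matrix(xyz) || !is.numeric(xyz))
    stop("xyz must be a numeric matrix (frames x 3*atoms)")
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("dimension error: xyz has ", ncol(xyz), " columns but atom table ",
         "implies ", 3L * nrow(atoms))
  if (nrow(xyz) < 1) stop("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  if (is.null(frame_labels)) frame_labels <- seq_len(nrow(xyz)) - 1
  if (length(frame_labels) != nrow(xyz))
    stop("frame_labels length must equal the number of frames")
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz,
                 frame_labels = as.numeric(frame_labels)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<%s> %d atoms, %d frame(s)\n",
              paste(class(x), collapse = "/"), n_atoms(x), n_frames(x)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an [ensemble()].
#' @return integer count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Number of atoms in an ensemble
#' @param ensemble an [ensemble()].
#' @return integer count.
#' @export
n_atoms <- function(ensemble) nrow(ensemble$atoms)

#' Extract one frame as an N x 3 coordinate matrix
#' @param ensemble an [ensemble()].
#' @param i frame index (1-based).
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
frame_coords <- function(ensemble, i = 1L) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

# columns of the xyz matrix belonging to atom (or bead) indices
xyz_cols <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

#' Mark an ensemble as already superposed
#'
#' Ensembles produced by the synthetic generators are constructed in a common
#' laboratory frame: no global rotation or translation is ever applied, so a
#' least-squares fit is unnecessary.  Refitting such an ensemble would remove
#' part of the planted collective displacement field (the usual fit-induced
#' bias of RMS fitting), so recovery analyses use this constructor instead of
#' [superpose()].  Use [superpose()] for any ensemble whose frames may carry
#' rigid-body motion.
#'
#' @param ensemble an [ensemble()].
#' @param reference_index frame used as reference for RMSD reporting.
#' @param fit_weights label recorded for provenance (`"uniform"` or `"mass"`).
#' @return the ensemble with class `superposed_ensemble` prepended.
#' @export
as_superposed <- function(ensemble, reference_index = 1L,
                          fit_weights = "uniform") {
  stopifnot(inherits(ensemble, "ensemble"))
  stopifnot(reference_index >= 1, reference_index <= n_frames(ensemble))
  ensemble$reference_index <- as.integer(reference_index)
  ensemble$fit_weights <- fit_weights
  class(ensemble) <- unique(c("superposed_ensemble", class(ensemble)))
  ensemble
}
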