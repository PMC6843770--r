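# Residue-name vocabularies used for bead selection: one bead per residue,
# CA for amino acids and P for nucleotides.
.amino_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN", "SEC", "PYL"
)
.nucleotide_residues <- c(
  "A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU",
  "RA", "RC", "RG", "RU", "A5", "C5", "G5", "U5", "A3", "C3", "G3", "U3"
)

# ---- structure / trajectory readers -----------------------------------------

#' Read a structure or multi-model ensemble from PDB or GRO
#'
#' Multi-model PDB files yield one frame per `MODEL` record.  GRO coordinates
#' (stored in nm by the format standard) are converted to Angstrom on read.
#' Alternate locations: only altloc 'A' or blank is kept, so the one-bead-
#' per-residue invariant holds downstream.  Masses come from an element
#' lookup, never from the file.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension when missing.
#' @return an [ensemble()].
#' @export
read_structure <- function(path, format = c("pdb", "gro")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(format) > 1)
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  format <- match.arg(format, c("pdb", "gro"))
  if (format == "pdb") read_pdb_ensemble(path) else read_gro_ensemble(path)
}

read_pdb_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  nmodels <- max(1L, sum(grepl("^MODEL", lines)))
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = nmodels > 1, rm.alt = TRUE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("empty-input error: no atoms in ", path)
  elem <- at$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  if (any(bad)) elem[bad] <- infer_element(at$elety[bad])
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    element = trimws(elem),
    residue_number = at$resno,
    residue_name = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  atoms$mass <- element_mass(atoms$element)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  ensemble(atoms, xyz)
}

# Pre-validation with line numbers: bio3d is lenient, but malformed records
# and models with inconsistent atom counts must be reported precisely.
validate_pdb_lines <- function(lines, path) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("empty-input error: no ATOM/HETATM records in ", path)
  short <- is_atom & nchar(lines) < 54
  if (any(short))
    stop("parse error in ", path, " at line ", which(short)[1],
         ": ATOM/HETATM record shorter than the coordinate fields")
  coords <- substr(lines[is_atom], 31, 54)
  ok <- grepl("^[-+ .0-9]{24}$", coords)
  if (!all(ok))
    stop("parse error in ", path, " at line ", which(is_atom)[!ok][1],
         ": unreadable coordinate fields")
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      stop("parse error in ", path, ": MODEL without matching ENDMDL")
    counts <- mapply(function(s, e) sum(is_atom[s:e]), starts, ends)
    if (length(unique(counts)) > 1) {
      k <- which(counts != counts[1])[1]
      stop("inconsistent atom count: model ", k, " has ", counts[k],
           " atoms but model 1 has ", counts[1])
    }
  }
  invisible(TRUE)
}

# GRO is a simple fixed-width format; no installed R package reads it.
# Columns: resno(1-5) resname(6-10) atomname(11-15) atomno(16-20)
# x,y,z in nm as %8.3f.  Concatenated frames are supported.
read_gro_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    if (i + 1L > length(lines)) stop("parse error in ", path, " at line ", i,
                                     ": truncated GRO header")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1)
      stop("parse error in ", path, " at line ", i + 1L,
           ": invalid atom count")
    rows <- lines[(i + 2L):(i + 1L + nat)]
    if (length(rows) < nat || any(nchar(rows) < 44))
      stop("parse error in ", path, " at line ", i + 1L + length(rows),
           ": truncated GRO frame")
    fr <- data.frame(
      residue_number = as.integer(substr(rows, 1, 5)),
      residue_name = trimws(substr(rows, 6, 10)),
      atom_name = trimws(substr(rows, 11, 15)),
      x = as.numeric(substr(rows, 21, 28)) * 10,
      y = as.numeric(substr(rows, 29, 36)) * 10,
      z = as.numeric(substr(rows, 37, 44)) * 10,
      stringsAsFactors = FALSE
    )
    if (anyNA(fr))
      stop("parse error in ", path, ": unreadable GRO fields near line ", i + 2L)
    if (is.null(atoms)) {
      atoms <- data.frame(
        atom_name = fr$atom_name,
        element = infer_element(fr$atom_name),
        residue_number = fr$residue_number,
        residue_name = fr$residue_name,
        chain_id = "A",
        stringsAsFactors = FALSE
      )
    } else if (nrow(fr) != nrow(atoms)) {
      stop("inconsistent atom count across GRO frames in ", path)
    }
    frames[[length(frames) + 1L]] <- as.vector(t(as.matrix(fr[, c("x", "y", "z")])))
    i <- i + 3L + nat  # title + count + atoms + box line
  }
  if (length(frames) == 0) stop("empty-input error: no frames in ", path)
  ensemble(atoms, do.call(rbind, frames))
}

#' Read a trajectory against a topology
#'
#' @param topology path to a PDB or GRO file; only its atom table is used.
#' @param coords path to the coordinate file.
#' @param format `"dcd"` or `"multi_model_pdb"`; guessed from the extension.
#' @return an [ensemble()] with frames in file order; frame labels are frame
#'   indices (DCD stride metadata is not propagated by the reader used).
#' @export
read_trajectory <- function(topology, coords,
                            format = c("dcd", "multi_model_pdb")) {
  if (length(format) > 1)
    format <- if (grepl("\\.dcd$", coords, ignore.case = TRUE)) "dcd"
              else "multi_model_pdb"
  format <- match.arg(format, c("dcd", "multi_model_pdb"))
  top <- read_structure(topology)
  if (format == "dcd") {
    if (!file.exists(coords)) stop("file not found: ", coords)
    xyz <- tryCatch(
      suppressWarnings(bio3d::read.dcd(coords, verbose = FALSE)),
      error = function(e) {
        stop("truncated or unreadable DCD '", coords, "': ",
             conditionMessage(e), call. = FALSE)
      })
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    xyz <- read_structure(coords, "pdb")$xyz
  }
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("dimension error: topology has ", n_atoms(top),
         " atoms but trajectory frames have ", ncol(xyz) / 3)
  ensemble(top$atoms, xyz)
}

# ---- writers ----------------------------------------------------------------

#' Write an ensemble as a multi-model PDB or DCD trajectory
#'
#' PDB output keeps three decimals (round trips to 1e-3 Angstrom); DCD output
#' is single-precision binary in the CHARMM layout.
#'
#' @param ensemble an [ensemble()].
#' @param path output file path.
#' @param format `"multi_model_pdb"` or `"dcd"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ensemble, path,
                             format = c("multi_model_pdb", "dcd")) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (length(format) > 1)
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd"
              else "multi_model_pdb"
  format <- match.arg(format, c("multi_model_pdb", "dcd"))
  if (format == "multi_model_pdb") {
    at <- ensemble$atoms
    suppressWarnings(bio3d::write.pdb(
      pdb = NULL, file = path, xyz = ensemble$xyz,
      resno = at$residue_number, resid = at$residue_name,
      eleno = seq_len(nrow(at)), elety = at$atom_name,
      chain = at$chain_id, elesy = at$element
    ))
  } else {
    write_dcd(ensemble$xyz, path)
  }
  invisible(path)
}

# Minimal CHARMM-format DCD writer (no installed R package provides one).
# Fortran unformatted records framed by int32 byte counts; one X, Y and Z
# float record per frame; no unit-cell records.
write_dcd <- function(xyz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  nframes <- nrow(xyz)
  natoms <- ncol(xyz) %/% 3L
  icntrl <- integer(20)
  icntrl[1] <- nframes   # NSET
  icntrl[2] <- 1L        # ISTART
  icntrl[3] <- 1L        # NSAVC
  icntrl[4] <- nframes
  icntrl[20] <- 24L      # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "generated trajectory")
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natoms), con, size = 4), 4)
  xi <- seq(1, ncol(xyz), by = 3)
  for (f in seq_len(nframes)) {
    for (off in 0:2) {
      vals <- xyz[f, xi + off]
      rec(function() writeBin(as.numeric(vals), con, size = 4), 4 * natoms)
    }
  }
  invisible(path)
}

# ---- component maps ---------------------------------------------------------

#' Build or load a component map
#'
#' A component map assigns residue ranges (1-based, inclusive on both ends,
#' as domains are cited in the literature, e.g. HEAT repeats H1-H20) to named
#' components.  Ranges within one chain must not overlap, so every bead maps
#' to at most one component.
#'
#' @param entries data frame with columns `component_name`, `chain_id`,
#'   `residue_start`, `residue_end`.
#' @return a validated `component_map` (a data frame).
#' @export
component_map <- function(entries) {
  stopifnot(is.data.frame(entries))
  req <- c("component_name", "chain_id", "residue_start", "residue_end")
  miss <- setdiff(req, names(entries))
  if (length(miss) > 0)
    stop("component map lacks column(s): ", paste(miss, collapse = ", "))
  entries <- entries[, req, drop = FALSE]
  entries$component_name <- as.character(entries$component_name)
  entries$chain_id <- as.character(entries$chain_id)
  entries$residue_start <- as.integer(entries$residue_start)
  entries$residue_end <- as.integer(entries$residue_end)
  bad <- entries$residue_start > entries$residue_end
  if (any(bad))
    stop("validation error: residue_start > residue_end for component '",
         entries$component_name[which(bad)[1]], "'")
  for (ch in unique(entries$chain_id)) {
    e <- entries[entries$chain_id == ch, , drop = FALSE]
    if (nrow(e) < 2) next
    o <- order(e$residue_start)
    e <- e[o, , drop = FALSE]
    ov <- which(e$residue_start[-1] <= e$residue_end[-nrow(e)])
    if (length(ov) > 0)
      stop("validation error: overlapping ranges in chain ", ch, ": '",
           e$component_name[ov[1]], "' [", e$residue_start[ov[1]], "-",
           e$residue_end[ov[1]], "] and '", e$component_name[ov[1] + 1],
           "' [", e$residue_start[ov[1] + 1], "-", e$residue_end[ov[1] + 1], "]")
  }
  rownames(entries) <- NULL
  class(entries) <- c("component_map", "data.frame")
  entries
}

#' @rdname component_map
#' @param path TSV file with a header row naming the four columns.
#' @export
load_component_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  component_map(df)
}

#' Write a component map as TSV
#' @param map a [component_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_component_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- bead selection ---------------------------------------------------------

#' Select analysis beads: one per residue (CA / P)
#'
#' Amino-acid residues contribute their CA atom, nucleotides their P atom
#' (a 5'-terminal nucleotide has no phosphate and is skipped with a warning).
#' Non-polymer residues (water, ions, ligands) are skipped silently.  Bead
#' order follows atom-table order, so downstream matrices have a stable,
#' reproducible indexing.
#'
#' @param ensemble an [ensemble()].
#' @param map optional [component_map()]; beads outside every mapped range
#'   get the component label `"unassigned"`.
#' @return a `bead_selection` data frame with columns `atom_index`,
#'   `atom_name`, `chain_id`, `residue_number`, `residue_name`, `component`,
#'   `mass`.
#' @export
select_beads <- function(ensemble, map = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  resname <- toupper(at$residue_name)
  is_aa <- resname %in% .amino_residues
  is_nt <- resname %in% .nucleotide_residues
  want <- (is_aa & toupper(at$atom_name) == "CA") |
          (is_nt & toupper(at$atom_name) == "P")
  idx <- which(want)
  # warn about polymer residues that lack their bead atom
  res_key <- paste(at$chain_id, at$residue_number)
  poly_res <- unique(res_key[is_aa | is_nt])
  bead_res <- res_key[idx]
  missing_res <- setdiff(poly_res, bead_res)
  if (length(missing_res) > 0)
    warning("skipping ", length(missing_res),
            " residue(s) lacking a bead atom: ",
            paste(utils::head(missing_res, 5), collapse = ", "),
            if (length(missing_res) > 5) ", ..." else "")
  if (length(idx) == 0)
    stop("empty-selection error: no CA or P bead atoms found")
  idx <- sort(idx)
  beads <- data.frame(
    atom_index = idx,
    atom_name = at$atom_name[idx],
    chain_id = at$chain_id[idx],
    residue_number = at$residue_number[idx],
    residue_name = at$residue_name[idx],
    component = "unassigned",
    mass = at$mass[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(map)) {
    map <- if (inherits(map, "component_map")) map else component_map(map)
    for (k in seq_len(nrow(map))) {
      hit <- beads$chain_id == map$chain_id[k] &
        beads$residue_number >= map$residue_start[k] &
        beads$residue_number <= map$residue_end[k]
      beads$component[hit] <- map$component_name[k]
    }
  }
  rownames(beads) <- NULL
  class(beads) <- c("bead_selection", "data.frame")
  beads
}

# bead coordinates of selected frames as (frames x 3*nbeads)
bead_xyz <- function(ensemble, beads, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  ensemble$xyz[frames, xyz_cols(beads$atom_index), drop = FALSE]
}
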