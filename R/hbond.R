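#' Geometric hydrogen-bond criterion
#'
#' A frame counts as hydrogen-bonded for a donor-acceptor pair when the
#' donor-acceptor heavy-atom distance is at most `max_heavy_distance` and
#' the best donor-H...acceptor angle over the donor's hydrogens is at least
#' `angle_threshold`.  The angle is a linearity threshold (convention
#' `"DHA_min"`): a perfectly linear bond has a 180 degree D-H...A angle, so
#' angles *above* the threshold are accepted.  Defaults follow the common
#' trajectory-analysis criterion of 3.3 Angstrom and 145 degrees.
#'
#' @param max_heavy_distance donor-acceptor heavy-atom cutoff, Angstrom.
#' @param angle_threshold minimum D-H...A angle, degrees.
#' @param angle_convention only `"DHA_min"` is implemented.
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_heavy_distance = 3.3, angle_threshold = 145,
                            angle_convention = "DHA_min") {
  stopifnot(max_heavy_distance > 0,
            angle_threshold > 0, angle_threshold <= 180)
  angle_convention <- match.arg(angle_convention, "DHA_min")
  structure(list(max_heavy_distance = max_heavy_distance,
                 angle_threshold = angle_threshold,
                 angle_convention = angle_convention),
            class = "hbond_criterion")
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Donors are N/O heavy atoms with at least one bonded hydrogen; with no
#' connectivity available, a hydrogen (element H) within 1.2 Angstrom of the
#' heavy atom in the reference frame is taken as bonded.  Acceptors are all
#' N/O heavy atoms.
#'
#' @param ensemble an [ensemble()]; the first frame provides the reference
#'   geometry for hydrogen attachment.
#' @return list with `donors` (atom indices), `donor_hydrogens` (list of
#'   hydrogen atom indices per donor) and `acceptors` (atom indices).
#' @export
assign_donors_acceptors <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  elem <- toupper(at$element)
  h_idx <- which(elem == "H")
  no_idx <- which(elem %in% c("N", "O"))
  if (length(no_idx) == 0) stop("no N/O atoms: nothing can donate or accept")
  if (length(h_idx) == 0)
    stop("structure carries no hydrogens; use hbond_occupancy(mode = ",
         "\"distance_only\") for heavy-atom-only detection")
  ref <- frame_coords(ensemble, 1)
  donors <- integer(0)
  donor_h <- list()
  for (d in no_idx) {
    dd <- sqrt(rowSums(sweep(ref[h_idx, , drop = FALSE], 2, ref[d, ])^2))
    hh <- h_idx[dd <= 1.2]
    if (length(hh) > 0) {
      donors <- c(donors, d)
      donor_h[[length(donor_h) + 1L]] <- hh
    }
  }
  list(donors = donors, donor_hydrogens = donor_h, acceptors = no_idx)
}

#' Hydrogen-bond occupancy over an analysis window
#'
#' For every donor-acceptor pair, the fraction of window frames satisfying
#' the geometric criterion.  Pair identity is keyed by the donor heavy atom
#' and the acceptor (not by the hydrogen); the angle test takes the best
#' angle over the donor's hydrogens.  `mode = "distance_only"` drops the
#' angle test and lets every N/O heavy atom donate (usable for structures
#' without hydrogens, and for salt-bridge-like contacts).
#'
#' @param ensemble an [ensemble()].
#' @param criterion an [hbond_criterion()].
#' @param window frame indices (1-based) or `NULL` for all frames.
#' @param mode `"full"` (distance + angle) or `"distance_only"`.
#' @param map,pair_filter optional: a [component_map()] plus a length-2
#'   character vector of component names; only pairs with the donor in one
#'   named component and the acceptor in the other (either direction) are
#'   reported.
#' @return data frame of class `hbond_occupancy` with one row per pair
#'   observed in at least one frame: donor/acceptor chain, residue, atom,
#'   `occupancy`, `n_frames`.
#' @export
hbond_occupancy <- function(ensemble, criterion = hbond_criterion(),
                            window = NULL, mode = c("full", "distance_only"),
                            map = NULL, pair_filter = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  mode <- match.arg(mode)
  if (is.null(window)) window <- seq_len(n_frames(ensemble))
  window <- as.integer(window)
  if (length(window) == 0) stop("empty analysis window")
  at <- ensemble$atoms
  if (mode == "full") {
    da <- assign_donors_acceptors(ensemble)
  } else {
    no_idx <- which(toupper(at$element) %in% c("N", "O"))
    da <- list(donors = no_idx,
               donor_hydrogens = rep(list(integer(0)), length(no_idx)),
               acceptors = no_idx)
  }
  if (length(da$donors) == 0 || length(da$acceptors) == 0)
    stop("empty donor or acceptor set")
  comp_of <- NULL
  if (!is.null(pair_filter)) {
    if (is.null(map)) stop("pair_filter requires a component map")
    stopifnot(length(pair_filter) == 2)
    map <- if (inherits(map, "component_map")) map else component_map(map)
    comp_of <- rep("unassigned", nrow(at))
    for (k in seq_len(nrow(map))) {
      hit <- at$chain_id == map$chain_id[k] &
        at$residue_number >= map$residue_start[k] &
        at$residue_number <= map$residue_end[k]
      comp_of[hit] <- map$component_name[k]
    }
  }
  xyz <- ensemble$xyz[window, , drop = FALSE]
  col3 <- function(i) xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  nW <- length(window)
  rows <- list()
  for (di in seq_along(da$donors)) {
    d <- da$donors[di]
    D <- col3(d)
    for (a in da$acceptors) {
      if (a == d) next
      if (!is.null(comp_of)) {
        pc <- c(comp_of[d], comp_of[a])
        if (!(setequal(pc, pair_filter) ||
              (pair_filter[1] == pair_filter[2] &&
               all(pc == pair_filter[1])))) next
      }
      A <- col3(a)
      dv <- A - D
      ok <- sqrt(rowSums(dv^2)) <= criterion$max_heavy_distance
      if (mode == "full" && any(ok)) {
        best <- rep(-Inf, nW)
        for (h in da$donor_hydrogens[[di]]) {
          H <- col3(h)
          v1 <- D - H
          v2 <- A - H
          cosang <- rowSums(v1 * v2) /
            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          best <- pmax(best, ang)
        }
        ok <- ok & (best >= criterion$angle_threshold)
      }
      cnt <- sum(ok)
      if (cnt > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          donor_chain = at$chain_id[d], donor_res = at$residue_number[d],
          donor_atom = at$atom_name[d],
          acceptor_chain = at$chain_id[a], acceptor_res = at$residue_number[a],
          acceptor_atom = at$atom_name[a],
          occupancy = cnt / nW, n_frames = nW,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(rows) == 0) {
    data.frame(donor_chain = character(), donor_res = integer(),
               donor_atom = character(), acceptor_chain = character(),
               acceptor_res = integer(), acceptor_atom = character(),
               occupancy = numeric(), n_frames = integer(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("hbond_occupancy", "data.frame")
  res
}

#' Compare hydrogen-bond occupancy tables across models
#'
#' Takes the union of donor-acceptor pairs over all tables (a pair missing
#' from a table has occupancy 0) and reports the pairs whose occupancy range
#' (max - min across models) reaches `min_delta`, sorted by range
#' descending.
#'
#' @param tables named list of [hbond_occupancy()] tables; names are model
#'   labels and must be unique.
#' @param min_delta minimum occupancy range to report.
#' @return data frame with the pair identity columns, one occupancy column
#'   per model label, and `delta`.
#' @export
compare_occupancies <- function(tables, min_delta = 0.1) {
  stopifnot(is.list(tables), length(tables) >= 2)
  labels <- names(tables)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels))
    stop("tables must carry unique, non-empty model labels")
  keycols <- c("donor_chain", "donor_res", "donor_atom",
               "acceptor_chain", "acceptor_res", "acceptor_atom")
  keyed <- lapply(tables, function(tb) {
    k <- do.call(paste, c(tb[keycols], sep = "|"))
    setNames(tb$occupancy, k)
  })
  all_keys <- sort(unique(unlist(lapply(keyed, names))))
  if (length(all_keys) == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(keycols) + length(labels) + 1))
    names(out) <- c(keycols, labels, "delta")
    return(out)
  }
  occ <- sapply(keyed, function(v) {
    x <- v[all_keys]
    x[is.na(x)] <- 0
    unname(x)
  })
  occ <- matrix(occ, nrow = length(all_keys),
                dimnames = list(NULL, labels))
  delta <- apply(occ, 1, max) - apply(occ, 1, min)
  keep <- delta >= min_delta
  parts <- do.call(rbind, strsplit(all_keys[keep], "|", fixed = TRUE))
  out <- if (sum(keep) == 0) {
    data.frame(matrix(nrow = 0, ncol = length(keycols)))
  } else {
    data.frame(parts, stringsAsFactors = FALSE)
  }
  names(out) <- keycols
  if (sum(keep) > 0) {
    out$donor_res <- as.integer(out$donor_res)
    out$acceptor_res <- as.integer(out$acceptor_res)
  }
  for (l in labels) out[[l]] <- occ[keep, l]
  out$delta <- delta[keep]
  out <- out[order(-out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}
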