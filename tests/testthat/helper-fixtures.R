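# Fixtures are built in code at test time; nothing binary is stored.

# a tiny protein-like atom table: `nres` residues with N/CA/C/O backbone
backbone_atoms <- function(nres, chain = "A") {
  do.call(rbind, lapply(seq_len(nres), function(r) {
    data.frame(
      atom_name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      residue_number = r, residue_name = "ALA", chain_id = chain,
      stringsAsFactors = FALSE
    )
  }))
}

# deterministic non-degenerate coordinates for n atoms (single frame vector)
spread_coords <- function(n, seed = 7) {
  set.seed(seed)
  as.vector(t(cbind(3.8 * seq_len(n), rnorm(n), rnorm(n))))
}

# write a well-formed (multi-model) PDB file and return its path
write_pdb_fixture <- function(atoms, xyz, path = tempfile(fileext = ".pdb")) {
  ens <- ensemble(atoms, xyz)
  write_trajectory(ens, path, "multi_model_pdb")
  path
}

# apply one rigid motion (rotation about z by `deg`, then translation) to a
# frame vector
rigid_move <- function(v, deg, shift = c(0, 0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  P <- matrix(v, ncol = 3, byrow = TRUE) %*% R
  as.vector(t(sweep(P, 2, shift, `+`)))
}

# random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply independent random rigid motions to every frame of an ensemble
randomly_rigid_move <- function(ens, seed = 99) {
  set.seed(seed)
  out <- ens$xyz
  for (f in seq_len(nrow(out))) {
    R <- random_rotation()
    t3 <- rnorm(3, sd = 10)
    P <- matrix(out[f, ], ncol = 3, byrow = TRUE) %*% R
    out[f, ] <- as.vector(t(sweep(P, 2, t3, `+`)))
  }
  ens$xyz <- out
  ens
}

# simple two-component map over one chain
two_block_map <- function(n1, n2, chain = "A", names = c("A", "B")) {
  component_map(data.frame(
    component_name = names, chain_id = chain,
    residue_start = c(1L, n1 + 1L), residue_end = c(n1, n1 + n2),
    stringsAsFactors = FALSE
  ))
}

# brute-force H-bond checker: exhaustive over pairs, hydrogens and frames
brute_force_hbonds <- function(ens, criterion, window = NULL,
                               mode = "full") {
  if (is.null(window)) window <- seq_len(n_frames(ens))
  at <- ens$atoms
  elem <- toupper(at$element)
  no_idx <- which(elem %in% c("N", "O"))
  h_idx <- which(elem == "H")
  ref <- frame_coords(ens, 1)
  res <- list()
  for (d in no_idx) {
    hs <- if (mode == "full") {
      h_idx[vapply(h_idx, function(h) sqrt(sum((ref[h, ] - ref[d, ])^2)) <= 1.2,
                   logical(1))]
    } else integer(0)
    if (mode == "full" && length(hs) == 0) next
    for (a in no_idx) {
      if (a == d) next
      cnt <- 0L
      for (f in window) {
        P <- frame_coords(ens, f)
        if (sqrt(sum((P[d, ] - P[a, ])^2)) > criterion$max_heavy_distance) next
        if (mode == "full") {
          angs <- vapply(hs, function(h) {
            v1 <- P[d, ] - P[h, ]
            v2 <- P[a, ] - P[h, ]
            acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) *
              180 / pi
          }, numeric(1))
          if (max(angs) < criterion$angle_threshold) next
        }
        cnt <- cnt + 1L
      }
      if (cnt > 0)
        res[[length(res) + 1L]] <- data.frame(
          donor = d, acceptor = a, occupancy = cnt / length(window))
    }
  }
  if (length(res) == 0) return(data.frame(donor = integer(),
                                          acceptor = integer(),
                                          occupancy = numeric()))
  do.call(rbind, res)
}
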