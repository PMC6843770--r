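#' Mass-weighted positional covariance matrix
#'
#' The 3N x 3N covariance of bead displacements about the window mean,
#' entries `sqrt(m_i m_j) * <dr_ia dr_jb>` in amu A^2, with the population
#' (1/n) normalization.  The input must already be superposed (global
#' rotation/translation removed), matching the convention of building the
#' covariance from position vectors after an RMS fit to a reference.
#'
#' @param superposed a `superposed_ensemble`.
#' @param beads a [select_beads()] selection.
#' @param window frame indices (1-based) or `NULL` for all; >= 2 frames.
#' @param mass_weighted logical; `FALSE` drops the `sqrt(m_i m_j)` factor.
#' @return object of class `covariance_matrix`: list with elements `matrix`,
#'   `beads`, `window`, `mass_weighted`.
#' @export
covariance <- function(superposed, beads, window = NULL, mass_weighted = TRUE) {
  if (!inherits(superposed, "superposed_ensemble"))
    stop("superpose() the ensemble first (covariance requires a fitted ensemble)")
  if (is.null(window)) window <- seq_len(n_frames(superposed))
  window <- as.integer(window)
  if (length(window) < 2) stop("covariance needs a window of >= 2 frames")
  B <- bead_xyz(superposed, beads, window)
  D <- sweep(B, 2, colMeans(B))
  C <- crossprod(D) / length(window)
  if (mass_weighted) {
    sm <- rep(sqrt(beads$mass), each = 3)
    C <- C * tcrossprod(sm)
  }
  structure(list(matrix = C, beads = beads, window = window,
                 mass_weighted = mass_weighted),
            class = "covariance_matrix")
}

#' Pearson cross-correlation matrix (DCCM)
#'
#' `CC_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, computed from the
#' traces of the 3x3 inter-bead covariance blocks (the standard dynamical
#' cross-correlation convention, for which `CC_ii = 1` exactly).  Mass
#' weighting cancels in the ratio, so CCij is independent of bead masses.
#'
#' A bead with zero positional variance has no defined correlation.  The
#' default errors, naming the immobile bead; `zero_policy = "zero"` instead
#' assigns zero correlation between an immobile bead and every other bead
#' (the limit of vanishing independent jitter) with a warning, which lets
#' hinge pivots flow through the switch-region pipeline.
#'
#' @param cov a [covariance()] result.
#' @param zero_policy `"error"` (default) or `"zero"`.
#' @param tol relative variance threshold below which a bead counts as
#'   immobile.
#' @return object of class `cross_correlation_matrix`: list with `cc`
#'   (N x N matrix) and `beads`.
#' @export
cross_correlation <- function(cov, zero_policy = c("error", "zero"),
                              tol = 1e-12) {
  stopifnot(inherits(cov, "covariance_matrix"))
  zero_policy <- match.arg(zero_policy)
  C <- cov$matrix
  n <- nrow(cov$beads)
  xi <- seq(1, 3 * n, 3)
  Tm <- C[xi, xi] + C[xi + 1, xi + 1] + C[xi + 2, xi + 2]
  if (cov$mass_weighted) {
    sm <- sqrt(cov$beads$mass)
    Tm <- Tm / tcrossprod(sm)
  }
  v <- diag(Tm)
  immobile <- v <= tol * max(v, 0)
  if (any(immobile)) {
    who <- paste0(cov$beads$chain_id[immobile], "/",
                  cov$beads$residue_number[immobile])
    if (zero_policy == "error")
      stop("zero-variance bead(s): ", paste(who, collapse = ", "),
           " (immobile over the window); use zero_policy = \"zero\" to assign",
           " them zero correlation")
    warning("assigning zero correlation to immobile bead(s): ",
            paste(who, collapse = ", "))
    v[immobile] <- 1  # placeholder; rows/cols overwritten below
  }
  cc <- Tm / sqrt(tcrossprod(v))
  if (any(immobile)) {
    cc[immobile, ] <- 0
    cc[, immobile] <- 0
  }
  diag(cc) <- 1
  structure(list(cc = cc, beads = cov$beads), class = "cross_correlation_matrix")
}

#' Component-pair correlation scores
#'
#' The correlation score of a component pair is the sum of CCij over all
#' bead pairs of the two components divided by the product of their bead
#' counts, i.e. the block mean of the cross-correlation matrix -- a
#' correlation density.  No cutoff is applied to the CCij entering the sum.
#' Diagonal blocks include the `i = j` self terms (`CC_ii = 1`), which
#' inflates small components' self scores; see the methods vignette.
#' Unassigned beads are excluded.
#'
#' @param ccm a [cross_correlation()] result whose beads carry component
#'   labels (from [select_beads()] with a map).
#' @param map optional [component_map()] to (re-)assign components; by
#'   default the labels already on the bead selection are used.
#' @return object of class `correlation_score_matrix`: list with `cs`
#'   (K x K matrix, component names on dimnames) and `sizes`.
#' @export
correlation_scores <- function(ccm, map = NULL) {
  stopifnot(inherits(ccm, "cross_correlation_matrix"))
  beads <- ccm$beads
  if (!is.null(map)) {
    map <- if (inherits(map, "component_map")) map else component_map(map)
    beads$component <- "unassigned"
    for (k in seq_len(nrow(map))) {
      hit <- beads$chain_id == map$chain_id[k] &
        beads$residue_number >= map$residue_start[k] &
        beads$residue_number <= map$residue_end[k]
      beads$component[hit] <- map$component_name[k]
    }
    comp_order <- unique(map$component_name)
  } else {
    comp_order <- unique(beads$component[beads$component != "unassigned"])
  }
  idx <- lapply(comp_order, function(k) which(beads$component == k))
  names(idx) <- comp_order
  empty <- lengths(idx) == 0
  if (any(empty)) {
    warning("dropping component(s) with zero beads: ",
            paste(comp_order[empty], collapse = ", "))
    idx <- idx[!empty]
  }
  K <- length(idx)
  if (K < 1) stop("no named component contains any bead")
  cs <- matrix(NA_real_, K, K, dimnames = list(names(idx), names(idx)))
  for (a in seq_len(K)) for (b in a:K) {
    m <- mean(ccm$cc[idx[[a]], idx[[b]], drop = FALSE])
    cs[a, b] <- m
    cs[b, a] <- m
  }
  structure(list(cs = cs, sizes = lengths(idx)),
            class = "correlation_score_matrix")
}

#' Clip a correlation-score matrix for display
#'
#' Rendering convenience only: stored scores are never clipped.
#'
#' @param csm a [correlation_scores()] result.
#' @param limits display range, default `c(-0.6, 0.6)`.
#' @return the clipped K x K matrix.
#' @export
clip_scores <- function(csm, limits = c(-0.6, 0.6)) {
  stopifnot(inherits(csm, "correlation_score_matrix"))
  pmin(pmax(csm$cs, limits[1]), limits[2])
}

#' Detect switch regions (correlation sign flips at low-mobility pivots)
#'
#' A switch region is a contiguous run of beads where the cross-correlation
#' against a probe component changes sign sharply while the first principal
#' component assigns the beads little displacement -- the pivot of a
#' spring-pulling / accordion-like motion.  The procedure, per chain:
#'
#' 1. profile `s_i` = mean CCij of bead i against the probe component;
#' 2. candidate boundaries where `s` changes sign and the flanking 5-bead
#'    means differ by at least `min_flip`;
#' 3. per-bead PC1 amplitude `a_i` = norm of the bead's 3-vector in the
#'    first eigenvector;
#' 4. the region is the maximal run of beads around the boundary with `a_i`
#'    at or below the `amplitude_percentile` of all amplitudes.
#'
#' @param ccm a [cross_correlation()] result.
#' @param pca a [pca_modes()] result computed from the same beads/window.
#' @param probe_block component name the correlation profile is taken
#'   against.
#' @param amplitude_percentile percentile (0-100) of PC1 amplitudes below
#'   which beads count as near-immobile (default 20).
#' @param min_flip minimum absolute difference between flanking 5-bead mean
#'   correlations (default 0.2).
#' @return data frame of class `switch_regions` with columns `chain_id`,
#'   `residue_start`, `residue_end`, `flank_left`, `flank_right`, `flip`,
#'   `amplitude_pct`, sorted by flip magnitude (descending).  Zero rows when
#'   no candidate boundary exists.
#' @export
detect_switch_regions <- function(ccm, pca, probe_block,
                                  amplitude_percentile = 20, min_flip = 0.2) {
  stopifnot(inherits(ccm, "cross_correlation_matrix"),
            inherits(pca, "pca_modes"))
  beads <- ccm$beads
  if (nrow(pca$beads) != nrow(beads))
    stop("ccm and pca were computed on different bead selections")
  probe <- which(beads$component == probe_block)
  if (length(probe) == 0) stop("unknown probe_block: ", probe_block)
  v1 <- pca$vectors[, 1]
  amp <- sqrt(v1[seq(1, length(v1), 3)]^2 + v1[seq(2, length(v1), 3)]^2 +
                v1[seq(3, length(v1), 3)]^2)
  thr <- quantile(amp, amplitude_percentile / 100, names = FALSE)
  s_all <- rowMeans(ccm$cc[, probe, drop = FALSE])
  out <- list()
  for (ch in unique(beads$chain_id)) {
    pos <- which(beads$chain_id == ch)
    if (length(pos) < 3) next
    s <- s_all[pos]
    a <- amp[pos]
    n <- length(pos)
    nz <- which(abs(s) > 1e-12)
    if (length(nz) < 2) next
    sg <- sign(s[nz])
    for (k in which(sg[-1] != sg[-length(sg)])) {
      bl <- nz[k]          # last bead of the earlier sign
      br <- nz[k + 1]      # first bead of the later sign
      left <- mean(s[max(1, bl - 4):bl])
      right <- mean(s[br:min(n, br + 4)])
      flip <- abs(left - right)
      if (flip < min_flip) next
      anchor <- (bl:br)[which.min(a[bl:br])]
      if (a[anchor] > thr) next
      lo <- anchor
      while (lo > 1 && a[lo - 1] <= thr) lo <- lo - 1
      hi <- anchor
      while (hi < n && a[hi + 1] <= thr) hi <- hi + 1
      out[[length(out) + 1L]] <- data.frame(
        chain_id = ch,
        residue_start = beads$residue_number[pos[lo]],
        residue_end = beads$residue_number[pos[hi]],
        flank_left = if (lo > 1) beads$component[pos[lo - 1]] else "",
        flank_right = if (hi < n) beads$component[pos[hi + 1]] else "",
        flip = flip,
        amplitude_pct = 100 * mean(amp <= max(a[lo:hi])),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    res <- empty_switch_regions()
  } else {
    res <- do.call(rbind, out)
    key <- paste(res$chain_id, res$residue_start, res$residue_end)
    res <- do.call(rbind, lapply(split(res, key), function(g)
      g[which.max(g$flip), , drop = FALSE]))
    res <- res[order(-res$flip), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("switch_regions", "data.frame")
  res
}

empty_switch_regions <- function() {
  res <- data.frame(chain_id = character(), residue_start = integer(),
                    residue_end = integer(), flank_left = character(),
                    flank_right = character(), flip = numeric(),
                    amplitude_pct = numeric(), stringsAsFactors = FALSE)
  class(res) <- c("switch_regions", "data.frame")
  res
}
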