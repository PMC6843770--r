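#' Resolve a window specification to a frame range
#'
#' Window specifications are `"all"`, `"last P%"` (later part of the
#' trajectory, ceil split: the window starts at frame
#' `n - floor(n * P / 100)`), or an explicit 0-based half-open integer range
#' `c(start, end)`.
#'
#' @param spec window specification.
#' @param n_frames total number of frames.
#' @return integer `c(start, end)`, 0-based half-open.
#' @export
window_resolve <- function(spec, n_frames) {
  stopifnot(n_frames >= 1)
  if (is.character(spec)) {
    spec <- trimws(spec)
    if (identical(spec, "all")) {
      rng <- c(0L, as.integer(n_frames))
    } else if (grepl("^last\\s+[0-9.]+%$", spec)) {
      p <- as.numeric(sub("^last\\s+([0-9.]+)%$", "\\1", spec))
      if (p <= 0 || p > 100) stop("window percentage must lie in (0, 100]")
      start <- n_frames - floor(n_frames * p / 100)
      rng <- c(as.integer(start), as.integer(n_frames))
    } else {
      stop("unrecognized window spec: '", spec, "'")
    }
  } else if (is.numeric(spec) && length(spec) == 2) {
    rng <- as.integer(spec)
    if (rng[1] < 0 || rng[2] > n_frames)
      stop("window [", rng[1], ", ", rng[2], ") outside 0..", n_frames)
  } else {
    stop("window spec must be \"all\", \"last P%\", or c(start, end)")
  }
  if (rng[2] <= rng[1])
    stop("empty window: [", rng[1], ", ", rng[2], ")")
  rng
}

# 1-based frame indices of a resolved window
window_frames <- function(spec, n_frames) {
  rng <- window_resolve(spec, n_frames)
  (rng[1] + 1L):rng[2]
}

#' Inter-residue distance in an ensemble
#'
#' Distance between one atom of each of two residues, per frame.  Used e.g.
#' to measure the separation between the branch-point adenosine and the
#' 5'-splice-site scissile phosphate in a spliceosome structure.
#'
#' @param ensemble an [ensemble()].
#' @param sel1,sel2 lists `list(chain, residue, atom = NULL)`; with
#'   `atom = NULL` the residue's bead atom (CA or P) is used, falling back
#'   to the residue's first atom.
#' @param frames frame indices, default all.
#' @return numeric vector of distances (Angstrom), one per frame.
#' @export
residue_distance <- function(ensemble, sel1, sel2, frames = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  find_atom <- function(sel) {
    at <- ensemble$atoms
    in_res <- which(at$chain_id == sel$chain & at$residue_number == sel$residue)
    if (length(in_res) == 0)
      stop("no atoms for chain ", sel$chain, " residue ", sel$residue)
    if (!is.null(sel$atom)) {
      i <- in_res[toupper(at$atom_name[in_res]) == toupper(sel$atom)]
      if (length(i) == 0)
        stop("atom ", sel$atom, " not found in chain ", sel$chain,
             " residue ", sel$residue)
      return(i[1])
    }
    bead <- in_res[toupper(at$atom_name[in_res]) %in% c("CA", "P")]
    if (length(bead) > 0) bead[1] else in_res[1]
  }
  i <- find_atom(sel1)
  j <- find_atom(sel2)
  dv <- ensemble$xyz[frames, (3 * i - 2):(3 * i), drop = FALSE] -
    ensemble$xyz[frames, (3 * j - 2):(3 * j), drop = FALSE]
  sqrt(rowSums(dv^2))
}

#' Run the full comparison workflow over labelled models
#'
#' Executes the analysis pipeline -- bead selection, window resolution,
#' superposition, fluctuation profiling, covariance, cross-correlation,
#' correlation scores, PCA, switch-region detection and (when the structures
#' carry N/O atoms) hydrogen-bond occupancy -- for every model of a
#' manifest, writes per-model CSV/TSV/NMD artifacts plus difference
#' matrices against a designated reference model, and returns the collected
#' report.  Identical manifest and seed give byte-identical outputs.
#'
#' @param manifest a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{models}{list of `list(label, topology, trajectory = NULL,
#'       format = NULL)`; alternatively a pre-built [ensemble()] under
#'       `ensemble` for in-memory use.  Labels must be unique.}
#'     \item{component_map}{path to a TSV map or a data frame.}
#'     \item{window}{window spec (see [window_resolve()]); default
#'       `"last 50%"`.}
#'     \item{reference_model}{label anchoring difference matrices; default
#'       the first model.}
#'     \item{probe_block}{component for [detect_switch_regions()]; default
#'       the component with most beads.}
#'     \item{assume_superposed}{logical: mark frames as already in a common
#'       frame ([as_superposed()]) instead of Kabsch-fitting; default FALSE.}
#'     \item{fit_weights}{`"uniform"` (default) or `"mass"`.}
#'     \item{n_modes}{eigenvectors to keep (default 10).}
#'     \item{criteria}{optional overrides: `hbond_distance`, `hbond_angle`,
#'       `switch_percentile`, `switch_min_flip`, `min_delta`.}
#'     \item{output_dir}{where artifacts are written.}
#'     \item{seed}{integer recorded in provenance and used for any
#'       resampling (the pipeline itself is deterministic).}
#'   }
#' @param output_dir overrides the manifest's output directory.
#' @return a list of class `comparison_report` (per-model results,
#'   difference matrices, H-bond delta table, provenance), invisibly.
#' @export
run_manifest <- function(manifest, output_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest_path <- manifest
    manifest <- yaml::read_yaml(manifest)
  } else manifest_path <- NULL
  m <- manifest
  if (is.null(m$models) || length(m$models) == 0)
    stop("manifest has no models")
  labels <- vapply(m$models, function(x) as.character(x$label %||% ""),
                   character(1))
  if (any(labels == "")) stop("every model needs a label")
  if (anyDuplicated(labels))
    stop("validation error: duplicate model labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out_dir <- output_dir %||% m$output_dir %||% stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  window_spec <- m$window %||% "last 50%"
  n_modes <- m$n_modes %||% 10L
  fit_weights <- m$fit_weights %||% "uniform"
  crit <- m$criteria %||% list()
  hb_crit <- hbond_criterion(
    max_heavy_distance = crit$hbond_distance %||% 3.3,
    angle_threshold = crit$hbond_angle %||% 145)
  sw_pct <- crit$switch_percentile %||% 20
  sw_flip <- crit$switch_min_flip %||% 0.2
  min_delta <- crit$min_delta %||% 0.1
  seed <- as.integer(m$seed %||% 0L)
  cmap <- m$component_map
  if (is.character(cmap)) cmap <- load_component_map(cmap)
  else if (!is.null(cmap) && !inherits(cmap, "component_map"))
    cmap <- component_map(as.data.frame(cmap))

  stage <- function(label, name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage '", name, "' for model '", label,
                        "': ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed for model '", label, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  wnum <- function(df, path) write.csv(df, path, row.names = FALSE)

  results <- list()
  hb_tables <- list()
  checksums <- character(0)
  for (mi in seq_along(m$models)) {
    mm <- m$models[[mi]]
    lab <- mm$label
    mdir <- file.path(out_dir, lab)
    dir.create(mdir, showWarnings = FALSE)
    message("model '", lab, "': loading")
    ens <- stage(lab, "load", {
      if (!is.null(mm$ensemble)) mm$ensemble
      else if (!is.null(mm$trajectory))
        read_trajectory(mm$topology, mm$trajectory,
                        format = mm$format %||% c("dcd", "multi_model_pdb"))
      else read_structure(mm$topology)
    })
    for (p in c(mm$topology, mm$trajectory))
      if (!is.null(p)) checksums[p] <- unname(tools::md5sum(p))
    beads <- stage(lab, "select_beads", select_beads(ens, cmap))
    frames <- stage(lab, "window",
                    window_frames(mm$window %||% window_spec, n_frames(ens)))
    sup <- stage(lab, "superpose", {
      if (isTRUE(m$assume_superposed)) as_superposed(ens, frames[1])
      else superpose(ens, beads, reference_index = frames[1],
                     weights = fit_weights)
    })
    fl <- stage(lab, "fluctuations", fluctuation_profile(sup, beads, frames))
    cv <- stage(lab, "covariance", covariance(sup, beads, frames))
    ccm <- stage(lab, "cross_correlation",
                 suppressWarnings(cross_correlation(cv, zero_policy = "zero")))
    csm <- stage(lab, "correlation_scores", correlation_scores(ccm))
    pca <- stage(lab, "pca",
                 pca_modes(cv, n_modes = min(n_modes, 3L * nrow(beads))))
    named <- beads$component[beads$component != "unassigned"]
    probe <- m$probe_block %||%
      if (length(named) > 0) names(which.max(table(named))) else NULL
    sw <- if (is.null(probe)) {
      empty_switch_regions()
    } else {
      stage(lab, "switch_regions",
            detect_switch_regions(ccm, pca, probe_block = probe,
                                  amplitude_percentile = sw_pct,
                                  min_flip = sw_flip))
    }
    has_h <- any(toupper(ens$atoms$element) == "H") &&
      any(toupper(ens$atoms$element) %in% c("N", "O"))
    hb <- if (has_h) {
      stage(lab, "hbonds", hbond_occupancy(ens, hb_crit, window = frames))
    } else {
      hbond_occupancy_empty()
    }
    hb_tables[[lab]] <- hb

    wnum(fl$rmsf, file.path(mdir, "rmsf.csv"))
    wnum(fl$per_frame, file.path(mdir, "rmsd_rg.csv"))
    wnum(fl$component_rmsf, file.path(mdir, "component_rmsf.csv"))
    wnum(mat_df(ccm$cc, bead_ids(beads)), file.path(mdir, "cc.csv"))
    wnum(mat_df(csm$cs, rownames(csm$cs)), file.path(mdir, "cs.csv"))
    wnum(data.frame(mode = seq_along(pca$values), eigenvalue = pca$values,
                    cumulative_variance = pca$cumulative_variance),
         file.path(mdir, "eigenvalues.csv"))
    utils::write.table(as.data.frame(sw), file.path(mdir, "switch_regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_nmd(pca, matrix(colMeans(bead_xyz(sup, beads, frames)),
                          ncol = 3, byrow = TRUE),
              file.path(mdir, "modes.nmd"),
              modes = seq_len(min(3L, ncol(pca$vectors))))
    wnum(hb, file.path(mdir, "hbond_occupancy.csv"))

    results[[lab]] <- list(beads = beads, fluct = fl, cs = csm, cc = ccm,
                           pca = pca, switch_regions = sw, hbonds = hb,
                           window = frames)
  }

  ref_lab <- m$reference_model %||% labels[1]
  if (!ref_lab %in% labels) stop("unknown reference model: ", ref_lab)
  cs_ref <- results[[ref_lab]]$cs$cs
  cs_diff <- list()
  for (lab in setdiff(labels, ref_lab)) {
    dmat <- results[[lab]]$cs$cs - cs_ref
    cs_diff[[lab]] <- dmat
    wnum(mat_df(dmat, rownames(dmat)),
         file.path(out_dir, paste0("cs_diff_", lab, "_vs_", ref_lab, ".csv")))
  }
  hb_delta <- if (length(hb_tables) >= 2)
    compare_occupancies(hb_tables, min_delta = min_delta)
  else hbond_occupancy_empty()
  wnum(hb_delta, file.path(out_dir, "hbond_delta.csv"))

  config_hash <- if (!is.null(manifest_path)) {
    unname(tools::md5sum(manifest_path))
  } else {
    tf <- tempfile(fileext = ".yaml")
    yaml::write_yaml(manifest_stub(m), tf)
    h <- unname(tools::md5sum(tf))
    unlink(tf)
    h
  }
  provenance <- list(
    package = "ensdyn",
    version = as.character(packageVersion("ensdyn")),
    config_hash = config_hash,
    input_md5 = as.list(checksums),
    seed = seed,
    reference_model = ref_lab,
    window = window_spec
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- structure(list(models = results, cs_diff = cs_diff,
                           hbond_delta = hb_delta, provenance = provenance,
                           output_dir = out_dir),
                      class = "comparison_report")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bead_ids <- function(beads)
  paste0(beads$chain_id, beads$residue_number)

mat_df <- function(mat, ids) {
  df <- as.data.frame(mat)
  names(df) <- ids
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), df)
}

hbond_occupancy_empty <- function() {
  res <- data.frame(donor_chain = character(), donor_res = integer(),
                    donor_atom = character(), acceptor_chain = character(),
                    acceptor_res = integer(), acceptor_atom = character(),
                    occupancy = numeric(), n_frames = integer(),
                    stringsAsFactors = FALSE)
  class(res) <- c("hbond_occupancy", "data.frame")
  res
}

# serializable subset of a manifest used for hashing in-memory configs;
# the output location is not part of the configuration identity
manifest_stub <- function(m) {
  m$output_dir <- NULL
  m$models <- lapply(m$models, function(x) {
    x$ensemble <- if (!is.null(x$ensemble))
      paste0("<in-memory:", n_atoms(x$ensemble), "x", n_frames(x$ensemble), ">")
    else NULL
    x
  })
  m$component_map <- if (is.data.frame(m$component_map))
    paste0("<map:", nrow(m$component_map), ">") else m$component_map
  m
}
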