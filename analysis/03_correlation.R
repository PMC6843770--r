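#!/usr/bin/env Rscript
# Cross-correlation analysis: per-bead Pearson CCij from the mass-weighted
# covariance, repeat-aggregated correlation scores (CS), and switch-region
# detection.  The wild-type-like model should show its planted lockstep
# N-/C-terminal blocks against an anticorrelated centre; the accordion-like
# variant should yield a single switch region at the planted pivot.

suppressMessages(library(ensdyn))

sim <- "results/sim"
out <- "results/corr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

analyse <- function(model, map_file, probe) {
  ens <- read_structure(file.path(sim, paste0(model, ".pdb")))
  beads <- select_beads(ens, load_component_map(file.path(sim, map_file)))
  frames <- seq.int(window_resolve("last 50%", n_frames(ens))[1] + 1L,
                    n_frames(ens))
  sup <- superpose(ens, beads, reference_index = frames[1])
  cv <- covariance(sup, beads, frames)
  ccm <- suppressWarnings(cross_correlation(cv, zero_policy = "zero"))
  cs <- correlation_scores(ccm)
  write.csv(cbind(bead = seq_len(nrow(ccm$cc)), as.data.frame(ccm$cc)),
            file.path(out, paste0(model, "_cc.csv")), row.names = FALSE)
  write.csv(cbind(component = rownames(cs$cs), as.data.frame(cs$cs)),
            file.path(out, paste0(model, "_cs.csv")), row.names = FALSE)
  sw <- detect_switch_regions(ccm, pca_modes(cv, n_modes = 1), probe)
  utils::write.table(as.data.frame(sw),
                     file.path(out, paste0(model, "_switch_regions.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(cs = cs$cs, sw = sw)
}

wt <- analyse("wt", "heat_map.tsv", probe = "H1")
cat(sprintf(paste0(
  "wt: CS(H1, H20) = %.2f (planted lockstep 0.6), CS(H1, H10) = %.2f ",
  "(planted -0.5);\n    deviations from the planted values reflect the ",
  "common-mode motion removed by the RMS fit\n"),
  wt$cs["H1", "H20"], wt$cs["H1", "H10"]))
cat(sprintf("wt: %d switch region(s) pass the default flip/amplitude gates\n",
            nrow(wt$sw)))

mut <- analyse("mut", "arm_map.tsv", probe = "arm1")
cat(sprintf("mut: CS(arm1, arm2) = %.2f (strong anticorrelation)\n",
            mut$cs["arm1", "arm2"]))
if (nrow(mut$sw) >= 1)
  cat(sprintf("mut: switch region at residues %d-%d (planted pivot 50), flip %.2f\n",
              mut$sw$residue_start[1], mut$sw$residue_end[1], mut$sw$flip[1]))
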