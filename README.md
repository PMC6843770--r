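# ensdyn

Correlation and essential-dynamics analysis of biomolecular conformational
ensembles, at one bead per residue (Cα for amino acids, P for nucleotides).

Splicing-factor complexes such as the HEAT-repeat protein Hsh155/SF3B1 work
through large collective motions — an accordion-like opening and closing of
the super-helix around its intron substrate — and pathogenic point mutations
can rewire those motions.  Reading this behaviour out of a conformational
ensemble (typically an MD trajectory) takes a standard toolbox, which this
package implements end to end for comparative, multi-model studies:

* Kabsch superposition, RMSD / radius-of-gyration / per-bead RMSF profiles;
* the dynamical cross-correlation matrix
  `CC_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)` from the mass-weighted
  covariance of bead positions;
* component-aggregated **correlation scores**
  `CS(A,B) = Σ_{i∈A, j∈B} CC_ij / (|A||B|)` — the DCCM compressed to domain
  resolution (HEAT repeats, protein domains, RNA filaments);
* essential dynamics: eigen-decomposition of the covariance, cumulative
  variance, per-frame mode projections, NMWiz-compatible `.nmd` export;
* switch/hinge-region detection: sign changes of the cross-correlation at
  beads carrying minimal PC1 amplitude;
* geometric hydrogen-bond occupancy (donor–acceptor ≤ 3.3 Å, D–H···A
  ≥ 145°) with cross-model occupancy deltas;
* synthetic-ensemble generators with *planted* block correlations, hinge
  motions and H-bond occupancies, giving every stage exact ground truth.

I/O: multi-model PDB, GRO and DCD trajectories; component maps as 4-column
TSV; labelled CSV/TSV/NMD/JSON outputs.

## Worked example

```r
library(ensdyn)

# plant two 10-bead domains: strong internal coupling, anticorrelated
C <- build_correlation_matrix(c(dom1 = 10, dom2 = 10),
                              intra = 0.8, inter = -0.6)
ens <- sample_gaussian_ensemble(C, stddev = 1, n_frames = 2000, seed = 1)
map <- component_map(data.frame(
  component_name = c("dom1", "dom2"), chain_id = "A",
  residue_start = c(1, 11), residue_end = c(10, 20)))
beads <- select_beads(ens, map)

sup <- as_superposed(ens)        # generator output shares a common frame
ccm <- cross_correlation(covariance(sup, beads))
round(correlation_scores(ccm)$cs, 2)
#>       dom1  dom2
#> dom1  0.83 -0.61
#> dom2 -0.61  0.83
```

The recovered correlation scores sit on the planted values (diagonal blocks
include the `CC_ii = 1` self terms, hence 0.83 for a planted 0.8).  The
`analysis/` directory walks a full comparative study on simulated systems:

```sh
Rscript analysis/01_simulate.R          # build synthetic study systems
Rscript analysis/02_fluctuations.R      # RMSD / Rg / RMSF
Rscript analysis/03_correlation.R       # DCCM, CS, switch regions
Rscript analysis/04_essential_dynamics.R
Rscript analysis/05_hbonds.R
Rscript analysis/06_compare_models.R    # run_manifest() workflow
```

`analysis/03_correlation.R`, for instance, finds the planted accordion
pivot from the data alone:

```
mut: CS(arm1, arm2) = -0.90 (strong anticorrelation)
mut: switch region at residues 40-59 (planted pivot 50), flip 1.21
```

`analysis/07_worked_example_5gm6.R` is optional: given a locally downloaded
copy of the activated-spliceosome cryo-EM structure (PDB 5GM6) it measures
the branch-point-adenosine to 5'-splice-site distance (about 48 Å in the
deposited structure).

## Package layout

```
R/                  implementation (io, generators, fit, DCCM/CS, PCA, H-bonds,
                    comparison workflow)
analysis/           numbered narrative drivers writing under results/
tests/testthat/     unit, property and end-to-end acceptance tests
scripts/acceptance.R
vignettes/          methods vignette: model, conventions, design choices
```
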