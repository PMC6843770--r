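test_that("multi-model PDB round trip preserves frames, order and coordinates", {
  atoms <- backbone_atoms(3)
  set.seed(1)
  xyz <- rbind(spread_coords(nrow(atoms), 1), spread_coords(nrow(atoms), 2))
  path <- write_pdb_fixture(atoms, xyz)
  ens <- read_structure(path, "pdb")
  expect_equal(n_frames(ens), 2)
  expect_equal(n_atoms(ens), nrow(atoms))
  expect_equal(ens$atoms$atom_name, atoms$atom_name)
  expect_equal(ens$atoms$residue_number, atoms$residue_number)
  expect_lt(max(abs(ens$xyz - xyz)), 1e-3 + 1e-12)  # PDB keeps 3 decimals
  # masses from element lookup, not from the file
  expect_equal(ens$atoms$mass[1:4], element_mass(c("N", "C", "C", "O")))
})

test_that("PDB models with inconsistent atom counts are rejected", {
  atoms <- backbone_atoms(2)
  path <- write_pdb_fixture(atoms, spread_coords(nrow(atoms)))
  lines <- readLines(path)
  # duplicate as model 2 but drop its last atom
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  bad <- c("MODEL     1", atom_lines, "ENDMDL",
           "MODEL     2", atom_lines[-length(atom_lines)], "ENDMDL", "END")
  bad_path <- tempfile(fileext = ".pdb")
  writeLines(bad, bad_path)
  expect_error(read_structure(bad_path, "pdb"), "inconsistent atom count")
})

test_that("malformed PDB records are reported with a line number", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad coords"), path)
  expect_error(read_structure(path, "pdb"), "line 1")
})

test_that("GRO coordinates are converted from nm to Angstrom", {
  path <- tempfile(fileext = ".gro")
  writeLines(c(
    "test system",
    "    3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "N", 1, 0.1, 0.2, 0.3),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "CA", 2, 0.25, 0.2, 0.3),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "ALA", "C", 3, 0.4, 0.2, 0.3),
    "   5.0   5.0   5.0"
  ), path)
  ens <- read_structure(path, "gro")
  expect_equal(n_frames(ens), 1)
  expect_equal(n_atoms(ens), 3)
  expect_equal(frame_coords(ens, 1)[1, ], c(1, 2, 3))     # 0.1 nm -> 1 A
  expect_equal(frame_coords(ens, 1)[2, 1], 2.5)
})

test_that("DCD trajectories round trip against a topology", {
  atoms <- backbone_atoms(4)
  set.seed(3)
  xyz <- do.call(rbind, lapply(1:10, function(i) spread_coords(nrow(atoms), i)))
  ens <- ensemble(atoms, xyz)
  top <- write_pdb_fixture(atoms, xyz[1, ])
  dcd <- tempfile(fileext = ".dcd")
  write_trajectory(ens, dcd, "dcd")
  back <- read_trajectory(top, dcd, "dcd")
  expect_equal(n_frames(back), 10)
  expect_equal(n_atoms(back), nrow(atoms))
  expect_lt(max(abs(back$xyz - xyz)), 1e-4)  # single-precision storage
  # atom-count mismatch is a dimension error
  small_top <- write_pdb_fixture(backbone_atoms(3), spread_coords(12))
  expect_error(read_trajectory(small_top, dcd), "dimension error")
})

test_that("component maps validate ranges and reject overlaps", {
  map <- component_map(data.frame(
    component_name = c("H1", "H2"), chain_id = "B",
    residue_start = c(1, 41), residue_end = c(40, 80)))
  expect_s3_class(map, "component_map")
  expect_equal(nrow(map), 2)
  expect_error(component_map(data.frame(
    component_name = c("H1", "H1b"), chain_id = "B",
    residue_start = c(1, 30), residue_end = c(40, 50))), "overlap")
  expect_error(component_map(data.frame(
    component_name = "X", chain_id = "B",
    residue_start = 10, residue_end = 5)), "residue_start > residue_end")
  # TSV round trip incl. empty map
  path <- tempfile(fileext = ".tsv")
  write_component_map(map, path)
  expect_equal(as.data.frame(load_component_map(path)), as.data.frame(map))
  empty <- component_map(data.frame(component_name = character(),
                                    chain_id = character(),
                                    residue_start = integer(),
                                    residue_end = integer()))
  expect_equal(nrow(empty), 0)
})

test_that("bead selection takes one CA per amino acid and one P per nucleotide", {
  atoms <- rbind(
    backbone_atoms(3),
    data.frame(atom_name = c("O5'", "C5'",          # 5'-terminal nt: no P
                             "P", "O5'", "P", "O5'"),
               element = c("O", "C", "P", "O", "P", "O"),
               residue_number = c(10, 10, 11, 11, 12, 12),
               residue_name = "U", chain_id = "R",
               stringsAsFactors = FALSE))
  ens <- ensemble(atoms, spread_coords(nrow(atoms)))
  expect_warning(beads <- select_beads(ens), "lacking a bead atom")
  expect_equal(nrow(beads), 5)  # 3 CA + 2 P
  expect_equal(beads$atom_name, c("CA", "CA", "CA", "P", "P"))
  expect_true(all(diff(beads$atom_index) > 0))
  # selection depends only on the atom table, not the frame content
  ens2 <- ens; ens2$xyz <- ens$xyz + 100
  expect_equal(suppressWarnings(select_beads(ens2)), beads)
  # ligand-only structure: no beads
  lig <- ensemble(data.frame(atom_name = c("C1", "C2"), element = "C",
                             residue_number = 1, residue_name = "LIG",
                             chain_id = "X", stringsAsFactors = FALSE),
                  spread_coords(2))
  expect_error(select_beads(lig), "empty-selection")
  # component labels from a map; unmapped beads stay unassigned
  map <- component_map(data.frame(component_name = "prot", chain_id = "A",
                                  residue_start = 1, residue_end = 2))
  withmap <- suppressWarnings(select_beads(ens, map))
  expect_equal(withmap$component, c("prot", "prot", "unassigned",
                                    "unassigned", "unassigned"))
})

test_that("synthetic ensembles survive a trajectory round trip unchanged", {
  ens <- sample_gaussian_ensemble(build_correlation_matrix(c(A = 5), 0.5),
                                  stddev = 1, n_frames = 8, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(ens, path)
  back <- read_structure(path)
  expect_equal(n_frames(back), 8)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-12)
})
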