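# Structure model: PDB I/O, model selection, selection resolution.

test_that("write/read round trip preserves identity and coordinates to 3 decimals", {
  s <- make_helix(20, backbone = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(nrow(s2$atoms), 20 * 5)
  expect_identical(s2$atoms[c("chain", "resseq", "resname", "atom")],
                   s$atoms[c("chain", "resseq", "resname", "atom")])
  expect_lt(max(abs(coords(s2) - coords(s))), 5.1e-4)
  # per-residue atom roster as generated: N, CA, C, O, CB
  expect_setequal(unique(s2$atoms$atom), c("N", "CA", "C", "O", "CB"))
  expect_equal(as.integer(table(s2$atoms$resseq)), rep(5L, 20))
})

test_that("read_pdb handles models, HETATM retention and malformed input", {
  a <- make_helix(10)
  b <- set_coords(a, coords(a) + 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(new_trajectory(a, list(coords(a), coords(b))), path)
  s1 <- read_pdb(path, model = "first")
  s2 <- read_pdb(path, model = 2)
  expect_equal(nrow(s1$atoms), 10)
  expect_equal(max(abs(coords(s2) - coords(s1) - 5)), 0, tolerance = 1e-3)
  expect_error(read_pdb(path, model = 9), "model 9 absent")

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad     0.000   0.000  1.00  0.00           C",
               "END"), bad)
  expect_error(read_pdb(bad), "line 1")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("TITLE     nothing here", "END"), empty)
  expect_error(read_pdb(empty), "no ATOM/HETATM")

  # HETATM ligand/water records keep their residue codes
  lig <- plant_site(data.frame(resseq = c(1, 2), resname = c("NO3", "HOH"),
                               atom = c("N", "O"), x = c(0, 3), y = 0, z = 0))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(lig, path2)
  s3 <- read_pdb(path2)
  expect_setequal(s3$atoms$resname, c("NO3", "HOH"))
  expect_true(all(s3$atoms$het))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AALA A   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       3.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(1, 2))   # occupancy winner, then alphabetical tie
})

test_that("read_multimodel builds a trajectory and rejects roster mismatches", {
  a <- make_helix(10)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(a, path)
  tr1 <- read_multimodel(path)
  expect_equal(n_frames(tr1), 1)

  traj <- make_trajectory(a, set_coords(a, coords(a) + 1), n_frames = 50)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj, path2)
  tr <- read_multimodel(path2)
  expect_equal(n_frames(tr), 50)
  expect_equal(coords(tr$topology), tr$frames[[1]])

  # drop one atom from the second model
  lines <- readLines(path2)
  atom_idx <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_idx[11]], path2)
  expect_error(read_multimodel(path2), "model 2")
})

test_that("resolve is ordered, idempotent, and counts skipped residues", {
  s <- make_helix(233, backbone = TRUE)
  # remove residues 1-14 (a disordered N-terminus)
  s <- new_structure(s$atoms[s$atoms$resseq >= 15, ], title = "")
  r <- resolve(sel(ranges = list(c(1, 233)), atoms = "CA"), s)
  expect_equal(nrow(r$coords), 219)
  expect_equal(r$n_skipped, 14)
  r2 <- resolve(sel(ranges = list(c(1, 233)), atoms = "CA"), s)
  expect_identical(r, r2)

  # empty range list means all residues; atoms "all" means every atom
  expect_equal(nrow(resolve(sel(), s)$coords), nrow(s$atoms))

  # union of disjoint ranges equals concatenated ranges, ascending order
  ra <- resolve(sel(ranges = list(c(20, 30)), atoms = "CA"), s)
  rb <- resolve(sel(ranges = list(c(40, 50)), atoms = "CA"), s)
  rab <- resolve(sel(ranges = list(c(20, 30), c(40, 50)), atoms = "CA"), s)
  expect_equal(rab$index, c(ra$index, rb$index))
  expect_false(any(ra$index %in% rb$index))
  expect_false(is.unsorted(rab$keys$resseq))

  expect_error(resolve(sel(ranges = list(c(500, 600))), s), "zero atoms")
  expect_error(sel(ranges = list(c(10, 5))), "start <= end")
})

test_that("selections exclude waters/ligands unless named, and hydrogens always", {
  at <- data.frame(resseq = c(1, 1, 2, 3), resname = c("ALA", "ALA", "HOH", "NO3"),
                   atom = c("CA", "HA", "O", "N"),
                   element = c("C", "H", "O", "N"),
                   x = 0:3, y = 0, z = 0)
  s <- plant_site(at)
  expect_equal(nrow(resolve(sel(), s)$coords), 1)          # CA only
  expect_equal(nrow(resolve(sel(resnames = "HOH"), s)$coords), 1)
  expect_equal(nrow(resolve(sel(resnames = "NO3"), s)$coords), 1)
})

test_that("parse_selection handles ranges, unions and all", {
  s1 <- parse_selection("1-233:CA")
  expect_equal(s1$ranges, list(c(1L, 233L)))
  expect_equal(s1$atoms, "CA")
  s2 <- parse_selection("369-380,399-409:CA")
  expect_length(s2$ranges, 2)
  s3 <- parse_selection("all:all")
  expect_equal(s3$atoms, "all")
  expect_length(s3$ranges, 0)
  expect_error(parse_selection("nonsense"), "selection")
})
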