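# Structure and map IO: PDB/mmCIF parsing, alternate locations, selections,
# MRC round trips and axis-order handling.

test_that("a minimal one-atom PDB record reads to an atom at the origin", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- readStructure(f)
  expect_equal(nAtoms(m), 1L)
  at <- atoms(m)
  expect_equal(unname(unlist(at[1, c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(at$chain, "A")
  expect_equal(at$resname, "ALA")
  expect_equal(at$atom, "CA")
  expect_equal(at$element, "C")
})

test_that("PDB write -> read -> write -> read round-trips the atom table exactly", {
  m <- buildToyAssembly(assemblyScenario(seed = 5))
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  writeStructure(m, f1)
  m1 <- readStructure(f1)
  writeStructure(m1, f2)
  m2 <- readStructure(f2)
  expect_identical(atoms(m1), atoms(m2))
  # first write quantises to the format's 3 decimals
  expect_lt(max(abs(coords(m) - coords(m1))), 5.1e-4)
  expect_equal(nAtoms(m), nAtoms(m1))
})

test_that("mmCIF write -> read round-trips coordinates and identity", {
  m <- mkModel(chain = c("AB", "AB", "CD"), resno = c(1L, 2L, 7L),
               resname = c("ALA", "GLY", "ARG"),
               atom = c("CA", "CA", "NH1"), element = c("C", "C", "N"),
               x = c(0.125, 3, -2), y = c(1, 2.25, 0), z = c(0, -1, 4.5))
  f <- tempfile(fileext = ".cif")
  writeStructure(m, f)
  m2 <- readStructure(f)
  expect_equal(atoms(m2)$chain, atoms(m)$chain)  # multi-character chains survive
  expect_equal(atoms(m2)$resno, atoms(m)$resno)
  expect_equal(coords(m2), coords(m), tolerance = 1e-8)
})

test_that("alternate locations resolve to highest occupancy, ties to first", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- readStructure(f)
  at <- atoms(m)
  expect_equal(nAtoms(m), 2L)
  expect_equal(at$x[at$atom == "CA"], 2)  # higher occupancy wins
  expect_equal(at$x[at$atom == "CB"], 3)  # tie keeps the first encountered
})

test_that("reading stops at the first model and errors usefully", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "ATOM      2  CA  ALA A   2       9.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_equal(nAtoms(readStructure(f)), 1L)
  f2 <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(readStructure(f2), "empty model")
  f3 <- tempfile(fileext = ".pdb")
  writeLines("ATOM      1  CA  ALA A   1       bad coords here", f3)
  expect_error(readStructure(f3), "format error")
})

test_that("selections subset by chain, residue, atom name and heaviness", {
  m <- mkModel(chain = c("A", "A", "A", "A", "B"),
               resno = c(384L, 384L, 384L, 384L, 1L),
               resname = c("ARG", "ARG", "ARG", "ARG", "GLY"),
               atom = c("NH1", "NH2", "NE", "HB2", "CA"),
               element = c("N", "N", "N", "H", "C"),
               x = 1:5, y = 0, z = 0)
  expect_equal(nAtoms(selectAtoms(m, atomSelection(chains = "A"))), 4L)
  guan <- selectAtoms(m, atomSelection(residues = 384,
                                       atomNames = c("NH1", "NH2", "NE", "CZ")))
  expect_equal(sort(atoms(guan)$atom), c("NE", "NH1", "NH2"))
  expect_equal(nAtoms(selectAtoms(m, atomSelection())), 5L)  # select-all
  expect_equal(nAtoms(selectAtoms(m, atomSelection(heavyOnly = TRUE))), 4L)
  # empty result is allowed
  expect_equal(nAtoms(selectAtoms(m, atomSelection(chains = "Z"))), 0L)
})

test_that("MRC maps round-trip grid, voxel size and origin", {
  set.seed(11)
  g <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  mp <- densityMap(g, voxel = c(1.2, 1.3, 1.1), origin = c(-3, 2, 5))
  f <- tempfile(fileext = ".mrc")
  writeDensityMap(mp, f)
  mp2 <- readDensityMap(f)
  # float32 storage precision
  expect_lt(max(abs(mapGrid(mp2) - g)), 1e-6)
  expect_equal(voxelSize(mp2), c(1.2, 1.3, 1.1), tolerance = 1e-6)
  expect_equal(mapOrigin(mp2), c(-3, 2, 5), tolerance = 1e-6)
  # second round trip is exact
  f2 <- tempfile(fileext = ".mrc")
  writeDensityMap(mp2, f2)
  expect_identical(mapGrid(readDensityMap(f2)), mapGrid(mp2))
})

test_that("header statistics are consistent for a constant map", {
  mp <- densityMap(array(1, dim = c(2, 2, 2)), voxel = 1)
  f <- tempfile(fileext = ".mrc")
  writeDensityMap(mp, f)
  st <- mapStatistics(readDensityMap(f))
  expect_equal(unname(st["mean"]), 1)
  expect_equal(unname(st["rms"]), 0)
})

test_that("unsupported MRC modes are rejected explicitly", {
  mp <- densityMap(array(0, dim = c(2, 2, 2)))
  f <- tempfile(fileext = ".mrc")
  writeDensityMap(mp, f)
  raw <- readBin(f, "raw", file.size(f))
  raw[13] <- as.raw(4)  # mode word -> 4 (complex), unsupported
  writeBin(raw, f)
  expect_error(readDensityMap(f), "unsupported MRC mode")
})

test_that("start-index origin dialect fires when ORIGIN is all zero", {
  mp <- densityMap(array(0, dim = c(3, 3, 3)), voxel = 2)
  f <- tempfile(fileext = ".mrc")
  writeDensityMap(mp, f)
  raw <- readBin(f, "raw", file.size(f))
  con <- rawConnection(raw, "r+")
  seek(con, 16); writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  patched <- rawConnectionValue(con); close(con)
  writeBin(patched, f)
  mp2 <- readDensityMap(f)
  expect_equal(mapOrigin(mp2), c(2, 4, 6))
  expect_match(mp2@originRule, "start-indices")
})

test_that("map lookup is invariant under the stored axis order", {
  set.seed(21)
  g <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  canonical <- densityMap(g, voxel = 2, origin = c(1, 2, 3))
  f <- tempfile(fileext = ".mrc")
  # hand-write a permuted-order file: columns = y, rows = x, sections = z
  gp <- aperm(g, c(2, 1, 3))
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(gp)); wi(2L); wi(c(0L, 0L, 0L)); wi(dim(g))
  wf(dim(g) * 2); wf(c(90, 90, 90)); wi(c(2L, 1L, 3L))
  wf(c(min(g), max(g), mean(g))); wi(1L); wi(0L); wi(rep(0L, 25))
  wf(c(1, 2, 3)); writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con); wf(0); wi(0L)
  writeBin(raw(800), con)
  writeBin(as.vector(gp), con, size = 4, endian = "little")
  close(con)
  permuted <- readDensityMap(f)
  set.seed(22)
  pts <- cbind(runif(50, 1, 7), runif(50, 2, 10), runif(50, 3, 13))
  expect_equal(mapValuesAt(permuted, pts), mapValuesAt(canonical, pts),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("simulated map values at generating atom centres match the analytic sum", {
  # atoms placed on lattice nodes so interpolation is exact at their centres
  m <- mkModel(x = c(0, 2, 4), y = c(0, 0, 2), z = c(0, 2, 0))
  cfg <- mapSimulationConfig(resolution = 6, voxel = 1, padding = 6)
  map <- simulateMap(m, cfg)
  pos <- coords(m)
  sigma <- cfg$sigma
  analytic <- vapply(seq_len(3), function(i) {
    d2 <- rowSums(sweep(pos, 2, pos[i, ], "-")^2)
    sum((2 * pi * sigma^2)^(-1.5) * exp(-d2 / (2 * sigma^2)))
  }, numeric(1))
  expect_equal(as.numeric(mapValuesAt(map, pos)), analytic, tolerance = 1e-6)
})
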