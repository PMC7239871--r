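test_that("minimal structure writes one atom record and no connectivity", {
  s <- NanoStructure(data.frame(serial = 1L, element = "Au", name = "Au1",
                                fragmentId = 0L, x = 0, y = 0, z = 0),
                     identifier = "oneAu", materialClass = "GNP",
                     shape = "sphere", sizeNm = 0.1)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "HETATM")), 1L)
  expect_equal(sum(startsWith(lines, "CONECT")), 0L)
})

test_that("C60 writes 60 atom records and connectivity covering 90 pairs", {
  c60 <- buildFullerene()
  expect_equal(nAtoms(c60), 60L)
  # brute-force edge enumeration at the bonding cutoff
  xyz <- coordinates(c60)
  d <- as.matrix(dist(xyz))
  expect_equal(sum(d < 1.2 * 2 * covalentRadius("C") & upper.tri(d)), 90L)
  expect_equal(nBonds(c60), 90L)

  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(c60, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "HETATM")), 60L)
  rt <- readPDB(f)
  key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  expect_setequal(key(bonds(rt)), key(bonds(c60)))
})

test_that("write/read round trip preserves atoms, bonds and metadata", {
  core <- buildCore(coreSpec("fcc-Pt", diameterNm = 1.2))
  dec <- graftLigands(core, data.frame(smiles = "CCS", count = 4), seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(dec, f)
  rt <- readPDB(f)

  expect_equal(atoms(rt)$serial, atoms(dec)$serial)
  expect_equal(atoms(rt)$element, atoms(dec)$element)
  expect_equal(atoms(rt)$fragmentId, atoms(dec)$fragmentId)
  # coordinates at 3-decimal precision (writer re-centres the centroid)
  centred <- sweep(coordinates(dec), 2, colMeans(coordinates(dec)))
  expect_lt(max(abs(coordinates(rt) - centred)), 5e-4 + 1e-9)
  key <- function(b) paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  expect_setequal(key(bonds(rt)), key(bonds(dec)))
  expect_identical(materialClass(rt), "PtNP")
  expect_identical(particleShape(rt), "sphere")
  expect_equal(sizeNm(rt), sizeNm(dec))
  expect_equal(ligandTable(rt)$smiles, "CCS")
  expect_equal(ligandTable(rt)$count, 4L)
})

test_that("rod annotations round-trip, including equal diameter and length", {
  rod <- buildCore(coreSpec("fcc-Pd", diameterNm = 1.2, shape = "rod",
                            lengthNm = 2.4))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(rod, f)
  expect_equal(sizeNm(readPDB(f)), c(1.2, 2.4))

  sq <- buildCore(coreSpec("fcc-Pd", diameterNm = 1.5, shape = "rod",
                           lengthNm = 1.5))
  writePDB(sq, f)
  expect_equal(sizeNm(readPDB(f)), c(1.5, 1.5))
})

test_that("files without connectivity give atoms with an empty bond list", {
  s <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f)
  rt <- readPDB(f)
  expect_equal(nAtoms(rt), nAtoms(s))
  expect_equal(nBonds(rt), 0L)
})

test_that("malformed input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK 300 MATERIAL GNP", "END"), f)
  expect_error(readPDB(f), "empty structure")

  # duplicate serials violate the uniqueness invariant
  au <- sprintf(
    "HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    c(1L, 1L), "Au", "COR", 0L, c(0, 1), c(0, 1), c(0, 1), "Au")
  writeLines(c(au, "END"), f)
  expect_error(readPDB(f), "duplicate")

  # corrupt coordinate field names the line
  bad <- sprintf(
    "HETATM%5d %-4s %3s A%4d    %8s%8.3f%8.3f  1.00  0.00          %2s",
    1L, "Au", "COR", 0L, "bad.x.00", 0, 0, "Au")
  writeLines(c(bad, "END"), f)
  expect_error(readPDB(f), "line 1")
})

test_that("hybrid-36 widened serials survive a write/read cycle", {
  enc <- nanotess:::.hy36encode(c(1L, 99999L, 100000L, 123456L))
  expect_identical(enc[3], "A0000")
  expect_equal(nanotess:::.hy36decode(enc), c(1L, 99999L, 100000L, 123456L))

  # small structure whose serials sit above the legacy 5-digit limit
  s <- NanoStructure(data.frame(
    serial = 99998L + 1:5, element = "Au", name = paste0("Au", 1:5),
    fragmentId = 0L, x = as.numeric(1:5), y = 0, z = 0),
    bonds = cbind(99998L + 1:4, 99998L + 2:5),
    identifier = "bigSerials", materialClass = "GNP")
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, f)
  rt <- readPDB(f)
  expect_equal(atoms(rt)$serial, atoms(s)$serial)
  expect_equal(nBonds(rt), 4L)
})

test_that("unknown elements are rejected at construction", {
  expect_error(
    NanoStructure(data.frame(serial = 1L, element = "Xx", name = "X",
                             fragmentId = 0L, x = 0, y = 0, z = 0)),
    "unknown element")
})

test_that("written files are readable by an independent PDB parser", {
  skip_if_not_installed("bio3d")
  c60 <- buildFullerene()
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDB(c60, f)
  ext <- suppressWarnings(bio3d::read.pdb(f))
  expect_equal(nrow(ext$atom), 60L)
  expect_equal(unname(ext$atom$elesy), atoms(c60)$element)
  ours <- sweep(coordinates(c60), 2, colMeans(coordinates(c60)))
  theirs <- cbind(ext$atom$x, ext$atom$y, ext$atom$z)
  expect_lt(max(abs(ours - theirs)), 5e-4 + 1e-9)
})

test_that("atom/bond CSV export round-trips through read.csv", {
  c60 <- buildFullerene()
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  writeStructureCSV(c60, fa, fb)
  expect_equal(nrow(read.csv(fa)), 60L)
  expect_equal(nrow(read.csv(fb)), 90L)
})
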