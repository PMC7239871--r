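test_that("fcc sphere carving matches brute-force lattice enumeration", {
  # d = 1 nm gold sphere: count fcc points within 5 Angstrom of a site
  au <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
  expect_equal(nAtoms(au), bruteFccCount(a = 4.078, radius = 5))
  # every atom is a lattice point of the replicated cell
  frac <- coordinates(au) %*% solve(nanotess:::.cellVectors(
    latticeRegistry("fcc-Au"))) * 2  # fcc sites live on half-integer frac
  expect_lt(max(abs(frac - round(frac))), 1e-6)

  pd <- buildCore(coreSpec("fcc-Pd", diameterNm = 1.4))
  expect_equal(nAtoms(pd), bruteFccCount(a = 3.891, radius = 7))
})

test_that("atom count scales with carved volume", {
  n2 <- nAtoms(buildCore(coreSpec("fcc-Au", diameterNm = 2)))
  n4 <- nAtoms(buildCore(coreSpec("fcc-Au", diameterNm = 4)))
  expect_lt(abs(n4 / n2 - 8), 0.15 * 8)
})

test_that("degenerate core specs error out", {
  expect_error(buildCore(coreSpec("fcc-Au", diameterNm = 0.2)), "too small")
  expect_error(coreSpec("no-such-material", diameterNm = 2), "unknown material")
  expect_error(coreSpec("fcc-Au", diameterNm = -1), "positive")
})

test_that("rod cores respect the declared diameter and length", {
  rod <- buildCore(coreSpec("fcc-Au", diameterNm = 1.5, shape = "rod",
                            lengthNm = 3))
  xyz <- coordinates(rod)
  expect_lte(max(sqrt(xyz[, 1]^2 + xyz[, 2]^2)) * 2, 15 + 1e-6)
  expect_lte(diff(range(xyz[, 3])), 30 + 1e-6)
  expect_gt(diff(range(xyz[, 3])), 15)  # longer than wide
  expect_equal(sizeNm(rod), c(1.5, 3))
})

test_that("CNT geometry follows the roll-up construction", {
  # (5,5): closed-form d = 2.46 * sqrt(75) / pi = 6.781 Angstrom
  expect_equal(cntDiameter(5, 5), 2.46 * sqrt(75) / pi)
  cnt <- buildCNT(cntSpec(5, 5, lengthNm = 0.246))
  expect_true(all(atoms(cnt)$element == "C"))
  radii <- sqrt(rowSums(coordinates(cnt)[, 1:2]^2))
  expect_lt(diff(range(radii)), 0.01)   # all atoms on a common cylinder
  expect_equal(mean(radii) * 2, cntDiameter(5, 5), tolerance = 1e-9)
})

test_that("interior CNT atoms have exactly 3 bonded neighbours", {
  cnt <- buildCNT(cntSpec(6, 6, lengthNm = 1.0))
  b <- bonds(cnt)
  degree <- table(factor(c(b[, 1], b[, 2]), levels = atoms(cnt)$serial))
  z <- coordinates(cnt)[, 3]
  interior <- z > min(z) + 1.5 & z < max(z) - 1.5
  expect_true(all(degree[interior] == 3))
  expect_true(all(degree <= 3))
})

test_that("invalid chiralities are rejected", {
  expect_error(cntSpec(0, 0, 1), "invalid chirality")
  expect_error(cntSpec(3, 5, 1), "n >= m")
})

test_that("cyclic peptide rings close with one peptide bond per residue", {
  ring <- buildCPNT(cpntSpec("AGAGAGAG", ringCount = 1))
  expect_equal(peptideBondCount(ring), 8L)
  ring5 <- buildCPNT(cpntSpec(c("LYS", "GLN", "ALA", "TRP", "PHE"),
                              ringCount = 1))
  expect_equal(peptideBondCount(ring5), 5L)
})

test_that("stacked rings replicate atom counts and axial extent", {
  one <- buildCPNT(cpntSpec("AGAGAGAG", ringCount = 1))
  three <- buildCPNT(cpntSpec("AGAGAGAG", ringCount = 3))
  expect_equal(nAtoms(three), 3L * nAtoms(one))

  # backbone (N/CA/C) centroid extent ~ (ringCount - 1) * 4.8 Angstrom
  a <- atoms(three)
  bb <- a[grepl("^(N|CA|C)_", a$name), ]
  ring <- as.integer(sub(".*r", "", bb$name))
  zc <- tapply(bb$z, ring, mean)
  expect_lt(abs(diff(range(zc)) - 2 * 4.8), 0.5)
})

test_that("unknown residue codes are rejected", {
  expect_error(cpntSpec("AGB"), "unknown residue")
  expect_error(cpntSpec("AG"), "at least 3")
})

test_that("ligand embedding does valence-correct hydrogen addition", {
  # ethanethiol CCS: 3 heavy atoms + 6 H; propanethiol CCCS: 4 heavy + 8 H
  eth <- embedLigand("CCS")
  expect_equal(sum(eth$elements != "H"), 3L)
  expect_equal(sum(eth$elements == "H"), 6L)
  prop <- embedLigand("CCCS")
  expect_equal(sum(prop$elements != "H"), 4L)
  expect_equal(sum(prop$elements == "H"), 8L)
  expect_identical(prop$elements[prop$anchor], "S")  # thiol anchor rule
})

test_that("embedding is deterministic under a fixed seed", {
  a <- embedLigand("OC(=O)CS", seed = 11)
  b <- embedLigand("OC(=O)CS", seed = 11)
  expect_identical(a$coords, b$coords)
  c <- embedLigand("OC(=O)CS", seed = 12)
  expect_false(identical(a$coords, c$coords))
})

test_that("embedded conformers have sane bond geometry", {
  conf <- embedLigand("NCCS")
  bl <- sqrt(rowSums((conf$coords[conf$bonds[, 1], ] -
                      conf$coords[conf$bonds[, 2], ])^2))
  ideal <- covalentRadius(conf$elements[conf$bonds[, 1]]) +
           covalentRadius(conf$elements[conf$bonds[, 2]])
  expect_lt(max(abs(bl - ideal) / ideal), 0.25)
})

test_that("empty or invalid SMILES are rejected", {
  expect_error(embedLigand(""), "invalid SMILES")
  expect_error(embedLigand("not-a-smiles((("), "invalid SMILES")
})

test_that("grafting zero ligands is the identity on the core", {
  core <- buildCore(coreSpec("fcc-Au", diameterNm = 1.5))
  out <- graftLigands(core, data.frame(smiles = "CCS", count = 0), seed = 1)
  expect_equal(atoms(out), atoms(core))
  expect_equal(nBonds(out), nBonds(core))
})

test_that("requests beyond the surface capacity raise a capacity error", {
  core <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
  nSites <- length(surfaceSites(core))
  expect_error(
    graftLigands(core, data.frame(smiles = "CCS", count = nSites + 1),
                 seed = 1),
    "capacity")
})

test_that("grafted output conserves core atoms and adds anchor bonds", {
  core <- buildCore(coreSpec("fcc-Au", diameterNm = 2))
  conf <- embedLigand("CCCS", seed = 5)
  out <- graftLigands(core, data.frame(smiles = "CCCS", count = 20), seed = 5)

  expect_equal(nAtoms(out), nAtoms(core) + 20L * length(conf$elements))
  # core atoms unchanged, in place
  expect_equal(atoms(out)[seq_len(nAtoms(core)), ], atoms(core))
  # exactly 20 new core-anchor bonds: S bonded to an Au serial
  b <- bonds(out)
  el <- setNames(atoms(out)$element, atoms(out)$serial)
  coreAnchor <- (el[as.character(b[, 1])] == "Au") |
                (el[as.character(b[, 2])] == "Au")
  expect_equal(sum(coreAnchor), 20L)
  # each anchor bonded to a distinct surface atom
  auEnd <- ifelse(el[as.character(b[, 1])] == "Au", b[, 1], b[, 2])[coreAnchor]
  expect_equal(length(unique(auEnd)), 20L)
  # ligand instances carry their own fragment ids
  expect_equal(length(setdiff(unique(atoms(out)$fragmentId), 0L)), 20L)
  # no inter-ligand heavy-atom clash below 1.0 Angstrom
  lig <- atoms(out)[atoms(out)$fragmentId > 0L & atoms(out)$element != "H", ]
  d <- as.matrix(dist(lig[, c("x", "y", "z")]))
  sameFrag <- outer(lig$fragmentId, lig$fragmentId, "==")
  expect_gt(min(d[!sameFrag & upper.tri(d)]), 1.0)
})

test_that("grafting is reproducible under a fixed seed", {
  core <- buildCore(coreSpec("fcc-Ag", diameterNm = 1.5))
  a <- graftLigands(core, data.frame(smiles = "CCS", count = 6), seed = 9)
  b <- graftLigands(core, data.frame(smiles = "CCS", count = 6), seed = 9)
  expect_equal(atoms(a), atoms(b))
})

test_that("declared sizes are consistent with coordinate extents", {
  expect_true(sizeConsistent(buildCore(coreSpec("fcc-Au", diameterNm = 2))))
  expect_true(sizeConsistent(buildCore(coreSpec("rutile-TiO2",
                                                diameterNm = 1.8))))
})
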