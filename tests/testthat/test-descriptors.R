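test_that("the tetrahedron class alphabet has exactly 126 entries", {
  cls <- tetrahedronClasses()
  expect_length(cls, 126L)
  expect_false(anyDuplicated(cls) > 0)
  expect_true(all(nchar(cls) == 4L))
})

test_that("four non-coplanar atoms give exactly one tetrahedron", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tets <- tessellate(p)
  expect_equal(nrow(tets), 1L)
  expect_equal(sort(tets[1, ]), 1:4)
})

test_that("five points in general position match the brute-force oracle", {
  set.seed(5)
  p <- matrix(runif(15), ncol = 3)
  tets <- tessellate(p, jitter = FALSE)
  expect_true(nrow(tets) %in% 2:3)
  expect_equal(unname(tets), unname(bruteDelaunay(p)))
})

test_that("degenerate geometries are refused", {
  expect_error(tessellate(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate|at least 4")
  coplanar <- cbind(matrix(runif(10), ncol = 2), 0)
  expect_error(tessellate(coplanar), "coplanar")
  expect_error(tessellate(matrix(runif(30), ncol = 3), atomBudget = 5),
               "budget")
})

test_that("tessellation matches the empty-circumsphere oracle on 100 random sets", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample(6:10, 1)
    p <- matrix(runif(3 * n), ncol = 3)
    expect_equal(unname(tessellate(p, jitter = FALSE)),
                 unname(bruteDelaunay(p)),
                 info = paste("case", case))
  }
})

test_that("classification lands in the right classes and conserves counts", {
  # all-carbon 4-atom structure: one count in CCCC
  s <- randomCloudStructure(4, seed = 1, elements = "C")
  counts <- classifyTetrahedra(tessellate(s), s)
  expect_equal(sum(counts), 1L)
  expect_equal(unname(counts["CCCC"]), 1L)

  # 4 Au + 1 S: only classes over the {X, M} sub-alphabet are populated
  s2 <- randomCloudStructure(5, seed = 2, elements = c("Au", "Au", "Au", "Au", "S"))
  tets2 <- tessellate(s2)
  counts2 <- classifyTetrahedra(tets2, s2)
  expect_equal(sum(counts2), nrow(tets2))
  populated <- names(counts2)[counts2 > 0]
  expect_true(all(grepl("^[XM]+$", populated)))

  # conservation on a larger cloud
  s3 <- randomCloudStructure(40, seed = 3, elements = c("C", "H", "O", "N"))
  tets3 <- tessellate(s3)
  expect_equal(sum(classifyTetrahedra(tets3, s3)), nrow(tets3))
})

test_that("unknown scheme entries raise a named error", {
  s <- randomCloudStructure(5, seed = 4, elements = "Au")
  tets <- tessellate(s)
  scheme <- atomTypeScheme()
  expect_error(classifyTetrahedra(tets, s, scheme[names(scheme) != "Au"]),
               "Au")
})

test_that("occurrences convert to frequencies summing to one", {
  counts <- setNames(integer(126), tetrahedronClasses())
  counts[1] <- 1L
  expect_equal(unname(tetrahedronFrequencies(counts)[1]), 1)
  counts[1] <- 2L; counts[5] <- 2L
  fr <- tetrahedronFrequencies(counts)
  expect_equal(unname(fr[c(1, 5)]), c(0.5, 0.5))

  set.seed(9)
  counts[] <- rpois(126, 2)
  expect_equal(sum(tetrahedronFrequencies(counts)), 1, tolerance = 1e-12)
  expect_error(tetrahedronFrequencies(counts * 0L), "zero tetrahedra")
})

test_that("homogeneous structures give frequency x 4 x property values", {
  s <- randomCloudStructure(4, seed = 6, elements = "Au")
  d <- nanoDescriptors(s)
  tbl <- atomicProperties()
  chiAu <- tbl$chi[tbl$element == "Au"]
  expect_equal(unname(d["chi.MMMM"]), 4 * chiAu)
  expect_true(all(d[!grepl("\\.MMMM$", names(d))] == 0))

  # larger one-element cloud: every nonzero value = freq * 4 * p(element)
  s2 <- randomCloudStructure(20, seed = 7, elements = "Ag")
  d2 <- nanoDescriptors(s2)
  expect_equal(unname(d2["mass.MMMM"]),
               4 * tbl$mass[tbl$element == "Ag"], tolerance = 1e-12)
})

test_that("mixed-element descriptors equal a brute-force recomputation", {
  s <- randomCloudStructure(8, seed = 8,
                            elements = c("Cd", "Se", "Cd", "Se",
                                         "Cd", "Se", "Cd", "Se"))
  tets <- tessellate(s)
  d <- propertyWeight(s, tets, tetrahedronFrequencies(
    classifyTetrahedra(tets, s)))
  oracle <- bruteDescriptors(s, tets)
  expect_equal(d[names(oracle)], oracle, tolerance = 1e-12)
  expect_length(d, 2142L)
})

test_that("descriptors are invariant under rigid motion", {
  s <- randomCloudStructure(30, seed = 10, elements = c("C", "H", "S", "Au"))
  d0 <- nanoDescriptors(s)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
       rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 7; a$y <- xyz[, 2] - 3; a$z <- xyz[, 3] + 0.5
  s2 <- NanoStructure(a, identifier = structureId(s))
  d1 <- nanoDescriptors(s2)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("descriptors are invariant under uniform scaling", {
  s <- randomCloudStructure(25, seed = 11, elements = c("C", "O", "Zn"))
  d0 <- nanoDescriptors(s)
  for (f in c(1e-3, 12.5)) {
    a <- atoms(s)
    a$x <- a$x * f; a$y <- a$y * f; a$z <- a$z * f
    s2 <- NanoStructure(a, identifier = structureId(s))
    expect_equal(nanoDescriptors(s2), d0, tolerance = 1e-9)
  }
})

test_that("descriptor vectors have 2142 named values and unit frequency sum", {
  d <- nanoDescriptors(buildFullerene())
  expect_length(d, 17L * 126L)
  expect_equal(length(propertyNames()), 17L)
  expect_equal(sum(attr(d, "frequencies")), 1, tolerance = 1e-12)
  expect_true(all(is.finite(d)))
  expect_true(all(grepl("^[a-z_0-9]+\\.[HCNOXM]{4}$", names(d))))
})

test_that("exactly degenerate lattice slabs tessellate deterministically", {
  core <- buildCore(coreSpec("fcc-Au", diameterNm = 1.2))
  t1 <- tessellate(core)
  t2 <- tessellate(core)
  expect_identical(t1, t2)
  expect_gt(nrow(t1), nAtoms(core))  # a real volumetric tessellation
})

test_that("descriptor sets assemble into a SummarizedExperiment", {
  structs <- list(buildFullerene(),
                  buildCore(coreSpec("fcc-Au", diameterNm = 1)),
                  buildCore(coreSpec("zincblende-CdSe", diameterNm = 1.4)))
  se <- descriptorSet(structs)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(2142L, 3L))
  m <- descriptorMatrix(se)
  expect_equal(dim(m), c(3L, 2142L))
  expect_equal(rownames(m), c("C60", "fccAucore", "zincblendeCdSecore"))
})

test_that("zero-variance filtering partitions the descriptor columns", {
  m <- rbind(a = c(1, 0, 5, 3), b = c(1, 1, 5, 4))
  colnames(m) <- paste0("d", 1:4)
  fl <- filterDescriptors(m)
  expect_equal(fl$kept, c("d2", "d4"))
  expect_equal(fl$removed, c("d1", "d3"))
  expect_equal(ncol(fl$matrix) + length(fl$removed), 4L)

  # identical rows: everything removed, with a warning
  expect_warning(fl2 <- filterDescriptors(rbind(m[1, ], m[1, ])), "constant")
  expect_equal(ncol(fl2$matrix), 0L)

  # full descriptor matrices keep kept + removed = 2142
  structs <- list(buildFullerene(), buildCore(coreSpec("fcc-Au", 1)))
  fl3 <- filterDescriptors(descriptorSet(structs))
  expect_equal(length(fl3$kept) + length(fl3$removed), 2142L)
})
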