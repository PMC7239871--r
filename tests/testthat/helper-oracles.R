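# Independent brute-force oracles used across the suite.

# Brute-force Delaunay: enumerate all C(n,4) tetrahedra and keep those whose
# circumsphere contains no other point (strict empty-circumsphere test).
bruteDelaunay <- function(p) {
  n <- nrow(p)
  res <- NULL
  cmb <- utils::combn(n, 4)
  for (ci in seq_len(ncol(cmb))) {
    v <- cmb[, ci]
    A <- 2 * sweep(p[v[2:4], , drop = FALSE], 2, p[v[1], ])
    b <- rowSums(p[v[2:4], , drop = FALSE]^2) - sum(p[v[1], ]^2)
    if (abs(det(A)) < 1e-10) next
    cc <- solve(A, b)
    r2 <- sum((cc - p[v[1], ])^2)
    d2 <- rowSums(sweep(p, 2, cc)^2)
    if (all(d2[-v] > r2 * (1 + 1e-9))) res <- rbind(res, sort(v))
  }
  res[order(res[, 1], res[, 2], res[, 3], res[, 4]), , drop = FALSE]
}

# Brute-force fcc lattice enumeration: all lattice points of an n x n x n
# supercell within a given radius of the origin (a lattice site).
bruteFccCount <- function(a, radius, reach = 5) {
  basis <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5)) * a
  cells <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach)) * a
  count <- 0L
  for (b in seq_len(nrow(basis))) {
    pts <- sweep(cells, 2, -basis[b, ])
    count <- count + sum(rowSums(pts^2) <= radius^2 + 1e-9)
  }
  count
}

# A small random point cloud wrapped as a NanoStructure (general position).
randomCloudStructure <- function(n, seed, elements = "C", spread = 10) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, spread), ncol = 3)
  NanoStructure(data.frame(
    serial = seq_len(n),
    element = rep_len(elements, n),
    name = paste0(rep_len(elements, n), seq_len(n)),
    fragmentId = 0L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    identifier = paste0("cloud", seed))
}

# Direct recomputation of the property-weighting formula from a raw
# tessellation (kept independent of propertyWeight's implementation).
bruteDescriptors <- function(structure, tets) {
  scheme <- atomTypeScheme()
  tbl <- atomicProperties()
  els <- atoms(structure)$element
  clsOrder <- c("H", "C", "N", "O", "X", "M")
  allCls <- tetrahedronClasses()
  props <- propertyNames()
  keys <- apply(tets, 1, function(v) {
    cl <- scheme[els[v]]
    paste(cl[order(match(cl, clsOrder))], collapse = "")
  })
  freq <- table(factor(keys, levels = allCls)) / nrow(tets)
  out <- numeric(0)
  for (p in props) {
    pv <- setNames(tbl[[p]], tbl$element)
    vals <- numeric(length(allCls))
    names(vals) <- allCls
    for (cl in unique(keys)) {
      rows <- which(keys == cl)
      sums <- vapply(rows, function(r) sum(pv[els[tets[r, ]]]), numeric(1))
      vals[cl] <- mean(sums) * freq[[cl]]
    }
    names(vals) <- paste(p, allCls, sep = ".")
    out <- c(out, vals)
  }
  out
}
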