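## Tessellation nanodescriptors: Delaunay tetrahedralization of the atomic
## coordinates, typing of each tetrahedron as an unordered multiset of four
## atom classes (6-letter alphabet -> choose(6+4-1, 4) = 126 fragment
## classes), conversion of occurrences to frequencies, and weighting by the
## 17 atomic properties into a fixed 2142-length descriptor vector.

#' The 126 tetrahedron fragment classes
#'
#' All unordered multisets of size 4 over the six atom-type classes, in
#' canonical (lexicographic by class order H, C, N, O, X, M) naming, e.g.
#' `"HHCC"` or `"XMMM"`.
#'
#' @return Character vector of length 126.
#' @export
tetrahedronClasses <- function() {
  if (!is.null(.nanotessCache$tclasses)) return(.nanotessCache$tclasses)
  cls <- .ATOM_CLASSES
  out <- character(0)
  for (i in 1:6) for (j in i:6) for (k in j:6) for (l in k:6)
    out <- c(out, paste0(cls[i], cls[j], cls[k], cls[l]))
  .nanotessCache$tclasses <- out
  out
}

#' Delaunay tessellation of a structure's atoms
#'
#' Computes the Delaunay tetrahedralization of the atomic coordinates:
#' every returned tetrahedron's circumsphere contains no other atom in its
#' interior.  Exactly degenerate inputs (lattice planes, cospherical
#' shells) are broken by a deterministic relative jitter of 1e-9 times the
#' coordinate extent, keyed to the structure id, so results are
#' reproducible and invariant under uniform scaling.
#'
#' @param structure A [NanoStructure-class], or a numeric n x 3 coordinate
#'   matrix.
#' @param atomBudget Refuse structures larger than this (default 200,000
#'   atoms); reduce the structure size rather than subsample.
#' @param jitter Logical; apply the deterministic degeneracy jitter.
#' @return Integer matrix (m x 4) of 1-based atom indices, rows sorted.
#' @examples
#' tets <- tessellate(buildFullerene())
#' nrow(tets)
#' @export
tessellate <- function(structure, atomBudget = 200000L, jitter = TRUE) {
  xyz <- if (is(structure, "NanoStructure")) coordinates(structure)
         else as.matrix(structure)
  id <- if (is(structure, "NanoStructure")) structure@identifier else "matrix"
  if (nrow(xyz) < 4)
    stop("degenerate geometry: need at least 4 atoms, got ", nrow(xyz))
  if (nrow(xyz) > atomBudget)
    stop("structure has ", nrow(xyz), " atoms, above the tessellation ",
         "budget of ", atomBudget, "; reduce the structure size")
  ctr <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("degenerate geometry: atoms are coplanar or collinear")
  if (jitter) {
    ext <- max(apply(xyz, 2, function(v) diff(range(v))))
    key <- sum(utf8ToInt(id)) %% 100000L + nrow(xyz)
    oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(key))
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, 1e-9 * ext),
                        ncol = 3)
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  }
  tets <- .delaunay_cpp(xyz)
  if (nrow(tets) == 0) stop("degenerate geometry: empty tessellation")
  tets[order(tets[, 1], tets[, 2], tets[, 3], tets[, 4]), , drop = FALSE]
}

#' Classify tetrahedra into the 126 fragment classes
#'
#' @param tets Tetrahedron index matrix from [tessellate()].
#' @param structure The [NanoStructure-class] the indices refer to (or a
#'   character vector of per-atom elements).
#' @param scheme Atom-type scheme from [atomTypeScheme()].
#' @return Named integer vector of occurrence counts over all 126 classes
#'   (unobserved classes are 0); sums to `nrow(tets)`.
#' @export
classifyTetrahedra <- function(tets, structure, scheme = atomTypeScheme()) {
  elements <- if (is.character(structure)) structure
              else atoms(structure)$element
  miss <- setdiff(unique(elements), names(scheme))
  if (length(miss))
    stop("element(s) missing from the atom-type scheme: ",
         paste(miss, collapse = ", "))
  cls <- scheme[elements]
  ord <- match(cls, .ATOM_CLASSES)
  m <- matrix(ord[tets], ncol = 4)
  m <- t(apply(m, 1, sort))
  key <- paste0(.ATOM_CLASSES[m[, 1]], .ATOM_CLASSES[m[, 2]],
                .ATOM_CLASSES[m[, 3]], .ATOM_CLASSES[m[, 4]])
  all <- tetrahedronClasses()
  counts <- table(factor(key, levels = all))
  stats::setNames(as.integer(counts), all)
}

#' Convert tetrahedron occurrences to frequencies
#'
#' Each occurrence count is divided by the total number of tetrahedra in
#' the structure, so the 126 frequencies sum to 1.
#'
#' @param counts Named count vector from [classifyTetrahedra()].
#' @return Named numeric vector of frequencies.
#' @export
tetrahedronFrequencies <- function(counts) {
  tot <- sum(counts)
  if (tot < 1) stop("degenerate geometry: zero tetrahedra")
  counts / tot
}

#' Property-weighted nanodescriptors from a classified tessellation
#'
#' For each of the 17 atomic properties p and each fragment class c, the
#' descriptor value is `frequency(c) * Pbar(p, c)`, where `Pbar(p, c)` is
#' the mean over the tetrahedron instances of class c of the sum of the
#' element-level property over the instance's four vertex atoms.  Classes
#' with frequency 0 get value 0.  The result has length 17 x 126 = 2142,
#' named `<property>.<class>` in property-major order.
#'
#' @param structure [NanoStructure-class] (or element vector).
#' @param tets Tessellation from [tessellate()].
#' @param frequencies From [tetrahedronFrequencies()].
#' @param table Property table, default [atomicProperties()].
#' @param scheme Atom-type scheme.
#' @return Named numeric vector of length 2142.
#' @export
propertyWeight <- function(structure, tets, frequencies,
                           table = atomicProperties(),
                           scheme = atomTypeScheme()) {
  elements <- if (is.character(structure)) structure
              else atoms(structure)$element
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    miss <- unique(elements[is.na(idx)])
    stop("element(s) lacking a property row: ", paste(miss, collapse = ", "))
  }
  props <- propertyNames()
  P <- as.matrix(table[idx, props])          # nAtoms x 17
  tetSum <- P[tets[, 1], , drop = FALSE] + P[tets[, 2], , drop = FALSE] +
            P[tets[, 3], , drop = FALSE] + P[tets[, 4], , drop = FALSE]
  counts <- classifyTetrahedra(tets, elements, scheme)
  cls <- scheme[elements]
  ord <- match(cls, .ATOM_CLASSES)
  m <- t(apply(matrix(ord[tets], ncol = 4), 1, sort))
  key <- paste0(.ATOM_CLASSES[m[, 1]], .ATOM_CLASSES[m[, 2]],
                .ATOM_CLASSES[m[, 3]], .ATOM_CLASSES[m[, 4]])
  allCls <- tetrahedronClasses()
  keyF <- factor(key, levels = allCls)
  out <- numeric(length(props) * length(allCls))
  names(out) <- paste(rep(props, each = length(allCls)),
                      rep(allCls, length(props)), sep = ".")
  for (pi in seq_along(props)) {
    classMean <- tapply(tetSum[, pi], keyF, mean, default = 0)
    classMean[is.na(classMean)] <- 0
    out[(pi - 1) * length(allCls) + seq_along(allCls)] <-
      frequencies * as.numeric(classMean)
  }
  out
}

#' Compute the full nanodescriptor vector of a structure
#'
#' Runs [tessellate()], [classifyTetrahedra()], [tetrahedronFrequencies()]
#' and [propertyWeight()] in sequence.
#'
#' @inheritParams tessellate
#' @param scheme,table Atom-type scheme and property table.
#' @return Named numeric vector of length 2142, with the 126 raw
#'   frequencies attached as attribute `"frequencies"`.
#' @examples
#' d <- nanoDescriptors(buildFullerene())
#' length(d)
#' sum(attr(d, "frequencies"))
#' @export
nanoDescriptors <- function(structure, scheme = atomTypeScheme(),
                            table = atomicProperties(),
                            atomBudget = 200000L) {
  tets <- tessellate(structure, atomBudget = atomBudget)
  counts <- classifyTetrahedra(tets, structure, scheme)
  freq <- tetrahedronFrequencies(counts)
  v <- propertyWeight(structure, tets, freq, table, scheme)
  attr(v, "frequencies") <- freq
  v
}

#' Descriptor matrix for a set of structures
#'
#' @param structures List of [NanoStructure-class] objects.
#' @param ... Passed to [nanoDescriptors()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"descriptors"` (2142 x n), rowData `property`/`tetClass`, and the
#'   126 x n raw frequency matrix as assay `"frequencies"` metadata entry.
#'   Use [descriptorMatrix()] to get the structures x descriptors matrix.
#' @export
descriptorSet <- function(structures, ...) {
  vecs <- lapply(structures, nanoDescriptors, ...)
  ids <- vapply(structures, structureId, character(1))
  mat <- do.call(cbind, vecs)
  colnames(mat) <- ids
  freqs <- do.call(cbind, lapply(vecs, attr, "frequencies"))
  colnames(freqs) <- ids
  allCls <- tetrahedronClasses()
  rd <- S4Vectors::DataFrame(
    property = rep(propertyNames(), each = length(allCls)),
    tetClass = rep(allCls, length(propertyNames())))
  cd <- S4Vectors::DataFrame(
    materialClass = vapply(structures, materialClass, character(1)),
    nAtoms = vapply(structures, nAtoms, integer(1)),
    row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(descriptors = mat),
    rowData = rd, colData = cd,
    metadata = list(frequencies = freqs))
}

#' Structures-by-descriptors matrix from a descriptor set
#'
#' @param x A `SummarizedExperiment` from [descriptorSet()], or a matrix
#'   already in structures x descriptors orientation (returned unchanged).
#' @return Numeric matrix, rows = structure ids, 2142 named columns.
#' @export
descriptorMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(t(SummarizedExperiment::assay(x, "descriptors")))
  as.matrix(x)
}

#' Remove constant (zero-variance) descriptor columns
#'
#' Drops descriptors carrying no information across the given structures;
#' column order is preserved and the kept/removed partition is reported.
#'
#' @param mat Structures x descriptors matrix (>= 2 rows), or a descriptor
#'   set from [descriptorSet()].
#' @param tol Variance threshold; the default 0 removes exactly-constant
#'   columns only.
#' @return List with `matrix` (reduced), `kept` and `removed` column names.
#' @export
filterDescriptors <- function(mat, tol = 0) {
  mat <- descriptorMatrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 structures to filter")
  v <- apply(mat, 2, stats::var)
  keep <- v > tol
  if (!any(keep))
    warning("all descriptor columns are constant; empty matrix returned")
  list(matrix = mat[, keep, drop = FALSE],
       kept = colnames(mat)[keep],
       removed = colnames(mat)[!keep])
}
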