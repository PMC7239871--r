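#' @import methods
#' @include AllGenerics.R
NULL

.MATERIAL_CLASSES <- c("GNP", "AgNP", "PtNP", "PdNP", "CNT", "C60", "QD",
                       "MONP", "DnaNP", "Dendrimer", "CPNT", "unknown")
.SHAPES <- c("sphere", "rod", "tube", "irregular", "unknown")

#' NanoStructure: an annotated atomistic nanomaterial
#'
#' The PDB-serializable unit of the package: an atom table with Cartesian
#' coordinates (Angstrom), an unordered bond list, and the structure-level
#' annotation (material class, shape, declared size in nm, surface-ligand
#' identities).  Core atoms carry `fragmentId` 0; each grafted ligand
#' instance gets its own positive `fragmentId`.
#'
#' @slot identifier Character id, e.g. `"GNP164"`.
#' @slot materialClass One of GNP, AgNP, PtNP, PdNP, CNT, C60, QD, MONP,
#'   DnaNP, Dendrimer, CPNT, or `"unknown"`.
#' @slot shape One of sphere, rod, tube, irregular, or `"unknown"`.
#' @slot sizeNm Numeric; diameter (length 1) or diameter x length (length 2)
#'   in nm.  May be `NA` for imported files without annotation.
#' @slot ligands `data.frame` with columns `smiles` and `count`.
#' @slot atoms `data.frame` with columns `serial` (unique positive integer),
#'   `element`, `name`, `fragmentId`, `x`, `y`, `z`.
#' @slot bonds Integer matrix, columns `a` and `b`: unordered pairs of atom
#'   serials, each pair stored once.
#' @seealso [buildCore()], [writePDB()], [nanoDescriptors()]
#' @export
setClass("NanoStructure",
  representation(
    identifier = "character",
    materialClass = "character",
    shape = "character",
    sizeNm = "numeric",
    ligands = "data.frame",
    atoms = "data.frame",
    bonds = "matrix"
  ),
  prototype(
    identifier = "structure",
    materialClass = "unknown",
    shape = "unknown",
    sizeNm = NA_real_,
    ligands = data.frame(smiles = character(), count = integer()),
    bonds = matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b")))
  )
)

setValidity("NanoStructure", function(object) {
  a <- object@atoms
  msgs <- character()
  need <- c("serial", "element", "name", "fragmentId", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) msgs <- c(msgs, "structure must contain at least one atom")
  if (anyDuplicated(a$serial)) msgs <- c(msgs, "atom serials must be unique")
  if (nrow(a) > 0 && any(a$serial < 1)) msgs <- c(msgs, "atom serials must be positive")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    msgs <- c(msgs, "atom coordinates must be finite")
  bad <- setdiff(unique(a$element), periodicTable()$element)
  if (length(bad))
    msgs <- c(msgs, paste0("unknown element(s): ", paste(bad, collapse = ", ")))
  if (!(object@materialClass %in% .MATERIAL_CLASSES))
    msgs <- c(msgs, paste("materialClass must be one of",
                          paste(.MATERIAL_CLASSES, collapse = ", ")))
  if (!(object@shape %in% .SHAPES))
    msgs <- c(msgs, paste("shape must be one of", paste(.SHAPES, collapse = ", ")))
  b <- object@bonds
  if (ncol(b) != 2L) msgs <- c(msgs, "bonds must have two columns")
  if (nrow(b) > 0) {
    if (any(b[, 1] == b[, 2])) msgs <- c(msgs, "bond endpoints must differ")
    if (!all(c(b) %in% a$serial))
      msgs <- c(msgs, "every bond endpoint must resolve to an atom serial")
    key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bonds")
  }
  lg <- object@ligands
  if (nrow(lg) > 0 && any(lg$count < 0)) msgs <- c(msgs, "ligand counts must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a NanoStructure
#'
#' Low-level constructor; the builders ([buildCore()], [buildCNT()],
#' [buildCPNT()], [graftLigands()]) are the usual entry points.
#'
#' @param atoms `data.frame` with columns `serial`, `element`, `name`,
#'   `fragmentId`, `x`, `y`, `z` (coordinates in Angstrom).  `serial`,
#'   `name` and `fragmentId` are filled in when missing.
#' @param bonds Two-column matrix/data.frame of bonded serial pairs.
#' @param identifier,materialClass,shape,sizeNm,ligands Structure-level
#'   annotation; see [NanoStructure-class].
#' @return A validated [NanoStructure-class] object.
#' @export
NanoStructure <- function(atoms, bonds = NULL, identifier = "structure",
                          materialClass = "unknown", shape = "unknown",
                          sizeNm = NA_real_,
                          ligands = data.frame(smiles = character(),
                                               count = integer())) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$fragmentId)) atoms$fragmentId <- 0L
  atoms$serial <- as.integer(atoms$serial)
  atoms$fragmentId <- as.integer(atoms$fragmentId)
  atoms <- atoms[, c("serial", "element", "name", "fragmentId", "x", "y", "z")]
  rownames(atoms) <- NULL
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- matrix(integer(), ncol = 2)
  } else {
    bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
    storage.mode(bonds) <- "integer"
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    bonds <- unique(bonds)
  }
  colnames(bonds) <- c("a", "b")
  new("NanoStructure", identifier = identifier, materialClass = materialClass,
      shape = shape, sizeNm = as.numeric(sizeNm), ligands = ligands,
      atoms = atoms, bonds = bonds)
}

#' @rdname NanoStructure-accessors
#' @export
setMethod("atoms", "NanoStructure", function(x) x@atoms)

#' @rdname NanoStructure-accessors
#' @export
setMethod("bonds", "NanoStructure", function(x) x@bonds)

#' @rdname NanoStructure-accessors
#' @export
setMethod("nAtoms", "NanoStructure", function(x) nrow(x@atoms))

#' @rdname NanoStructure-accessors
#' @export
setMethod("nBonds", "NanoStructure", function(x) nrow(x@bonds))

#' @rdname NanoStructure-accessors
#' @export
setMethod("materialClass", "NanoStructure", function(x) x@materialClass)

#' @rdname NanoStructure-accessors
#' @export
setMethod("particleShape", "NanoStructure", function(x) x@shape)

#' @rdname NanoStructure-accessors
#' @export
setMethod("sizeNm", "NanoStructure", function(x) x@sizeNm)

#' @rdname NanoStructure-accessors
#' @export
setMethod("structureId", "NanoStructure", function(x) x@identifier)

#' @rdname NanoStructure-accessors
#' @export
setMethod("ligandTable", "NanoStructure", function(x) x@ligands)

setMethod("show", "NanoStructure", function(object) {
  sz <- object@sizeNm
  szTxt <- if (all(is.na(sz))) "size unknown"
           else if (length(sz) == 2) sprintf("%.3g x %.3g nm", sz[1], sz[2])
           else sprintf("%.3g nm", sz[1])
  cat(sprintf("NanoStructure '%s' (%s, %s, %s)\n", object@identifier,
              object@materialClass, object@shape, szTxt))
  comp <- table(object@atoms$element)
  cat(sprintf("  %d atoms (%s), %d bonds\n", nrow(object@atoms),
              paste(sprintf("%s:%d", names(comp), as.integer(comp)),
                    collapse = " "),
              nrow(object@bonds)))
  if (nrow(object@ligands))
    cat(sprintf("  ligands: %s\n",
                paste(sprintf("%s x%d", object@ligands$smiles,
                              object@ligands$count), collapse = ", ")))
  invisible(object)
})

#' Coordinates of a NanoStructure as a matrix
#' @param x A [NanoStructure-class].
#' @return Numeric matrix (nAtoms x 3), Angstrom.
#' @export
coordinates <- function(x) {
  stopifnot(is(x, "NanoStructure"))
  as.matrix(x@atoms[, c("x", "y", "z")])
}

#' Train/test split plan with 5 cross-validation folds
#'
#' @slot seed Integer seed the plan was drawn with.
#' @slot trainIds,testIds Character ids of the 80/20 partition.
#' @slot folds List of 5 character vectors partitioning `trainIds`.
#' @export
setClass("SplitPlan",
  representation(seed = "integer", trainIds = "character",
                 testIds = "character", folds = "list"))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msgs <- c(msgs, "train and test ids overlap")
  fl <- unlist(object@folds)
  if (!setequal(fl, object@trainIds) || anyDuplicated(fl))
    msgs <- c(msgs, "folds must partition the training ids exactly")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d train / %d test (seed %d), folds %s\n",
              length(object@trainIds), length(object@testIds), object@seed,
              paste(lengths(object@folds), collapse = "/")))
  invisible(object)
})

#' Model performance report
#'
#' Holds the four headline statistics of the modeling protocol:
#' `R2_5CV`/`RMSE_5CV` from pooled out-of-fold predictions of the 5-fold
#' cross-validation, and `R2_val`/`RMSE_val` from the external 20% test set
#' predicted by a model refit on the full training set.
#'
#' @slot metrics Named numeric: `R2_5CV`, `RMSE_5CV`, `R2_val`, `RMSE_val`.
#' @slot cvPredictions,valPredictions `data.frame`s with `id`, `observed`,
#'   `predicted` (and `fold` for CV).
#' @slot details List: method, selected descriptors, k, training history,
#'   seeds.
#' @export
setClass("ModelReport",
  representation(metrics = "numeric", cvPredictions = "data.frame",
                 valPredictions = "data.frame", details = "list"))

setMethod("show", "ModelReport", function(object) {
  m <- object@metrics
  cat(sprintf("ModelReport (%s)\n", object@details$method))
  cat(sprintf("  5-fold CV : R2 = %.3f, RMSE = %.3f\n", m["R2_5CV"], m["RMSE_5CV"]))
  cat(sprintf("  external  : R2 = %.3f, RMSE = %.3f\n", m["R2_val"], m["RMSE_val"]))
  invisible(object)
})

#' Extract the metric vector from a ModelReport
#' @param report A [ModelReport-class].
#' @return Named numeric vector with R2_5CV, RMSE_5CV, R2_val, RMSE_val.
#' @export
modelMetrics <- function(report) {
  stopifnot(is(report, "ModelReport"))
  report@metrics
}
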