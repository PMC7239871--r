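#' Accessors for NanoStructure objects
#'
#' `atoms()` returns the atom table (one row per atom: `serial`, `element`,
#' `name`, `fragmentId`, `x`, `y`, `z` in Angstrom), `bonds()` the two-column
#' matrix of bonded atom serials, `nAtoms()`/`nBonds()` the respective counts,
#' `materialClass()` the material class label, `particleShape()` the declared
#' shape and `sizeNm()` the declared dimensions in nanometres.
#'
#' @param x A [NanoStructure-class] object.
#' @return `atoms()` a `data.frame`; `bonds()` an integer matrix with columns
#'   `a`, `b`; the scalar accessors return length-1 (or length-2 for rod
#'   sizes) vectors.
#' @examples
#' au <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
#' nAtoms(au)
#' head(atoms(au))
#' @aliases atoms bonds nAtoms nBonds materialClass particleShape sizeNm
#'   structureId ligandTable
#' @name NanoStructure-accessors
NULL

#' @rdname NanoStructure-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("nBonds", function(x) standardGeneric("nBonds"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("materialClass", function(x) standardGeneric("materialClass"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("particleShape", function(x) standardGeneric("particleShape"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("sizeNm", function(x) standardGeneric("sizeNm"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname NanoStructure-accessors
#' @export
setGeneric("ligandTable", function(x) standardGeneric("ligandTable"))
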