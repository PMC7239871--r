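## Packaged element data: the 17-property table used for descriptor
## weighting, covalent radii for bond perception, and the 6-class atom-type
## alphabet. Values compiled from standard element-data references.

.nanotessCache <- new.env(parent = emptyenv())

.METALS <- c("Na", "Mg", "Al", "Si", "K", "Ca", "Ti", "Fe", "Co", "Cu", "Zn",
             "Zr", "Pd", "Ag", "Cd", "La", "Ce", "Pt", "Au")
.OTHER_NONMETALS <- c("F", "P", "S", "Cl", "Se", "Br", "I")

#' The packaged atomic property table
#'
#' Seventeen physical properties per element, used to weight tetrahedron
#' frequencies into nanodescriptors: calculated, covalent and empirical
#' radii (pm); atomic mass (u); boiling and melting points (K); density
#' (g/cm^3); electron affinity, heat of fusion, heat of vaporization, first
#' and second ionization energies (kJ/mol); Pauling electronegativity; molar
#' volume (cm^3/mol); specific heat (J/(g K)); thermal conductivity
#' (W/(m K)); and common valence.  Electron affinities that are not bound
#' states (N, Mg, Zn, Cd) and the second ionization energy of H are recorded
#' as 0.
#'
#' @return `data.frame` with one row per supported element and 17 numeric
#'   property columns.
#' @examples
#' props <- atomicProperties()
#' ncol(props) - 1L  # 17 properties
#' @export
atomicProperties <- function() {
  if (is.null(.nanotessCache$props)) {
    path <- system.file("extdata", "atomic_properties.csv", package = "nanotess")
    .nanotessCache$props <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .nanotessCache$props
}

#' Names of the 17 atomic properties
#' @return Character vector of length 17, in descriptor-naming order.
#' @export
propertyNames <- function() setdiff(names(atomicProperties()), "element")

#' The packaged periodic table
#'
#' Element symbols recognized by the package, with covalent radii (Angstrom)
#' for distance-based bond perception and the assigned atom-type class.
#'
#' @return `data.frame` with columns `element`, `covalentRadius` (Angstrom),
#'   `class`.
#' @export
periodicTable <- function() {
  if (is.null(.nanotessCache$ptable)) {
    p <- atomicProperties()
    .nanotessCache$ptable <- data.frame(
      element = p$element,
      covalentRadius = p$r_cov / 100,  # pm -> Angstrom
      class = vapply(p$element, .elementClass, character(1)),
      stringsAsFactors = FALSE
    )
  }
  .nanotessCache$ptable
}

.elementClass <- function(el) {
  if (el %in% c("H", "C", "N", "O")) return(el)
  if (el %in% .OTHER_NONMETALS) return("X")
  if (el %in% .METALS) return("M")
  stop("element '", el, "' not in the packaged periodic table")
}

#' The six-class atom-type alphabet
#'
#' Maps every supported element to one of six atom-type classes: `H`, `C`,
#' `N`, `O`, `X` (other nonmetal: S, P, Se and the halogens) and `M`
#' (metal/metalloid).  Four-vertex multisets over this alphabet give the
#' choose(6+4-1, 4) = 126 tetrahedron fragment classes.  The mapping can be
#' overridden entry-wise.
#'
#' @param overrides Optional named character vector, e.g.
#'   `c(Se = "M")`, reassigning elements to classes.
#' @return Named character vector element -> class.
#' @examples
#' scheme <- atomTypeScheme()
#' table(scheme)
#' @export
atomTypeScheme <- function(overrides = NULL) {
  pt <- periodicTable()
  scheme <- stats::setNames(pt$class, pt$element)
  if (!is.null(overrides)) {
    bad <- setdiff(overrides, .ATOM_CLASSES)
    if (length(bad)) stop("unknown atom class(es): ", paste(bad, collapse = ", "))
    scheme[names(overrides)] <- overrides
  }
  scheme
}

.ATOM_CLASSES <- c("H", "C", "N", "O", "X", "M")

#' Covalent radius lookup
#' @param elements Character vector of element symbols.
#' @return Numeric vector of covalent radii in Angstrom.
#' @export
covalentRadius <- function(elements) {
  pt <- periodicTable()
  r <- pt$covalentRadius[match(elements, pt$element)]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  r
}

## standard valences used when hydrogen-filling built residue templates
.STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)
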