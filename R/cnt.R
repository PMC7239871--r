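## Carbon nanotubes by the standard graphene roll-up construction, and
## buckminsterfullerene from the exact truncated-icosahedron geometry.

.GRAPHENE_A <- 2.46  # graphene lattice constant, Angstrom

#' Declare a carbon nanotube
#'
#' @param n,m Chiral indices; non-negative integers with `n >= m`,
#'   `n >= 1`.
#' @param lengthNm Tube length in nm.
#' @return A `CNTSpec` list for [buildCNT()].
#' @export
cntSpec <- function(n, m, lengthNm) {
  if (n == 0 && m == 0) stop("invalid chirality: (n, m) = (0, 0)")
  if (n < 1 || m < 0 || m > n)
    stop("chiral indices must satisfy n >= m >= 0, n >= 1")
  if (lengthNm <= 0) stop("length must be positive")
  structure(list(n = as.integer(n), m = as.integer(m), lengthNm = lengthNm),
            class = "CNTSpec")
}

#' Roll-up diameter of a carbon nanotube
#'
#' `d = a * sqrt(n^2 + n*m + m^2) / pi` with the graphene lattice constant
#' `a = 2.46` Angstrom.
#'
#' @param n,m Chiral indices.
#' @return Diameter in Angstrom.
#' @export
cntDiameter <- function(n, m) .GRAPHENE_A * sqrt(n^2 + n * m + m^2) / pi

#' Build a pristine carbon nanotube
#'
#' Generates the graphene lattice in the (chiral vector, translation
#' vector) frame and wraps it onto a cylinder: an atom at fractional
#' position `s` along the chiral vector and height `t` maps to angle
#' `2*pi*s` at radius `d/2`.  All atoms are carbon and lie exactly on the
#' common cylinder; C-C bonds are assigned by the 1.2 x covalent-radii
#' distance cutoff.
#'
#' @param spec A [cntSpec()].
#' @param identifier Structure id.
#' @return A [NanoStructure-class] (materialClass `"CNT"`, shape `"tube"`).
#' @examples
#' cnt <- buildCNT(cntSpec(5, 5, lengthNm = 0.246))
#' sizeNm(cnt)
#' @export
buildCNT <- function(spec, identifier = "CNT") {
  stopifnot(inherits(spec, "CNTSpec"))
  n <- spec$n; m <- spec$m
  a <- .GRAPHENE_A
  a1 <- a * c(sqrt(3) / 2, 1 / 2)
  a2 <- a * c(sqrt(3) / 2, -1 / 2)
  Ch <- n * a1 + m * a2
  L <- sqrt(sum(Ch^2))
  diam <- L / pi
  lenAng <- spec$lengthNm * 10
  Tdir <- c(-Ch[2], Ch[1]) / L  # unit vector along the tube axis

  ## enumerate graphene cells covering the strip [0,L) x [0,lenAng]
  basis <- rbind(c(0, 0), (a1 + a2) / 3)
  rng <- ceiling((L + lenAng) / a) + 2
  ij <- as.matrix(expand.grid(-rng:rng, -rng:rng))
  pts <- NULL
  for (b in 1:2) {
    p <- cbind(ij[, 1] * a1[1] + ij[, 2] * a2[1] + basis[b, 1],
               ij[, 1] * a1[2] + ij[, 2] * a2[2] + basis[b, 2])
    pts <- rbind(pts, p)
  }
  s <- (pts[, 1] * Ch[1] + pts[, 2] * Ch[2]) / L^2     # fraction along Ch
  t <- pts[, 1] * Tdir[1] + pts[, 2] * Tdir[2]         # axial position
  eps <- 1e-6
  keep <- s >= -eps & s < 1 - eps & t >= -eps & t <= lenAng + eps
  s <- s[keep]; t <- t[keep]
  if (!length(s)) stop("tube too short: no atoms generated")
  theta <- 2 * pi * s
  xyz <- cbind(diam / 2 * cos(theta), diam / 2 * sin(theta), t)
  atomsDf <- data.frame(serial = seq_len(nrow(xyz)), element = "C",
                        name = paste0("C", seq_len(nrow(xyz))),
                        fragmentId = 0L,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bonds <- perceiveBonds(atomsDf)
  NanoStructure(atomsDf, bonds, identifier = identifier,
                materialClass = "CNT", shape = "tube",
                sizeNm = c(diam / 10, spec$lengthNm))
}

#' Build buckminsterfullerene (C60)
#'
#' Exact truncated-icosahedron vertex coordinates (the cyclic permutations
#' of `(0, +/-1, +/-3*phi)`, `(+/-1, +/-(2+phi), +/-2*phi)` and
#' `(+/-2, +/-(1+2*phi), +/-phi)` with the golden ratio `phi`), scaled so
#' every cage edge is a 1.42 Angstrom C-C bond.  Bond perception yields the
#' 90 cage bonds.
#'
#' @param identifier Structure id.
#' @return A [NanoStructure-class] with 60 C atoms and 90 bonds.
#' @export
buildFullerene <- function(identifier = "C60") {
  phi <- (1 + sqrt(5)) / 2
  base <- rbind(
    cbind(0, c(1, 1, -1, -1), 3 * phi * c(1, -1, 1, -1)),
    as.matrix(expand.grid(c(1, -1), (2 + phi) * c(1, -1),
                          2 * phi * c(1, -1))),
    as.matrix(expand.grid(c(2, -2), (1 + 2 * phi) * c(1, -1),
                          phi * c(1, -1)))
  )
  cyc <- function(p) p[, c(2, 3, 1), drop = FALSE]
  v <- rbind(base, cyc(base), cyc(cyc(base)))
  v <- v * (1.42 / 2)  # edge length 2 in the reference polyhedron
  atomsDf <- data.frame(serial = 1:60, element = "C",
                        name = paste0("C", 1:60), fragmentId = 0L,
                        x = v[, 1], y = v[, 2], z = v[, 3])
  bonds <- perceiveBonds(atomsDf)
  NanoStructure(atomsDf, bonds, identifier = identifier,
                materialClass = "C60", shape = "sphere",
                sizeNm = 2 * sqrt(sum(v[1, ]^2)) / 10)
}
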