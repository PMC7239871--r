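## Crystalline-core construction: replicate the registered unit cell of the
## material and delete atoms outside the target solid (sphere, or cylinder
## with hemispherical caps for rods).

.LATTICES <- list(
  "fcc-Au" = list(a = 4.078, b = 4.078, c = 4.078, alpha = 90, beta = 90,
    gamma = 90, materialClass = "GNP", bulkCoordination = 12,
    sites = data.frame(element = "Au",
      fx = c(0, .5, .5, 0), fy = c(0, .5, 0, .5), fz = c(0, 0, .5, .5))),
  "fcc-Ag" = list(a = 4.085, b = 4.085, c = 4.085, alpha = 90, beta = 90,
    gamma = 90, materialClass = "AgNP", bulkCoordination = 12,
    sites = data.frame(element = "Ag",
      fx = c(0, .5, .5, 0), fy = c(0, .5, 0, .5), fz = c(0, 0, .5, .5))),
  "fcc-Pt" = list(a = 3.924, b = 3.924, c = 3.924, alpha = 90, beta = 90,
    gamma = 90, materialClass = "PtNP", bulkCoordination = 12,
    sites = data.frame(element = "Pt",
      fx = c(0, .5, .5, 0), fy = c(0, .5, 0, .5), fz = c(0, 0, .5, .5))),
  "fcc-Pd" = list(a = 3.891, b = 3.891, c = 3.891, alpha = 90, beta = 90,
    gamma = 90, materialClass = "PdNP", bulkCoordination = 12,
    sites = data.frame(element = "Pd",
      fx = c(0, .5, .5, 0), fy = c(0, .5, 0, .5), fz = c(0, 0, .5, .5))),
  "zincblende-CdSe" = list(a = 6.052, b = 6.052, c = 6.052, alpha = 90,
    beta = 90, gamma = 90, materialClass = "QD", bulkCoordination = 4,
    sites = data.frame(
      element = c(rep("Cd", 4), rep("Se", 4)),
      fx = c(0, .5, .5, 0, .25, .75, .75, .25),
      fy = c(0, .5, 0, .5, .25, .75, .25, .75),
      fz = c(0, 0, .5, .5, .25, .25, .75, .75))),
  "zincblende-CdS" = list(a = 5.832, b = 5.832, c = 5.832, alpha = 90,
    beta = 90, gamma = 90, materialClass = "QD", bulkCoordination = 4,
    sites = data.frame(
      element = c(rep("Cd", 4), rep("S", 4)),
      fx = c(0, .5, .5, 0, .25, .75, .75, .25),
      fy = c(0, .5, 0, .5, .25, .75, .25, .75),
      fz = c(0, 0, .5, .5, .25, .25, .75, .75))),
  "rutile-TiO2" = list(a = 4.594, b = 4.594, c = 2.959, alpha = 90, beta = 90,
    gamma = 90, materialClass = "MONP", bulkCoordination = 6,
    sites = data.frame(
      element = c("Ti", "Ti", "O", "O", "O", "O"),
      fx = c(0, .5, .3053, .6947, .8053, .1947),
      fy = c(0, .5, .3053, .6947, .1947, .8053),
      fz = c(0, .5, 0, 0, .5, .5))),
  "wurtzite-ZnO" = list(a = 3.250, b = 3.250, c = 5.207, alpha = 90,
    beta = 90, gamma = 120, materialClass = "MONP", bulkCoordination = 4,
    sites = data.frame(
      element = c("Zn", "Zn", "O", "O"),
      fx = c(1/3, 2/3, 1/3, 2/3), fy = c(2/3, 1/3, 2/3, 1/3),
      fz = c(0, .5, .3825, .8825))),
  "fluorite-CeO2" = list(a = 5.411, b = 5.411, c = 5.411, alpha = 90,
    beta = 90, gamma = 90, materialClass = "MONP", bulkCoordination = 8,
    sites = data.frame(
      element = c(rep("Ce", 4), rep("O", 8)),
      fx = c(0, .5, .5, 0, .25, .25, .25, .75, .25, .75, .75, .75),
      fy = c(0, .5, 0, .5, .25, .25, .75, .25, .75, .25, .75, .75),
      fz = c(0, 0, .5, .5, .25, .75, .25, .25, .75, .75, .25, .75)))
)

#' The packaged lattice registry
#'
#' Default unit-cell parameters (standard crystallographic references) for
#' the crystalline cores the builder supports: fcc Au/Ag/Pt/Pd, zincblende
#' CdSe/CdS, rutile TiO2, wurtzite ZnO and fluorite CeO2.  Each entry holds
#' cell lengths (Angstrom), cell angles (degrees), fractional atom sites,
#' the bulk coordination number (used for surface-site detection) and the
#' default material class.
#'
#' @param material Optional registry key; omitted, the whole registry list
#'   is returned.
#' @return A list (one entry) or the named registry list.
#' @export
latticeRegistry <- function(material = NULL) {
  if (is.null(material)) return(.LATTICES)
  if (!material %in% names(.LATTICES))
    stop("unknown material key '", material, "'; registered: ",
         paste(names(.LATTICES), collapse = ", "))
  .LATTICES[[material]]
}

#' Declare a crystalline core
#'
#' @param material Registry key, e.g. `"fcc-Au"` (see [latticeRegistry()]),
#'   or a full lattice definition list of the same shape to override the
#'   registry.
#' @param shape `"sphere"` or `"rod"`.
#' @param diameterNm Sphere (or rod) diameter in nm.
#' @param lengthNm Total rod length in nm (tip to tip, hemispherical caps
#'   included); required for rods.
#' @return A `CoreSpec` list consumed by [buildCore()].
#' @export
coreSpec <- function(material, diameterNm, shape = c("sphere", "rod"),
                     lengthNm = NULL) {
  shape <- match.arg(shape)
  lattice <- if (is.list(material)) material else latticeRegistry(material)
  if (any(c(lattice$alpha, lattice$beta, lattice$gamma) <= 0) ||
      any(c(lattice$alpha, lattice$beta, lattice$gamma) >= 180))
    stop("lattice angles must lie in (0, 180) degrees")
  if (nrow(lattice$sites) < 1) stop("lattice needs at least one site per cell")
  if (diameterNm <= 0) stop("diameter must be positive")
  if (shape == "rod") {
    if (is.null(lengthNm) || lengthNm < diameterNm)
      stop("rod length (nm) must be given and >= diameter")
  }
  structure(list(material = if (is.list(material)) "custom" else material,
                 lattice = lattice, shape = shape, diameterNm = diameterNm,
                 lengthNm = lengthNm),
            class = "CoreSpec")
}

## cell vectors (rows) from lengths/angles, standard triclinic convention
.cellVectors <- function(l) {
  ca <- cos(l$alpha * pi / 180); cb <- cos(l$beta * pi / 180)
  cg <- cos(l$gamma * pi / 180); sg <- sin(l$gamma * pi / 180)
  v1 <- c(l$a, 0, 0)
  v2 <- c(l$b * cg, l$b * sg, 0)
  cx <- l$c * cb
  cy <- l$c * (ca - cb * cg) / sg
  cz <- sqrt(max(l$c^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz))
}

## minimum distance between lattice sites (nearest-neighbour distance)
.minSiteSeparation <- function(lattice) {
  V <- .cellVectors(lattice)
  fr <- as.matrix(lattice$sites[, c("fx", "fy", "fz")])
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  pts <- (do.call(rbind, lapply(seq_len(nrow(sh)), function(i)
    sweep(fr, 2, -as.numeric(sh[i, ])))) %*% V)
  d <- stats::dist(pts)
  min(d[d > 1e-9])
}

#' Build a crystalline nanoparticle core
#'
#' Replicates the unit cell of the requested lattice into a supercell and
#' deletes every site whose position falls outside the target solid: a
#' sphere of the given diameter, or for rods a cylinder with hemispherical
#' caps whose declared dimensions are diameter x total length.  The carved
#' core is centred on a lattice point so that the result is an exact subset
#' of the infinite lattice.
#'
#' @param spec A [coreSpec()].
#' @param withBonds Emit distance-cutoff connectivity records (1.2 x sum of
#'   covalent radii)?  Off by default: metal-metal connectivity is not
#'   stored.
#' @param identifier Structure id.
#' @return A [NanoStructure-class] whose atoms are exactly the lattice
#'   points of the replicated cell inside the solid.
#' @examples
#' au <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
#' nAtoms(au)
#' @export
buildCore <- function(spec, withBonds = FALSE, identifier = NULL) {
  stopifnot(inherits(spec, "CoreSpec"))
  lat <- spec$lattice
  V <- .cellVectors(lat)
  dAng <- spec$diameterNm * 10
  nn <- .minSiteSeparation(lat)
  if (dAng < nn)
    stop("core too small: diameter ", dAng,
         " Angstrom is below the nearest-neighbour distance ",
         signif(nn, 4), " Angstrom")
  R <- dAng / 2
  halfLen <- if (spec$shape == "rod") spec$lengthNm * 10 / 2 else R

  ## replication range: cover the solid plus one cell margin, using the
  ## perpendicular inter-plane distances of the cell
  Vinv <- solve(V)
  reach <- max(halfLen, R) + max(lat$a, lat$b, lat$c)
  nrep <- ceiling(reach * sqrt(colSums(Vinv^2)))
  grid <- as.matrix(expand.grid(-nrep[1]:nrep[1], -nrep[2]:nrep[2],
                                -nrep[3]:nrep[3]))
  fr <- as.matrix(lat$sites[, c("fx", "fy", "fz")])
  cellXYZ <- fr %*% V
  nS <- nrow(fr)
  origin <- grid %*% V
  xyz <- matrix(0, nrow(grid) * nS, 3)
  el <- character(nrow(grid) * nS)
  for (s in seq_len(nS)) {
    idx <- seq(s, by = nS, length.out = nrow(grid))
    xyz[idx, ] <- sweep(origin, 2, -cellXYZ[s, ])
    el[idx] <- lat$sites$element[s]
  }
  keep <- if (spec$shape == "sphere") {
    rowSums(xyz^2) <= R^2 + 1e-9
  } else {
    z0 <- halfLen - R  # cap centres at +/- z0 on the rod axis
    rho2 <- xyz[, 1]^2 + xyz[, 2]^2
    inCyl <- abs(xyz[, 3]) <= z0 + 1e-9 & rho2 <= R^2 + 1e-9
    inCap <- rho2 + (abs(xyz[, 3]) - z0)^2 <= R^2 + 1e-9 & abs(xyz[, 3]) > z0
    inCyl | inCap
  }
  xyz <- xyz[keep, , drop = FALSE]
  el <- el[keep]
  if (nrow(xyz) == 0) stop("core too small: no lattice points inside solid")

  atomsDf <- data.frame(serial = seq_len(nrow(xyz)), element = el,
                        name = paste0(el, seq_len(nrow(xyz))),
                        fragmentId = 0L,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bonds <- if (withBonds) perceiveBonds(atomsDf) else NULL
  sz <- if (spec$shape == "rod") c(spec$diameterNm, spec$lengthNm)
        else spec$diameterNm
  if (is.null(identifier))
    identifier <- paste0(gsub("[^A-Za-z0-9]", "", spec$material), "core")
  NanoStructure(atomsDf, bonds, identifier = identifier,
                materialClass = lat$materialClass, shape = spec$shape,
                sizeNm = sz)
}

#' Distance-cutoff bond perception
#'
#' Bonds every atom pair closer than `factor` times the sum of their
#' covalent radii (default 1.2).
#'
#' @param atomsDf Atom `data.frame` with `element`, `x`, `y`, `z`.
#' @param factor Cutoff multiplier.
#' @return Two-column matrix of bonded atom serials.
#' @export
perceiveBonds <- function(atomsDf, factor = 1.2) {
  n <- nrow(atomsDf)
  if (n < 2) return(NULL)
  r <- covalentRadius(atomsDf$element)
  xyz <- as.matrix(atomsDf[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cut <- factor * outer(r, r, "+")
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  serial <- if (is.null(atomsDf$serial)) seq_len(n) else atomsDf$serial
  cbind(a = serial[hit[, 1]], b = serial[hit[, 2]])
}
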