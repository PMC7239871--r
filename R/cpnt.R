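## Cyclic-peptide nanotubes: residues joined head-to-tail into a closed
## ring, rings stacked along the tube axis at the beta-sheet-like 4.8 A
## spacing with alternate rings flipped.  Geometry is an idealized template
## model (planar backbone ring, side chains grown radially); hydrogen bonds
## between rings are implied by the stacking, not stored as bonds.

.RING_SPACING <- 4.8  # inter-ring axial spacing, Angstrom

## side-chain templates: heavy atoms as a parent tree rooted at CA
## (parent 0 = CA), explicit hydrogen counts, optional ring-closure bonds
.SIDECHAINS <- list(
  G = list(atoms = NULL, closures = NULL),
  A = list(atoms = data.frame(name = "CB", element = "C", parent = 0, nH = 3)),
  S = list(atoms = data.frame(name = c("CB", "OG"), element = c("C", "O"),
                              parent = c(0, 1), nH = c(2, 1))),
  C = list(atoms = data.frame(name = c("CB", "SG"), element = c("C", "S"),
                              parent = c(0, 1), nH = c(2, 1))),
  T = list(atoms = data.frame(name = c("CB", "OG1", "CG2"),
                              element = c("C", "O", "C"),
                              parent = c(0, 1, 1), nH = c(1, 1, 3))),
  V = list(atoms = data.frame(name = c("CB", "CG1", "CG2"),
                              element = c("C", "C", "C"),
                              parent = c(0, 1, 1), nH = c(1, 3, 3))),
  L = list(atoms = data.frame(name = c("CB", "CG", "CD1", "CD2"),
                              element = "C", parent = c(0, 1, 2, 2),
                              nH = c(2, 1, 3, 3))),
  I = list(atoms = data.frame(name = c("CB", "CG1", "CG2", "CD1"),
                              element = "C", parent = c(0, 1, 1, 2),
                              nH = c(1, 2, 3, 3))),
  M = list(atoms = data.frame(name = c("CB", "CG", "SD", "CE"),
                              element = c("C", "C", "S", "C"),
                              parent = c(0, 1, 2, 3), nH = c(2, 2, 0, 3))),
  P = list(atoms = data.frame(name = c("CB", "CG", "CD"), element = "C",
                              parent = c(0, 1, 2), nH = c(2, 2, 2)),
           closures = "CD-N"),
  F = list(atoms = data.frame(
             name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             element = "C", parent = c(0, 1, 2, 2, 3, 4, 5),
             nH = c(2, 0, 1, 1, 1, 1, 1)),
           closures = "CZ-CE2"),
  Y = list(atoms = data.frame(
             name = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
             element = c(rep("C", 7), "O"), parent = c(0, 1, 2, 2, 3, 4, 5, 7),
             nH = c(2, 0, 1, 1, 1, 1, 0, 1)),
           closures = "CZ-CE2"),
  W = list(atoms = data.frame(
             name = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ3",
                      "CH2", "CZ2"),
             element = c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
             parent = c(0, 1, 2, 2, 3, 5, 4, 7, 8, 9),
             nH = c(2, 0, 1, 0, 1, 0, 1, 1, 1, 1)),
           closures = c("CE2-CD2", "CZ2-CE2")),
  D = list(atoms = data.frame(name = c("CB", "CG", "OD1", "OD2"),
                              element = c("C", "C", "O", "O"),
                              parent = c(0, 1, 2, 2), nH = c(2, 0, 0, 1))),
  E = list(atoms = data.frame(name = c("CB", "CG", "CD", "OE1", "OE2"),
                              element = c("C", "C", "C", "O", "O"),
                              parent = c(0, 1, 2, 3, 3), nH = c(2, 2, 0, 0, 1))),
  N = list(atoms = data.frame(name = c("CB", "CG", "OD1", "ND2"),
                              element = c("C", "C", "O", "N"),
                              parent = c(0, 1, 2, 2), nH = c(2, 0, 0, 2))),
  Q = list(atoms = data.frame(name = c("CB", "CG", "CD", "OE1", "NE2"),
                              element = c("C", "C", "C", "O", "N"),
                              parent = c(0, 1, 2, 3, 3), nH = c(2, 2, 0, 0, 2))),
  K = list(atoms = data.frame(name = c("CB", "CG", "CD", "CE", "NZ"),
                              element = c("C", "C", "C", "C", "N"),
                              parent = c(0, 1, 2, 3, 4), nH = c(2, 2, 2, 2, 2))),
  R = list(atoms = data.frame(name = c("CB", "CG", "CD", "NE", "CZ", "NH1",
                                       "NH2"),
                              element = c("C", "C", "C", "N", "C", "N", "N"),
                              parent = c(0, 1, 2, 3, 4, 5, 5),
                              nH = c(2, 2, 2, 1, 0, 2, 2))),
  H = list(atoms = data.frame(name = c("CB", "CG", "ND1", "CD2", "CE1",
                                       "NE2"),
                              element = c("C", "C", "N", "C", "C", "N"),
                              parent = c(0, 1, 2, 2, 3, 4),
                              nH = c(2, 0, 1, 1, 1, 0)),
           closures = "CE1-NE2")
)

.AA3TO1 <- c(GLY = "G", ALA = "A", SER = "S", CYS = "C", THR = "T",
             VAL = "V", LEU = "L", ILE = "I", MET = "M", PRO = "P",
             PHE = "F", TYR = "Y", TRP = "W", ASP = "D", GLU = "E",
             ASN = "N", GLN = "Q", LYS = "K", ARG = "R", HIS = "H")

#' Declare a cyclic-peptide nanotube
#'
#' @param sequence Residues of one ring: a single-letter string
#'   (`"AGAGAGAG"`), or a vector of one- or three-letter codes.  At least
#'   3 residues.
#' @param ringCount Number of stacked rings (>= 1).
#' @return A `CPNTSpec` list for [buildCPNT()].
#' @export
cpntSpec <- function(sequence, ringCount = 1L) {
  if (length(sequence) == 1 && nchar(sequence) > 3 ||
      (length(sequence) == 1 && nchar(sequence) <= 3 &&
       !toupper(sequence) %in% names(.AA3TO1)))
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  long <- nchar(sequence) == 3
  sequence[long] <- .AA3TO1[sequence[long]]
  bad <- is.na(sequence) | !sequence %in% names(.SIDECHAINS)
  if (any(bad)) stop("unknown residue code(s): ",
                     paste(unique(sequence[bad]), collapse = ", "))
  if (length(sequence) < 3) stop("ring needs at least 3 residues")
  if (ringCount < 1) stop("ringCount must be >= 1")
  structure(list(sequence = sequence, ringCount = as.integer(ringCount)),
            class = "CPNTSpec")
}

## one ring of the cyclic peptide as an atom table + intra-ring bonds
.buildRing <- function(sequence) {
  R <- length(sequence)
  nb <- 3 * R  # backbone ring atoms: N, CA, C per residue
  rb <- nb * 1.45 / (2 * pi)  # backbone bond ~1.45 A along the ring
  ang <- 2 * pi * (seq_len(nb) - 1) / nb
  atomsL <- list(); bondsL <- list(); serial <- 0L
  backboneSerial <- matrix(0L, R, 3)  # N, CA, C
  addAtom <- function(name, element, x, y, z, res) {
    serial <<- serial + 1L
    atomsL[[length(atomsL) + 1L]] <<- data.frame(
      serial = serial, element = element,
      name = paste0(name, "_", res), fragmentId = 0L, x = x, y = y, z = z)
    serial
  }
  for (r in seq_len(R)) {
    code <- sequence[r]
    zO <- 1.23 * (-1)^r   # carbonyl O alternates up/down around the ring
    for (j in 1:3) {
      i <- 3 * (r - 1) + j
      el <- if (j == 1) "N" else "C"
      nm <- c("N", "CA", "C")[j]
      backboneSerial[r, j] <- addAtom(nm, el, rb * cos(ang[i]),
                                      rb * sin(ang[i]), 0, r)
    }
    ## carbonyl O axially off the C atom
    iC <- 3 * (r - 1) + 3
    addAtom("O", "O", rb * cos(ang[iC]), rb * sin(ang[iC]), zO, r)
    bondsL[[length(bondsL) + 1L]] <- cbind(backboneSerial[r, 3], serial)
    ## amide H (absent for proline) opposite the carbonyl
    iN <- 3 * (r - 1) + 1
    if (code != "P") {
      addAtom("HN", "H", rb * cos(ang[iN]), rb * sin(ang[iN]), -zO * 0.82, r)
      bondsL[[length(bondsL) + 1L]] <- cbind(backboneSerial[r, 1], serial)
    }
    ## CA hydrogens (2 for glycine) point inward
    iA <- 3 * (r - 1) + 2
    nHA <- if (code == "G") 2 else 1
    for (h in seq_len(nHA)) {
      addAtom("HA", "H", (rb - 1.0) * cos(ang[iA]), (rb - 1.0) * sin(ang[iA]),
              0.45 * (-1)^(r + h) * h, r)
      bondsL[[length(bondsL) + 1L]] <- cbind(backboneSerial[r, 2], serial)
    }
    ## side chain grown radially outward from CA
    sc <- .SIDECHAINS[[code]]
    if (!is.null(sc$atoms)) {
      scSerial <- integer(nrow(sc$atoms))
      dirR <- c(cos(ang[iA]), sin(ang[iA]))
      depth <- integer(nrow(sc$atoms))
      for (k in seq_len(nrow(sc$atoms))) {
        par <- sc$atoms$parent[k]
        parSerial <- if (par == 0) backboneSerial[r, 2] else scSerial[par]
        depth[k] <- if (par == 0) 1L else depth[par] + 1L
        parRow <- atomsL[[parSerial]]
        blen <- sum(covalentRadius(c(sc$atoms$element[k],
                                     parRow$element)))
        ## zig-zag outward; siblings separated axially
        sib <- sum(sc$atoms$parent[seq_len(k)] == par)
        dz <- 0.55 * (-1)^depth[k] + 0.9 * (sib - 1)
        step <- blen / sqrt(1 + dz^2)
        scSerial[k] <- addAtom(sc$atoms$name[k], sc$atoms$element[k],
                               parRow$x + step * dirR[1],
                               parRow$y + step * dirR[2],
                               parRow$z + step * dz, r)
        bondsL[[length(bondsL) + 1L]] <- cbind(parSerial, scSerial[k])
        for (h in seq_len(sc$atoms$nH[k])) {
          hlen <- sum(covalentRadius(c("H", sc$atoms$element[k])))
          hz <- 0.8 * ifelse(h %% 2 == 0, 1, -1) * ceiling(h / 2)
          hstep <- hlen / sqrt(1 + hz^2)
          hs <- addAtom("H", "H",
                        atomsL[[scSerial[k]]]$x + hstep * dirR[1] * 0.9 -
                          0.35 * h * dirR[2],
                        atomsL[[scSerial[k]]]$y + hstep * dirR[2] * 0.9 +
                          0.35 * h * dirR[1],
                        atomsL[[scSerial[k]]]$z + hstep * hz, r)
          bondsL[[length(bondsL) + 1L]] <- cbind(scSerial[k], hs)
        }
      }
      for (cl in sc$closures) {
        ends <- strsplit(cl, "-")[[1]]
        s1 <- scSerial[match(ends[1], sc$atoms$name)]
        s2 <- if (ends[2] == "N") backboneSerial[r, 1]
              else scSerial[match(ends[2], sc$atoms$name)]
        bondsL[[length(bondsL) + 1L]] <- cbind(s1, s2)
      }
    }
  }
  ## backbone ring bonds: N-CA, CA-C within residues, C-N peptide links
  for (r in seq_len(R)) {
    bondsL[[length(bondsL) + 1L]] <-
      rbind(backboneSerial[r, c(1, 2)], backboneSerial[r, c(2, 3)],
            c(backboneSerial[r, 3], backboneSerial[r %% R + 1, 1]))
  }
  list(atoms = do.call(rbind, atomsL), bonds = do.call(rbind, bondsL),
       backboneSerial = backboneSerial)
}

#' Build a cyclic-peptide nanotube
#'
#' Joins the residues of one ring head-to-tail through peptide bonds (the
#' backbone closure gives exactly one C->N link per residue) and stacks
#' `ringCount` copies along the z axis at 4.8 Angstrom spacing, with
#' alternate rings flipped (antiparallel, beta-sheet-like stacking).
#' Inter-ring hydrogen bonds are implied by the geometry and not stored.
#'
#' @param spec A [cpntSpec()].
#' @param identifier Structure id.
#' @return A [NanoStructure-class] (materialClass `"CPNT"`).
#' @examples
#' tube <- buildCPNT(cpntSpec("AGAGAGAG", ringCount = 3))
#' nAtoms(tube)
#' @export
buildCPNT <- function(spec, identifier = "CPNT") {
  stopifnot(inherits(spec, "CPNTSpec"))
  ring <- .buildRing(spec$sequence)
  nR <- nrow(ring$atoms)
  halfTurn <- pi / (3 * length(spec$sequence))
  atomsL <- list(); bondsL <- list()
  for (k in seq_len(spec$ringCount)) {
    a <- ring$atoms
    if (k %% 2 == 0) {  # flipped ring: mirror z, offset rotation
      a$z <- -a$z
      th <- halfTurn
      xr <- a$x * cos(th) - a$y * sin(th)
      yr <- a$x * sin(th) + a$y * cos(th)
      a$x <- xr; a$y <- yr
    }
    a$z <- a$z + (k - 1) * .RING_SPACING
    off <- (k - 1L) * nR
    a$serial <- a$serial + off
    a$name <- paste0(a$name, "r", k)
    atomsL[[k]] <- a
    bondsL[[k]] <- ring$bonds + off
  }
  allAtoms <- do.call(rbind, atomsL)
  diamNm <- (max(sqrt(allAtoms$x^2 + allAtoms$y^2)) * 2) / 10
  lenNm <- (diff(range(allAtoms$z)) + 2) / 10
  NanoStructure(allAtoms, do.call(rbind, bondsL), identifier = identifier,
                materialClass = "CPNT",
                shape = if (spec$ringCount > 1) "tube" else "irregular",
                sizeNm = c(diamNm, lenNm))
}

#' Peptide-bond count of a cyclic-peptide structure
#'
#' Counts backbone C->N peptide links per ring (closure check: equals the
#' residue count for a closed ring).
#'
#' @param structure A CPNT [NanoStructure-class] built by [buildCPNT()].
#' @return Integer: number of C-N backbone bonds per ring.
#' @export
peptideBondCount <- function(structure) {
  a <- structure@atoms
  isC <- grepl("^C_", a$name)
  isN <- grepl("^N_", a$name)
  b <- structure@bonds
  el <- stats::setNames(seq_len(nrow(a)), a$serial)
  cn <- (isC[el[as.character(b[, 1])]] & isN[el[as.character(b[, 2])]]) |
        (isN[el[as.character(b[, 1])]] & isC[el[as.character(b[, 2])]])
  ring1 <- grepl("r1$", a$name)
  both1 <- ring1[el[as.character(b[, 1])]] & ring1[el[as.character(b[, 2])]]
  sum(cn & both1)
}
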