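## Surface-ligand handling: SMILES parsing and hydrogen addition through
## ChemmineOB (Open Babel), deterministic 3D embedding by internal
## coordinates plus steepest-descent relaxation, and random (seeded)
## grafting of ligand conformers onto detected surface sites.

#' Parse a SMILES string into a molecular graph
#'
#' Uses Open Babel (via ChemmineOB) to parse the SMILES and add explicit
#' hydrogens; returns the atom list and bond list only (no coordinates).
#'
#' @param smiles A SMILES string.
#' @return List with `elements` (character), `bonds` (two-column matrix of
#'   1-based atom indices) and `nAtoms`.
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles)))
    stop("invalid SMILES: empty input")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"),
                              options = data.frame(names = "h", args = "")),
    error = function(e) "")
  lines <- strsplit(sdf, "\n")[[1]]
  if (length(lines) < 4) stop("invalid SMILES: '", smiles, "' did not parse")
  counts <- lines[4]
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nA) || nA < 1) stop("invalid SMILES: '", smiles, "' did not parse")
  atomLines <- lines[5:(4 + nA)]
  elements <- trimws(substr(atomLines, 32, 34))
  bonds <- NULL
  if (!is.na(nB) && nB > 0) {
    bondLines <- lines[(5 + nA):(4 + nA + nB)]
    bonds <- cbind(as.integer(substr(bondLines, 1, 3)),
                   as.integer(substr(bondLines, 4, 6)))
  }
  list(elements = elements, bonds = bonds, nAtoms = nA)
}

## default anchor rule: thiol/thioether S, else first heteroatom, else
## first heavy atom
.anchorAtom <- function(elements) {
  s <- which(elements == "S")
  if (length(s)) return(s[1])
  het <- which(!elements %in% c("C", "H"))
  if (length(het)) return(het[1])
  heavy <- which(elements != "H")
  if (length(heavy)) heavy[1] else 1L
}

#' Embed a ligand SMILES as a 3D conformer
#'
#' Deterministic conformer generation: the molecular graph (with explicit
#' hydrogens, from Open Babel) is embedded by internal coordinates - ideal
#' bond lengths from covalent radii, near-tetrahedral branching, staggered
#' torsions - and then relaxed by a fixed number of steepest-descent steps
#' on a harmonic-bond plus soft-repulsion potential.  The same SMILES and
#' seed always give identical coordinates.
#'
#' @param smiles SMILES string.
#' @param seed Integer seed (controls the symmetry-breaking jitter).
#' @param relaxSteps Steepest-descent iterations.
#' @return A `LigandConformer`: list with `elements`, `coords` (n x 3,
#'   Angstrom), `bonds`, `anchor` (index of the attachment atom: thiol S if
#'   present, else the first heteroatom, else the first heavy atom) and
#'   `smiles`.
#' @examples
#' conf <- embedLigand("CCCS")  # propanethiol: 4 heavy atoms + 8 H
#' table(conf$elements)
#' @export
embedLigand <- function(smiles, seed = 1L, relaxSteps = 200L) {
  g <- parseSmiles(smiles)
  n <- g$nAtoms
  ## adjacency
  adj <- vector("list", n)
  if (!is.null(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  rad <- covalentRadius(g$elements)
  coords <- matrix(NA_real_, n, 3)
  placed <- logical(n)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))

  ## BFS placement with staggered branch directions
  parent <- rep(0L, n)
  coords[1, ] <- 0
  placed[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    kids <- adj[[p]][!placed[adj[[p]]]]
    if (!length(kids)) next
    gp <- parent[p]
    baseDir <- if (gp == 0) c(1, 0, 0) else {
      d <- coords[p, ] - coords[gp, ]; d / sqrt(sum(d^2))
    }
    ## orthonormal frame around baseDir
    ref <- if (abs(baseDir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    u <- ref - sum(ref * baseDir) * baseDir; u <- u / sqrt(sum(u^2))
    v <- c(baseDir[2] * u[3] - baseDir[3] * u[2],
           baseDir[3] * u[1] - baseDir[1] * u[3],
           baseDir[1] * u[2] - baseDir[2] * u[1])
    for (ci in seq_along(kids)) {
      k <- kids[ci]
      blen <- rad[p] + rad[k]
      if (gp == 0 && ci == 1) {
        dir <- baseDir
      } else {
        phi <- 2 * pi * (ci - 1) / max(length(kids), 3) + pi / 6
        ## ~109.5 deg from the incoming bond
        dir <- baseDir * cos(1.911) + (u * cos(phi) + v * sin(phi)) * sin(1.911)
        dir <- -dir  # extend away from the grandparent
      }
      coords[k, ] <- coords[p, ] + blen * dir + stats::rnorm(3, 0, 1e-3)
      placed[k] <- TRUE
      parent[k] <- p
      queue <- c(queue, k)
    }
  }
  if (any(!placed)) {  # disconnected SMILES fragments: line them up
    coords[!placed, ] <- cbind(seq_len(sum(!placed)) * 3, 0, 0)
  }

  ## steepest descent: harmonic bonds + soft nonbonded repulsion
  bmat <- g$bonds
  bl <- if (!is.null(bmat)) rad[bmat[, 1]] + rad[bmat[, 2]] else numeric()
  isBonded <- matrix(FALSE, n, n)
  if (!is.null(bmat)) isBonded[rbind(bmat, bmat[, 2:1, drop = FALSE])] <- TRUE
  for (it in seq_len(relaxSteps)) {
    grad <- matrix(0, n, 3)
    if (!is.null(bmat)) {
      dvec <- coords[bmat[, 1], , drop = FALSE] - coords[bmat[, 2], , drop = FALSE]
      dd <- sqrt(rowSums(dvec^2)); dd[dd < 1e-9] <- 1e-9
      f <- 2 * (dd - bl) / dd
      gb <- dvec * f
      for (j in 1:3) {
        grad[, j] <- grad[, j] +
          as.numeric(tapply(c(gb[, j], -gb[, j]),
                            factor(c(bmat[, 1], bmat[, 2]), levels = 1:n),
                            sum, default = 0))
      }
      grad[is.na(grad)] <- 0
    }
    if (n > 2) {
      D <- as.matrix(stats::dist(coords))
      rep0 <- 2.0
      close <- which(D < rep0 & upper.tri(D) & !isBonded, arr.ind = TRUE)
      if (nrow(close)) {
        for (ri in seq_len(nrow(close))) {
          i1 <- close[ri, 1]; i2 <- close[ri, 2]
          dvec <- coords[i1, ] - coords[i2, ]
          dd <- max(sqrt(sum(dvec^2)), 1e-9)
          f <- -2 * (rep0 - dd) / dd
          grad[i1, ] <- grad[i1, ] + f * dvec
          grad[i2, ] <- grad[i2, ] - f * dvec
        }
      }
    }
    coords <- coords - 0.05 * grad
  }
  coords <- sweep(coords, 2, colMeans(coords))
  structure(list(smiles = smiles, elements = g$elements, coords = coords,
                 bonds = g$bonds, anchor = .anchorAtom(g$elements)),
            class = "LigandConformer")
}

#' @export
print.LigandConformer <- function(x, ...) {
  cat(sprintf("LigandConformer '%s': %d atoms (%d heavy), anchor %s%d\n",
              x$smiles, length(x$elements), sum(x$elements != "H"),
              x$elements[x$anchor], x$anchor))
  invisible(x)
}

#' Detect surface sites of a core
#'
#' Core atoms whose coordination number (neighbours within 1.2 x the sum of
#' covalent radii) falls below the bulk coordination of the lattice are
#' surface sites.  When `bulkCoordination` is not given it defaults to the
#' maximum coordination observed in the structure.
#'
#' @param core A [NanoStructure-class].
#' @param bulkCoordination Integer; see above.
#' @return Integer vector of surface-atom serials.
#' @export
surfaceSites <- function(core, bulkCoordination = NULL) {
  a <- core@atoms[core@atoms$fragmentId == 0L, ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- covalentRadius(a$element)
  D <- as.matrix(stats::dist(xyz))
  cut <- 1.2 * outer(r, r, "+")
  coord <- rowSums(D < cut) - 1L
  if (is.null(bulkCoordination)) bulkCoordination <- max(coord)
  a$serial[coord < bulkCoordination]
}

#' Graft surface ligands onto a core
#'
#' Randomly places `count` copies of each ligand on detected surface sites:
#' sites are sampled without replacement (seeded) subject to a minimum
#' inter-anchor distance that scales with the requested count; each
#' conformer is rotated so its anchor-to-centroid axis points along the
#' outward surface normal, spun about the normal to avoid heavy-atom
#' clashes below 1.0 Angstrom, and bonded to its site.  Core atoms are
#' never moved or deleted.
#'
#' @param core A [NanoStructure-class] core.
#' @param ligands `data.frame` with columns `smiles` and `count`, or a list
#'   of such rows.
#' @param seed Integer seed; the same (core, ligands, seed) triple always
#'   yields the same structure.
#' @param bulkCoordination Passed to [surfaceSites()].
#' @return A new [NanoStructure-class]: all core atoms unchanged, plus the
#'   ligand copies (each with its own `fragmentId`) and one core-anchor
#'   bond per ligand.
#' @examples
#' au <- buildCore(coreSpec("fcc-Au", diameterNm = 1.5))
#' dec <- graftLigands(au, data.frame(smiles = "CCCS", count = 5), seed = 1)
#' nAtoms(dec) - nAtoms(au)  # 5 x 12 atoms
#' @export
graftLigands <- function(core, ligands, seed = 1L, bulkCoordination = NULL) {
  stopifnot(is(core, "NanoStructure"))
  ligands <- as.data.frame(ligands)
  if (!all(c("smiles", "count") %in% names(ligands)))
    stop("ligands must have columns smiles and count")
  ligands$count <- as.integer(ligands$count)
  if (any(ligands$count < 0)) stop("ligand counts must be >= 0")
  total <- sum(ligands$count)
  if (total == 0) {
    out <- core
    out@ligands <- ligands[ligands$count > 0, , drop = FALSE]
    return(out)
  }
  sites <- surfaceSites(core, bulkCoordination)
  if (total > length(sites))
    stop("capacity error: requested ", total, " ligands but only ",
         length(sites), " surface sites are available")

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(as.integer(seed))

  a <- core@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rownames(xyz) <- a$serial
  centroid <- colMeans(xyz)
  siteXYZ <- xyz[as.character(sites), , drop = FALSE]
  Rcore <- sqrt(max(rowSums(sweep(siteXYZ, 2, centroid)^2)))

  ## seeded greedy selection with a count-scaled minimum anchor spacing
  targetSpacing <- sqrt(4 * pi * Rcore^2 / total)
  chosen <- integer(0)
  dmin <- 0.5 * targetSpacing
  repeat {
    ord <- sample(length(sites))
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen)) { chosen <- i; next }
      dd <- sqrt(rowSums(sweep(siteXYZ[chosen, , drop = FALSE], 2,
                               siteXYZ[i, ])^2))
      if (all(dd >= dmin)) chosen <- c(chosen, i)
      if (length(chosen) == total) break
    }
    if (length(chosen) == total || dmin < 0.1) break
    dmin <- dmin * 0.7
  }
  if (length(chosen) < total)
    stop("capacity error: could not place ", total,
         " ligands with non-overlapping anchors; maximum is ", length(chosen))

  confs <- lapply(unique(ligands$smiles[ligands$count > 0]), embedLigand,
                  seed = seed)
  names(confs) <- unique(ligands$smiles[ligands$count > 0])

  newAtoms <- list(); newBonds <- list()
  nextSerial <- max(a$serial)
  fragId <- max(a$fragmentId)
  placedHeavy <- NULL
  instSmiles <- rep(ligands$smiles[ligands$count > 0],
                    ligands$count[ligands$count > 0])
  for (inst in seq_len(total)) {
    conf <- confs[[instSmiles[inst]]]
    site <- sites[chosen[inst]]
    sPos <- xyz[as.character(site), ]
    normal <- sPos - centroid
    nrm <- sqrt(sum(normal^2))
    normal <- if (nrm < 1e-9) c(0, 0, 1) else normal / nrm
    anchorEl <- conf$elements[conf$anchor]
    siteEl <- a$element[a$serial == site]
    bondLen <- sum(covalentRadius(c(anchorEl, siteEl)))

    ## rotate conformer: anchor->centroid axis onto the outward normal
    rel <- sweep(conf$coords, 2, conf$coords[conf$anchor, ])
    heavy <- conf$elements != "H"
    axis <- colMeans(rel[heavy, , drop = FALSE])
    if (sqrt(sum(axis^2)) < 1e-6) axis <- c(1, 0, 0)
    axis <- axis / sqrt(sum(axis^2))
    Ralign <- .rotationBetween(axis, normal)
    rel0 <- rel %*% t(Ralign)
    base <- sPos + bondLen * normal

    spins <- stats::runif(12, 0, 2 * pi)
    best <- NULL; bestScore <- -Inf
    for (sp in spins) {
      Rspin <- .axisRotation(normal, sp)
      cand <- sweep(rel0 %*% t(Rspin), 2, -base)
      candHeavy <- cand[heavy, , drop = FALSE]
      score <- if (is.null(placedHeavy)) Inf else {
        min(.crossDistMin(candHeavy, placedHeavy))
      }
      if (score > bestScore) { bestScore <- score; best <- cand }
      if (bestScore >= 1.5) break
    }
    fragId <- fragId + 1L
    serials <- nextSerial + seq_len(nrow(best))
    nextSerial <- max(serials)
    newAtoms[[inst]] <- data.frame(
      serial = serials, element = conf$elements,
      name = paste0(conf$elements, serials), fragmentId = fragId,
      x = best[, 1], y = best[, 2], z = best[, 3])
    lb <- if (!is.null(conf$bonds))
      cbind(serials[conf$bonds[, 1]], serials[conf$bonds[, 2]]) else NULL
    newBonds[[inst]] <- rbind(lb, cbind(site, serials[conf$anchor]))
    placedHeavy <- rbind(placedHeavy, best[heavy, , drop = FALSE])
  }

  allAtoms <- rbind(a, do.call(rbind, newAtoms))
  allBonds <- rbind(core@bonds, do.call(rbind, newBonds))
  NanoStructure(allAtoms, allBonds, identifier = core@identifier,
                materialClass = core@materialClass, shape = core@shape,
                sizeNm = core@sizeNm,
                ligands = ligands[ligands$count > 0, , drop = FALSE])
}

## rotation matrix taking unit vector a to unit vector b
.rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {  # opposite: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(.axisRotation(v, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

## rotation about a unit axis by angle theta (Rodrigues)
.axisRotation <- function(axis, theta) {
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * vx + (1 - cos(theta)) * vx %*% vx
}

## minimum distances from each row of A to the point set B
.crossDistMin <- function(A, B) {
  if (is.null(B) || !nrow(B)) return(Inf)
  apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
}
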