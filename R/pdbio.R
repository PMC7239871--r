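## Three-part PDB encoding of nanostructures:
##   part 1: REMARK 300 key:value lines with the structure annotation
##   part 2: one HETATM record per atom (element right-justified, 3-decimal
##           Angstrom coordinates)
##   part 3: CONECT records covering every bond exactly once
## Serials above 99999 use hybrid-36 widening (A0000... in the serial field);
## strict legacy PDB consumers may not accept such files.

.HB36_BASE <- 10 * 36^4  # value of "A0000" in base 36

.hy36encode <- function(serial) {
  vapply(serial, function(s) {
    if (s <= 99999) return(formatC(s, width = 5))
    v <- s - 100000 + .HB36_BASE
    if (v >= 36^5) stop("serial ", s, " exceeds hybrid-36 capacity")
    digits <- character(5)
    alphabet <- c(0:9, LETTERS)
    for (i in 5:1) { digits[i] <- alphabet[v %% 36 + 1]; v <- v %/% 36 }
    paste(digits, collapse = "")
  }, character(1))
}

.hy36decode <- function(field) {
  field <- trimws(field)
  vapply(field, function(f) {
    if (grepl("^[0-9]+$", f)) return(as.integer(f))
    if (!grepl("^[A-Z][A-Z0-9]{4}$", f))
      stop("malformed serial field '", f, "'")
    chars <- strsplit(f, "")[[1]]
    alphabet <- c(0:9, LETTERS)
    v <- 0
    for (ch in chars) v <- v * 36 + (match(ch, alphabet) - 1)
    as.integer(v - .HB36_BASE + 100000)
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a nanostructure as a three-part PDB file
#'
#' Writes the annotation header (REMARK 300 `MATERIAL`, `SHAPE`, `SIZE_NM`,
#' `ID` and per-ligand `SMILES`/`COUNT` lines), one HETATM record per atom
#' with coordinates at 3-decimal Angstrom precision, and CONECT records
#' encoding every bond once.  The particle centroid is translated to the
#' origin on write.  Structures with more than 99,999 atoms get hybrid-36
#' widened serials.
#'
#' @param structure A valid [NanoStructure-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readPDB()] for the inverse; the pair round-trips atoms, bonds
#'   and metadata exactly (coordinates at format precision).
#' @examples
#' au <- buildCore(coreSpec("fcc-Au", diameterNm = 1))
#' f <- tempfile(fileext = ".pdb")
#' writePDB(au, f)
#' readPDB(f)
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "NanoStructure"))
  validObject(structure)
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))  # centroid at origin
  if (any(abs(xyz) >= 10000))
    stop("coordinates exceed the PDB fixed-column range after centering")

  hdr <- c(
    sprintf("REMARK 300 ID %s", structure@identifier),
    sprintf("REMARK 300 MATERIAL %s", structure@materialClass),
    sprintf("REMARK 300 SHAPE %s", structure@shape),
    sprintf("REMARK 300 SIZE_NM %s",
            paste(format(structure@sizeNm, trim = TRUE), collapse = " x "))
  )
  lg <- structure@ligands
  if (nrow(lg)) {
    for (i in seq_len(nrow(lg))) {
      hdr <- c(hdr,
               sprintf("REMARK 300 LIGAND %d SMILES %s", i, lg$smiles[i]),
               sprintf("REMARK 300 LIGAND %d COUNT %d", i, lg$count[i]))
    }
  }

  resname <- ifelse(a$fragmentId == 0L, "COR", "LIG")
  atomLines <- sprintf(
    "HETATM%s %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    .hy36encode(a$serial), substr(a$name, 1, 4), resname,
    a$fragmentId %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], a$element)

  b <- structure@bonds
  conectLines <- character(0)
  if (nrow(b)) {
    partners <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
    ser <- as.integer(names(partners))
    ord <- order(ser)
    for (i in ord) {
      p <- sort(partners[[i]])
      for (chunk in split(p, ceiling(seq_along(p) / 4))) {
        conectLines <- c(conectLines,
          paste0("CONECT", .hy36encode(ser[i]),
                 paste(.hy36encode(chunk), collapse = "")))
      }
    }
  }
  writeLines(c(hdr, atomLines, conectLines, "END"), path)
  invisible(path)
}

#' Read a nanostructure from a PDB file
#'
#' Parses atom records (ATOM/HETATM), the CONECT connectivity (each
#' unordered pair kept once; records are cross-checked against the atom
#' serials) and, when present, the REMARK 300 annotation header written by
#' [writePDB()].  Files without an annotation header (e.g. imported
#' DNA-origami or dendrimer structures) get `materialClass`/`shape`
#' `"unknown"` and `NA` size.
#'
#' @param path PDB file path.
#' @param materialClass Optional override for the material class of imported
#'   files.
#' @return A [NanoStructure-class].
#' @export
readPDB <- function(path, materialClass = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atomIdx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(atomIdx)) stop("empty structure: no atom records in '", path, "'")

  al <- lines[atomIdx]
  serial <- .hy36decode(substr(al, 7, 11))
  name <- trimws(substr(al, 13, 16))
  frag <- suppressWarnings(as.integer(trimws(substr(al, 23, 26))))
  frag[is.na(frag)] <- 0L
  coords <- matrix(NA_real_, length(al), 3)
  for (j in 1:3) {
    f <- trimws(substr(al, 31 + 8 * (j - 1), 38 + 8 * (j - 1)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("malformed coordinate field at line ",
           atomIdx[which(is.na(v))[1]], " of '", path, "'")
    coords[, j] <- v
  }
  element <- trimws(substr(al, 77, 78))
  noEl <- element == ""
  if (any(noEl)) element[noEl] <- sub("^([A-Za-z]+).*", "\\1", name[noEl])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  element <- trimws(element)
  if (anyDuplicated(serial)) stop("duplicate atom serials in '", path, "'")

  bonds <- NULL
  conIdx <- which(rec == "CONECT")
  if (length(conIdx)) {
    prs <- lapply(lines[conIdx], function(l) {
      body <- substring(l, 7)
      n <- nchar(body) %/% 5
      if (n < 2) return(NULL)
      fields <- substring(body, 5 * (0:(n - 1)) + 1, 5 * (1:n))
      fields <- fields[trimws(fields) != ""]
      if (length(fields) < 2) return(NULL)
      s <- .hy36decode(fields)
      cbind(s[1], s[-1])
    })
    bonds <- do.call(rbind, prs)
  }

  meta <- list(id = basename(path), material = "unknown", shape = "unknown",
               size = NA_real_)
  ligands <- list()
  for (l in lines[rec == "REMARK"]) {
    f <- strsplit(trimws(substring(l, 12)), "\\s+")[[1]]
    if (!length(f)) next
    key <- f[1]
    if (key == "ID" && length(f) > 1) meta$id <- f[2]
    else if (key == "MATERIAL" && length(f) > 1) meta$material <- f[2]
    else if (key == "SHAPE" && length(f) > 1) meta$shape <- f[2]
    else if (key == "SIZE_NM")
      meta$size <- suppressWarnings(as.numeric(f[-1][f[-1] != "x"]))
    else if (key == "LIGAND" && length(f) >= 4) {
      i <- f[2]
      if (is.null(ligands[[i]])) ligands[[i]] <- list(smiles = NA, count = 0L)
      if (f[3] == "SMILES") ligands[[i]]$smiles <- f[4]
      if (f[3] == "COUNT") ligands[[i]]$count <- as.integer(f[4])
    }
  }
  lg <- if (length(ligands)) {
    data.frame(smiles = vapply(ligands, `[[`, "", "smiles"),
               count = vapply(ligands, `[[`, 0L, "count"),
               row.names = NULL)
  } else data.frame(smiles = character(), count = integer())

  if (!is.null(materialClass)) meta$material <- materialClass
  NanoStructure(
    atoms = data.frame(serial = serial, element = element, name = name,
                       fragmentId = frag,
                       x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    bonds = bonds, identifier = meta$id, materialClass = meta$material,
    shape = meta$shape, sizeNm = meta$size, ligands = lg)
}

#' Export atom and bond tables as CSV
#'
#' @param structure A [NanoStructure-class].
#' @param atomsPath,bondsPath Output CSV paths (`bondsPath` optional).
#' @return Invisibly, the paths written.
#' @export
writeStructureCSV <- function(structure, atomsPath, bondsPath = NULL) {
  stopifnot(is(structure, "NanoStructure"))
  utils::write.csv(structure@atoms, atomsPath, row.names = FALSE)
  if (!is.null(bondsPath))
    utils::write.csv(as.data.frame(structure@bonds), bondsPath,
                     row.names = FALSE)
  invisible(c(atomsPath, bondsPath))
}

#' Check declared size against the coordinate extent
#'
#' The declared size (nm) is compared with the maximum coordinate extent of
#' the core atoms; agreement within `tolNm` (default one typical lattice
#' constant, 0.5 nm) is accepted.
#'
#' @param structure A [NanoStructure-class].
#' @param tolNm Tolerance in nm.
#' @return Logical.
#' @export
sizeConsistent <- function(structure, tolNm = 0.5) {
  sz <- structure@sizeNm
  if (all(is.na(sz))) return(NA)
  core <- structure@atoms[structure@atoms$fragmentId == 0L, c("x", "y", "z")]
  ext <- max(apply(core, 2, function(v) diff(range(v)))) / 10  # Angstrom->nm
  abs(ext - max(sz)) <= tolNm
}
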