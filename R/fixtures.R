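## Synthetic fixtures with planted structure-activity signal, and the
## database census registry (per-class structure counts and endpoint
## memberships as printed for the curated 705-structure collection).

.REGISTRY <- data.frame(
  materialClass = c("GNP", "AgNP", "PtNP", "PdNP", "CNT", "C60", "QD",
                    "MONP", "DnaNP", "Dendrimer", "CPNT"),
  count = c(414L, 17L, 12L, 12L, 80L, 48L, 34L, 32L, 21L, 11L, 24L),
  logP = c(123L, 0L, 12L, 12L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
  zetaPotential = c(148L, 6L, 12L, 12L, 0L, 0L, 24L, 8L, 0L, 3L, 0L),
  cellularUptake = c(71L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
)

#' Database census registry
#'
#' Per-material-class structure counts of the curated nanomaterial
#' collection (705 total), with per-endpoint dataset memberships: logP
#' (147: 123 GNPs, 12 PtNPs, 12 PdNPs), zeta potential in water at pH 7
#' (213) and A549 cellular uptake (71 GNPs).
#'
#' @return `data.frame` with columns `materialClass`, `count`, `logP`,
#'   `zetaPotential`, `cellularUptake`.
#' @examples
#' sum(registryCounts()$count)  # 705
#' @export
registryCounts <- function() .REGISTRY

#' Declare a synthetic fixture recipe
#'
#' Recipe R1: small ligand-decorated metal cores with a planted linear
#' structure-activity signal.  The endpoint is
#' `y = X[, signal] %*% beta + eps` with `eps ~ N(0, sigma^2)` and `sigma`
#' set so the planted signal variance is `noiseRatio` (default 4) times
#' the noise variance.  The signal columns are chosen deterministically
#' from the normalized, filtered descriptor matrix: the `nSignal` highest-
#' variance columns with pairwise |correlation| below 0.95.
#'
#' @param n Number of structures.
#' @param materials Lattice registry keys to sample cores from.
#' @param diameterRangeNm Core diameter range (nm).
#' @param ligandPool SMILES pool for surface ligands.
#' @param ligandCountRange Per-particle ligand count range.
#' @param nSignal Number of planted signal descriptors.
#' @param beta Signal coefficients (length `nSignal`).
#' @param noiseRatio Signal-to-noise variance ratio.
#' @param endpointName Endpoint label (unitless logP by default).
#' @param seed Integer seed.
#' @return A `SyntheticRecipe` list.
#' @export
syntheticRecipe <- function(n = 150L,
                            materials = c("fcc-Au", "fcc-Ag", "fcc-Pt",
                                          "fcc-Pd"),
                            diameterRangeNm = c(1.0, 2.0),
                            ligandPool = c("CCCS", "OCCS", "NCCS", "CCS",
                                           "OC(=O)CS"),
                            ligandCountRange = c(0L, 30L),
                            nSignal = 5L, beta = c(2, -1.5, 1.2, 0.9, -1.1),
                            noiseRatio = 4, endpointName = "logP",
                            seed = 7L) {
  stopifnot(n >= 2, length(beta) == nSignal, noiseRatio > 0,
            diameterRangeNm[1] > 0, diameterRangeNm[2] <= 3)
  structure(list(n = as.integer(n), materials = materials,
                 diameterRangeNm = diameterRangeNm, ligandPool = ligandPool,
                 ligandCountRange = as.integer(ligandCountRange),
                 nSignal = as.integer(nSignal), beta = beta,
                 noiseRatio = noiseRatio, endpointName = endpointName,
                 seed = as.integer(seed)),
            class = "SyntheticRecipe")
}

#' Generate a synthetic fixture set with planted signal
#'
#' Builds `n` small ligand-decorated particles via the core builder and
#' grafting machinery, computes their nanodescriptors, removes constant
#' descriptors, and assigns the endpoint by the recipe's planted linear
#' rule.  Fully reproducible under the recipe seed.
#'
#' @param recipe A [syntheticRecipe()].
#' @param keepStructures Return the built [NanoStructure-class] objects
#'   too (larger object).
#' @return List: `ids`, `x` (raw filtered structures x descriptors
#'   matrix), `y` (named endpoint vector), `signalColumns`, `sigma`,
#'   `recipe`, and optionally `structures`.
#' @export
generateFixtureSet <- function(recipe = syntheticRecipe(),
                               keepStructures = FALSE) {
  stopifnot(inherits(recipe, "SyntheticRecipe"))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(recipe$seed)
  n <- recipe$n
  mats <- sample(recipe$materials, n, replace = TRUE)
  diams <- stats::runif(n, recipe$diameterRangeNm[1], recipe$diameterRangeNm[2])
  ligs <- sample(recipe$ligandPool, n, replace = TRUE)
  cnts <- sample(seq(recipe$ligandCountRange[1], recipe$ligandCountRange[2]),
                 n, replace = TRUE)
  graftSeeds <- sample.int(1e6, n)
  noiseDraw <- stats::rnorm(n)

  structures <- vector("list", n)
  for (i in seq_len(n)) {
    core <- buildCore(coreSpec(mats[i], diameterNm = diams[i]),
                      identifier = sprintf("SYN%03d", i))
    structures[[i]] <- if (cnts[i] > 0) {
      graftLigands(core, data.frame(smiles = ligs[i], count = cnts[i]),
                   seed = graftSeeds[i])
    } else core
  }
  ids <- vapply(structures, structureId, character(1))
  mat <- t(vapply(structures, function(s) as.numeric(nanoDescriptors(s)),
                  numeric(17L * 126L)))
  colnames(mat) <- names(nanoDescriptors(structures[[1]]))
  rownames(mat) <- ids

  flt <- filterDescriptors(mat)
  xn <- normalizeDescriptors(flt$matrix)

  ## deterministic signal-column choice: top variance, decorrelated
  v <- apply(xn, 2, stats::var)
  ord <- order(v, decreasing = TRUE)
  chosen <- integer(0)
  for (j in ord) {
    if (!length(chosen)) { chosen <- j }
    else if (all(abs(stats::cor(xn[, j], xn[, chosen])) < 0.95))
      chosen <- c(chosen, j)
    if (length(chosen) == recipe$nSignal) break
  }
  if (length(chosen) < recipe$nSignal)
    stop("not enough decorrelated descriptors for the planted signal")
  signalCols <- colnames(xn)[chosen]
  y0 <- as.numeric(xn[, chosen, drop = FALSE] %*% recipe$beta)
  sigma <- stats::sd(y0) / sqrt(recipe$noiseRatio)
  y <- stats::setNames(y0 + sigma * noiseDraw, ids)

  out <- list(ids = ids, x = flt$matrix, y = y, signalColumns = signalCols,
              sigma = sigma, recipe = recipe)
  if (keepStructures) out$structures <- structures
  out
}
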