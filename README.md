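# nanotess

Atomistic nanostructure annotation and Delaunay-tessellation
nanodescriptors for quantitative nanostructure-activity modeling.

Experimental nanomaterial data are usually reported as recipes (material,
size, shape, surface ligands), not as structures a model can consume.
`nanotess` closes that gap for computational nanotechnology and
nano-QSAR researchers: it builds atomistic structures from such
declarative annotations, stores them as annotated PDB files, and converts
every structure into a fixed-length numerical descriptor vector suitable
for machine learning.

## The descriptor model

A structure's atoms are partitioned by **Delaunay tessellation** into
tetrahedra (no atom lies inside any tetrahedron's circumsphere). Each
tetrahedron is typed as the unordered multiset of its four vertex atom
classes over a six-letter alphabet — H, C, N, O, X (other nonmetal),
M (metal/metalloid) — giving C(6+4−1, 4) = **126 fragment classes**.
Occurrences are converted to frequencies f(c) (they sum to 1), and for each
of **17 atomic properties** p (radii, mass, electronegativity, ionization
energies, thermal quantities, valence, ...) the descriptor is

    value(p, c) = f(c) · mean over instances of c of Σ₄ p(atom)

yielding 17 × 126 = **2142 nanodescriptors** per structure. Constant
descriptors are filtered, the rest min–max normalized for diversity
analysis (pairwise Euclidean distances, PCA) and regression: an 80/20
split with 5-fold cross-validation, kNN with simulated-annealing variable
selection and exp(−d)-weighted neighbour averaging, or a 512/128/64
relu/dropout feedforward network (rmsprop, MSE), reporting R²/RMSE for
both cross-validation and external prediction.

Builders cover fcc Au/Ag/Pt/Pd cores (spheres and capped rods), zincblende
CdSe/CdS quantum dots, TiO2/ZnO/CeO2 oxides, carbon nanotubes from chiral
indices, buckminsterfullerene, cyclic-peptide nanotubes, and seeded random
grafting of SMILES-defined surface ligands.

## Worked example

```r
library(nanotess)

core <- buildCore(coreSpec("fcc-Au", diameterNm = 2))
gnp  <- graftLigands(core, data.frame(smiles = "CCCS", count = 20), seed = 1)
gnp
#> NanoStructure 'fccAucore' (GNP, sphere, 2 nm)
#>   489 atoms (Au:249 C:60 H:160 S:20), 240 bonds
#>   ligands: CCCS x20

writePDB(gnp, "gnp.pdb")          # three-part annotated PDB file

d <- nanoDescriptors(gnp)         # 2142 named values
round(d[c("chi.MMMM", "chi.XMMM")], 4)
#> chi.MMMM chi.XMMM
#>   3.7624   0.1730
sum(attr(d, "frequencies"))       # tetrahedron frequencies sum to 1
#> [1] 1
```

`chi.MMMM` is the electronegativity-weighted all-metal tetrahedron
descriptor: the frequency of Au₄ tetrahedra (here 0.370) times the mean
per-tetrahedron electronegativity sum (4 × 2.54). `chi.XMMM` reflects the
rarer S–Au₃ tetrahedra at the ligand anchors.

Diversity and modeling on a set of structures:

```r
structs <- list(gnp, buildFullerene(), buildCNT(cntSpec(6, 6, 1)),
                buildCPNT(cpntSpec("AGAGAGAG", 3)),
                buildCore(coreSpec("zincblende-CdSe", diameterNm = 1.6)))
flt <- filterDescriptors(descriptorSet(structs))
xn  <- normalizeDescriptors(flt$matrix)
attr(pairwiseDistances(xn), "summary")
#>      min      max     mean
#>  0.00000 23.87133 15.60141
descriptorPCA(xn, k = 3)$explained
#> [1] 0.579 0.325 0.096
```

(The 0 minimum distance is the fullerene/nanotube pair: pure-carbon
structures have identical composition-based descriptors — see the methods
vignette.)

Endpoint modeling on the built-in synthetic benchmark:

```r
fx   <- generateFixtureSet(syntheticRecipe())   # 150 particles, planted signal
plan <- makeSplit(fx$ids, seed = 1)
rep  <- crossValidate(fx$x, fx$y, plan, method = "knn", seed = 1)
rep
#> ModelReport (knn)
#>   5-fold CV : R2 = 0.652, RMSE = 0.497
#>   external  : R2 = 0.639, RMSE = 0.469
```

A command-line interface wrapping the same functions ships as
`inst/scripts/nanotess-cli.R` (subcommands `build`, `descriptors`,
`distances`, `pca`, `split`, `train`, `evaluate`, `fixtures`, `registry`).

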