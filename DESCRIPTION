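Package: nanotess
Title: Atomistic Nanostructure Annotation and Delaunay Tessellation
    Nanodescriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds atomistic nanomaterial structures from declarative
    specifications (crystalline cores carved to size, carbon nanotubes from
    chiral indices, cyclic-peptide nanotubes, ligand-decorated particles),
    encodes them as annotated three-part PDB files, and computes
    tessellation-based nanodescriptors: the Delaunay tetrahedralization of
    the atomic coordinates is typed over a six-letter atom-class alphabet
    into 126 tetrahedron fragment classes, converted to frequencies, and
    weighted by 17 atomic properties into a fixed 2142-length descriptor
    vector per structure.  Includes chemical-space diversity analysis
    (min-max normalization, pairwise Euclidean distances, PCA) and
    quantitative nanostructure-activity modeling (kNN with simulated
    annealing variable selection and a feedforward neural network) under an
    80/20 split with 5-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    ChemmineOB,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cli.R'
    'cnt.R'
    'cpnt.R'
    'descriptors.R'
    'diversity.R'
    'elements.R'
    'fixtures.R'
    'lattice.R'
    'ligand.R'
    'modeling.R'
    'nanotess-package.R'
    'pdbio.R'
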