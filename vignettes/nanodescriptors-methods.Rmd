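---
title: "Tessellation nanodescriptors: models, parameters and design choices"
author: "nanotess maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tessellation nanodescriptors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotess)
```

# Scope

`nanotess` turns a declarative description of a nanomaterial (material,
shape, size, surface ligands) into an atomistic structure, encodes it as an
annotated PDB file, summarizes its geometry and composition as a fixed
2142-length descriptor vector, and uses those descriptors for diversity
analysis and structure-activity regression. This vignette explains the
science behind each stage, the tunable parameters and their defaults, and
the design decisions taken where the underlying procedure was genuinely
open.

# Structure generation

## Crystalline cores

Metal (Au, Ag, Pt, Pd), quantum-dot (CdSe, CdS) and metal-oxide (TiO2, ZnO,
CeO2) cores are built by replicating the material's registered unit cell
into a supercell and deleting every site outside the target solid. The
lattice registry (`latticeRegistry()`) holds standard crystallographic
parameters - e.g. fcc gold at a = 4.078 Angstrom - and is user-overridable
by passing a full lattice definition to `coreSpec()`. Spheres keep sites
with |r| <= d/2 about a lattice point; rods are cylinders with
hemispherical caps, declared as diameter x total length. Because the carved
set is an exact subset of the infinite lattice, atom counts can be checked
against independent brute-force lattice enumeration, and they scale with
the carved volume (doubling the diameter multiplies the count by ~8).

Metal-metal connectivity records are not written by default (the files
describe geometry, not a bonding model); `buildCore(withBonds = TRUE)`
switches on distance-cutoff perception at 1.2 x the sum of covalent radii,
the same rule used for covalent materials.

## Carbon nanotubes and fullerene

`buildCNT()` uses the standard graphene roll-up: the chiral vector (n, m)
on a graphene sheet with lattice constant a = 2.46 Angstrom is wrapped into
a cylinder of diameter d = a sqrt(n^2 + nm + m^2) / pi. All atoms lie
exactly on the cylinder, and interior atoms have exactly three bonded
neighbours at the 1.42 Angstrom C-C distance. Buckminsterfullerene is
generated from the exact truncated-icosahedron vertex coordinates scaled to
1.42 Angstrom edges, giving the canonical 60 atoms and 90 bonds; we chose
the closed-form geometry over conformer generation from a cage SMILES
because it is exact and deterministic.

## Cyclic-peptide nanotubes

`buildCPNT()` joins residues head-to-tail through peptide bonds into a
closed ring (one C->N link per residue by construction) and stacks rings
along the tube axis at 4.8 Angstrom - the backbone-to-backbone spacing of
beta-sheet-like hydrogen bonding - with alternate rings flipped
(antiparallel stacking). Inter-ring hydrogen bonds are implied by this
geometry and deliberately not stored as bonds. The geometry is an idealized
template model: backbone atoms on a planar ring, side chains grown radially
outward with hydrogens filled to standard valences. It reproduces
composition, connectivity and dimensions faithfully; it is not an
energy-minimized conformation, which is irrelevant for the
composition-topology descriptors computed downstream but should be kept in
mind if the files are used for anything force-field based.

## Ligand embedding and grafting

SMILES parsing and hydrogen addition go through Open Babel (ChemmineOB).
Conformer coordinates, however, are produced by the package's own
deterministic internal-coordinate embedding (ideal bond lengths from
covalent radii, near-tetrahedral branching, staggered torsions) followed by
a fixed number of steepest-descent steps on a harmonic-bond plus
soft-repulsion potential. We require bit-for-bit reproducibility under a
seed - the same (SMILES, seed) pair must always give the same coordinates -
and stochastic conformer searches cannot provide that.

`graftLigands()` detects surface sites as core atoms whose coordination
number (1.2 x covalent-radii cutoff) falls below the bulk coordination of
the lattice, samples sites without replacement under a minimum inter-anchor
spacing that scales as sqrt(4 pi R^2 / count), and plants each conformer
with its anchor atom (thiol sulfur if present, else the first heteroatom,
else the first heavy atom) bonded to its site, oriented along the outward
surface normal, and spun about the normal to maximize clearance from
previously placed ligands. Core atoms are never moved or deleted; ligand
density is always the user's declared count, never predicted from
chemistry.

# The descriptor model

## Delaunay tessellation

The atomic point set is partitioned into tetrahedra such that no atom lies
inside any tetrahedron's circumsphere. The implementation is an incremental
Bowyer-Watson tetrahedralization in C++ with extended-precision circumsphere
predicates, validated in the test suite against a brute-force
empty-circumsphere oracle over random point sets. Crystalline cores are
exactly degenerate (coplanar lattice planes, cospherical shells); before
tessellating, coordinates receive a deterministic jitter of 1e-9 times the
coordinate extent, keyed to the structure id. The jitter is relative, so
the tessellation topology - and hence every descriptor - is invariant under
uniform scaling, and it is orders of magnitude below any physical length
scale. Structures above a configurable budget (200,000 atoms) are refused
with an instructive error rather than silently subsampled.

## Fragment classes and frequencies

Each tetrahedron is typed as the unordered multiset of its four vertex atom
classes. The alphabet has six classes - H, C, N, O, X (other nonmetals:
S, P, Se, halogens) and M (metals/metalloids) - because multisets of size 4
over 6 letters give choose(9, 4) = 126 fragment classes, the fixed
descriptor alphabet. The element-to-class mapping is config-overridable
(`atomTypeScheme()`). Occurrences are converted to frequencies (dividing by
the structure's total tetrahedron count) so that structures of very
different sizes remain comparable; the 126 frequencies always sum to 1.

## Property weighting

Seventeen atomic properties (three radii, mass, boiling/melting points,
density, electron affinity, electronegativity, heats of fusion and
vaporization, first/second ionization energies, molar volume, specific
heat, thermal conductivity, valence; units documented in
`?atomicProperties`) weight the frequencies: for property p and class c,

    value(p, c) = frequency(c) x mean over instances of c of
                  sum of p over the instance's four atoms.

Summing over the four atoms (rather than averaging) was an open choice; we
chose the sum and kept the per-class mean over instances so that distinct
elements mapping to the same coarse class still move the descriptor - a
CdSe and a ZnO tetrahedron of identical class pattern get different values.
The result is a 17 x 126 = 2142-vector with deterministic property-major
naming (`chi.XMMM`, `mass.HHCC`, ...). Genuinely undefined property values
(unbound electron affinities of N, Mg, Zn, Cd; the second ionization energy
of hydrogen) are recorded as 0.

A structural consequence worth knowing: single-element structures populate
only one class per composition, so the descriptors of two pure-carbon
allotropes (a fullerene and a nanotube) are identical. The descriptors
capture composition-weighted packing, not long-range shape.

## Filtering

Descriptors constant across the analyzed set carry no information and are
removed by `filterDescriptors()` before normalization. We implement exact
zero variance with a configurable threshold, since the alternative (a
near-constant cutoff) was unspecified; the kept/removed partition always
sums to 2142.

# Diversity analysis

All kept descriptors are min-max scaled to [0, 1] using the min/max of the
analyzed set (`normalizeDescriptors()`); similarity calls based on
normalized Euclidean distance depend on this convention, so per-subset
rescaling is deliberately not done. `pairwiseDistances()` enumerates all
n(n-1)/2 unordered pairs. `descriptorPCA()` mean-centers columns (no
re-standardization beyond the min-max step), decomposes the covariance, and
fixes each component's sign by making its largest-magnitude loading
positive, so results are deterministic.

# Modeling protocol

Endpoints are modeled from the filtered descriptor matrix under a fixed
protocol: a seeded 80/20 split (`round(0.8 n)` training structures), five
cross-validation folds dealt round-robin after a seeded shuffle,
`R2_5CV`/`RMSE_5CV` computed on the pooled out-of-fold predictions, and
`R2_val`/`RMSE_val` from the external 20% predicted by a model refit on the
full training set. Min-max statistics are always fitted on the training
portion in play and applied to the held-out data - the test suite checks
that corrupting test rows cannot move any training-side number. R2 is the
squared Pearson correlation between predicted and observed values (the
common QSAR convention); the coefficient-of-determination alternative is
available via `evaluateModel(method = "cod")`.

## kNN with variable selection

`knnFit()` selects a descriptor subset by simulated annealing with
geometric cooling, maximizing the leave-one-out q2 of weighted kNN on the
training set; prediction is the exp(-d)-weighted average of the k nearest
training points in the selected-subset metric, with ties broken by id
order. Defaults: k searched over 1-5 jointly with the subset, subset sizes
5-30 in steps of 5, 400 annealing steps per size, initial temperature 0.05,
cooling 0.97. These defaults were frozen after comparing candidate grids
across independent protocol seeds on the synthetic benchmark; all knobs are
arguments.

A known behaviour of this estimator family at typical dataset sizes
(~100-200 structures vs ~1000 surviving descriptors): the selection
objective can reach LOO q2 around 0.8 while the externally validated R2 is
lower - selection overfitting. We report both cross-validated and external
statistics precisely so this gap is visible, and we do not patch it with
consensus averaging, which would change the single-subset model contract.

## Neural network

`dnnFit()` is a fully connected regressor - hidden widths 512/128/64,
rectified-linear activations, inverted dropout 0.2 after each hidden layer,
rmsprop at its standard learning rate (1e-3), mean-squared-error loss, 300
epochs - implemented directly in R with seeded, fully deterministic
initialization, shuffling and dropout masks. The endpoint is standardized
internally and predictions are returned on the original scale. Width and
epoch counts are arguments; the desk-scale tests use reduced
configurations (e.g. 32/16/8, 30 epochs) to stay fast while exercising the
same code path. Divergence (non-finite or runaway loss) raises an error
naming the seed.

# The synthetic benchmark

`syntheticRecipe()` / `generateFixtureSet()` emulate a curated
structure-activity dataset at desk scale: by default 150 ligand-decorated
fcc metal cores (Au/Ag/Pt/Pd, 1-2 nm, thiol-anchored ligands from a small
SMILES pool, 0-30 per particle), descriptors computed by the full pipeline,
and an endpoint planted as a linear function of five deterministically
chosen, decorrelated, high-variance descriptor columns plus Gaussian noise
with signal variance exactly 4x the noise variance (so the attainable R2 is
about 0.8). Core sizes are deliberately small so tessellation-based tests
run in seconds - a scale choice, not a method change; problem sizes used by
the test suite are n = 150 structures of roughly 100-700 atoms each.

What passing tests on this fixture do and do not show: they demonstrate
that the pipeline recovers a planted linear composition-descriptor signal
through the full build -> tessellate -> select -> validate chain. Real
nanomaterial endpoints are noisier, nonlinear, and depend on features
(surface curvature at fixed composition, ligand conformation) that
composition-based tetrahedron statistics only partly capture, so fixture
performance is an upper bound on what identical settings would achieve on
laboratory data.

# Numerical choices and degenerate inputs

* Tessellation requires >= 4 affinely independent atoms; collinear or
  coplanar inputs raise a degenerate-geometry error.
* PDB serials beyond 99,999 (a 40 nm metal sphere exceeds this) switch to
  hybrid-36 widened fields, accepted on read; strict legacy consumers may
  reject such files, which is documented rather than worked around.
* Coordinates are written at the format's 3-decimal Angstrom precision;
  round-trip identity holds at that precision with the centroid re-centred
  to the origin.
* Constant endpoints: kNN predicts the constant with zero error; R2 is
  reported as NA with a warning (undefined correlation).
* Fold membership, SA proposals, dropout masks and grafting placements all
  draw from seeded, state-restored RNG streams, so every pipeline stage is
  reproducible end to end.

# Known limitations

* Descriptors are composition-and-packing statistics; they cannot separate
  same-composition allotropes (see above) and carry no explicit surface
  curvature term.
* CPNT and embedded-ligand geometries are idealized templates, not
  minimized conformations.
* The zero-variance filter is the only descriptor selection performed
  outside the modeling stage; near-constant descriptors survive filtering
  by design.
* Imported structures (DNA origami, dendrimers) are supported through the
  PDB reader only; the package does not generate them.
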