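---
title: "Topological featurization of protein mutations: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological featurization of protein mutations: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toplap)
```

## The problem and the model

A point mutation changes one residue of a protein and, with it, the local
packing, hydrogen-bond network and hydrophobic contacts around the mutation
site.  Those geometric changes correlate with changes in solubility, which
this package treats as a three-class prediction problem: does solubility
*decrease* (`-`), stay unchanged (`N`), or *increase* (`+`) upon mutation?

The structural signal is extracted with **persistent topological
Laplacians**.  For a simplicial complex $K$ with boundary matrices $B_k$,
the combinatorial (Hodge) Laplacian is

$$L_k = B_{k+1} B_{k+1}^\top + B_k^\top B_k,$$

a symmetric positive semi-definite integer matrix.  Its zero eigenvalues
(the *harmonic spectrum*) count the $k$-dimensional holes — components,
rings, cavities for $k = 0, 1, 2$ — while the positive (*non-harmonic*)
eigenvalues carry geometric shape information invisible to homology.
Running this along a filtration — a nested family of complexes indexed by a
growing scale parameter $f$ in Ångström — yields, per snapshot, a full
eigenvalue multiset; the harmonic part reproduces persistent homology, the
non-harmonic part tracks homotopic shape evolution.

Two filtrations are used:

* a **Vietoris–Rips filtration over the interactive distance** $D_I$, which
  is infinite between atoms sharing a location class (both in the mutation
  site, or both in the rest of the protein) and Euclidean otherwise.  Its
  complexes contain only site–environment contacts, so the dimension-0
  Laplacian spectra describe how the mutation site binds to its
  surroundings;
* a **Euclidean alpha-type filtration** of selected atom clouds, whose
  dimension-1 and -2 barcodes describe rings and cavities in the local
  packing.

Atom clouds are *element-specific*: one element (C, N or O) is chosen in
the mutation site and one in the environment, giving nine element pairs
(carbon pairs probe hydrophobic contacts, N/O pairs hydrogen-bonding), plus
one all-heavy-atom pair (C, N, O, S) for the higher-dimensional features.

## Feature layouts

All layout constants are fixed and tested:

| block | layout | total |
|---|---|---|
| 0-dim PL | 2 proteins × 13 grid values × 9 pairs × 8 spectrum statistics | 1872 |
| high-dim PL | (9 + 1) pairs × dims {1,2} × 7 bar statistics, for wild, mutant, difference | 420 |
| PH | 9 pairs × 12 bins × 2 statistics, for wild, mutant, difference | 648 |
| transformer | final-layer mean of a protein language model | 1280 |

The eight spectrum statistics are the non-harmonic count, sum, min, max,
mean, standard deviation, variance and sum of squares (population moments,
so a single eigenvalue has zero spread).  The seven bar statistics are sum,
max and mean of bar lengths, min and max birth, min and max death, after
removal of bars shorter than 0.1 Å.  The "TopLap" assembly is PL blocks +
transformer + auxiliary; the "TopGBT" assembly replaces PL with the PH
embedding.

## Numerical and design choices

**Čech instead of Delaunay-alpha.**  The package computes the
higher-dimensional barcodes from the Čech nerve filtration, in which a
simplex enters at the radius of the smallest ball enclosing its vertices.
The Čech and alpha filtrations are both nerves of the same growing union of
balls, so their persistence diagrams are identical bar for bar; the Čech
route avoids exact 3D Delaunay triangulation, which is degenerate for
coplanar point sets such as an aromatic ring.  The cost is a larger
complex, acceptable because clouds are local (a configurable 12 Å
neighborhood of the mutation site) and element-filtered.  Diagrams are
cross-checked in the test suite against an independent plain-R
boundary-matrix reduction.

**Radius scale.**  Bar endpoints are reported as ball radii in Å (not
diameters, not squared radii).  The 0.1 Å bar filter and the PH bin edges
apply on this scale.  The printed feature totals are scale-independent, so
this is a convention, fixed and documented rather than inferable.

**Filtration grid.**  0-dim features use 0 to 6 Å in 0.5 Å steps
(13 values); PH death values are binned into the 12 half-open half-Å bins
of that range.  Essential (infinite) 0-dim bars are assigned the grid
maximum (6 Å) when binned, and are excluded from barcode min/max death
statistics.

**Rips conventions.**  The edge threshold is inclusive (an edge appears at
$f$ equal to the pair distance).  Rips complexes are built only to the
dimension needed (the 1-skeleton for dimension-0 Laplacians).

**Environment cutoff.**  The environment side of every selection is
restricted to atoms within 12 Å of any mutation-site atom.  The method is
explicitly local, but no cutoff value is canonical; 12 Å comfortably covers
the 6 Å filtration range plus side-chain extent, and it is recorded in
block metadata and configurable everywhere.

**Orientation and ordering.**  Simplices are stored with ascending vertex
order, which fixes the orientation; Laplacian spectra are
orientation-invariant (tested under random vertex relabeling).  Bases are
ordered lexicographically so all matrices are reproducible bit for bit.

**Zero-eigenvalue tolerance.**  Harmonic and non-harmonic spectra are split
at $|\lambda| \le 10^{-8}\max(1, \lambda_{max})$; fixture-scale Laplacians
are integer matrices, so the split is unambiguous.

**Metric normalization.**  Confusion-matrix rows are rescaled to equal
class mass ($N/K$ per true class) before computing the "normalized" metric
of each raw/normalized pair.  Row rescaling is the unique simple scheme
under which sensitivity — a row-internal ratio — is exactly invariant while
PPV and specificity shift, the pattern published raw/normalized tables
exhibit.  Note that specificity is *not* invariant (it mixes counts across
rows); the test suite asserts both facts.  Cross-validation pools the fold
confusion matrices per repeat before computing CPR and GC², because
averaging GC² over small folds is biased; means over repeats are reported.

**Division by zero.** Metric cells of the form 0/0 are reported as 0 and
flagged, mirroring the NaN entries that sparse confusion matrices produce
in published comparisons.

**Gradient boosting.**  No boosting library is assumed: the classifier is
an in-package multinomial-deviance gradient-boosted tree ensemble
(softmax residuals, depth-limited least-squares trees, one-step Newton
leaf values scaled by $(K-1)/K$).  Production defaults follow the stated
setting — 20000 estimators, learning rate 0.05, depth 7, subsample 0.4,
min split 3, `sqrt` feature subsampling — with reduced tree counts in tests
and examples.  Feature subsampling is drawn per node rather than per
split-candidate evaluation; at the `sqrt` setting this is functionally
equivalent and deterministic under the seed.

**Sequence and auxiliary blocks are interfaces.**  The 1280-component
transformer block is whatever provider you hand in (a per-sample
tab-separated table is supported); a deterministic hash-based stub ships so
pipelines run without model weights.  The stub carries *no* biological
signal — any accuracy obtained with it comes from the other blocks.  The
auxiliary block (surface areas, charges, pKa shifts, …) is an opaque
pass-through.

## What the synthetic fixtures do and do not establish

The fixture module generates: idealized-geometry peptides (backbone plus
simplified side chains with correct C/N/O/S elements, deterministic down to
the byte in the seed) for parsing/selection/filtration tests; point clouds
of known topology (hexagonal ring, split clusters, tetrahedral shell) whose
Betti numbers are verified through *both* the Laplacian-nullity route and
the persistence engine; and Gaussian labeled datasets, optionally with the
1 : 0.69 : 0.34 class imbalance of curated solubility data, for classifier
and metric tests.

Green tests therefore establish: algebraic correctness of the Laplacian
machinery (entrywise oracle, $\partial\partial = 0$, Hodge agreement with
persistence on random clouds), exact feature layouts, determinism, and
sane classifier behaviour on separable data.  They do **not** establish
predictive performance on real mutation data: peptide fixtures are not
physical structures, the transformer stub is not a language model, and the
published cross-validation scores depend on an external curated dataset,
predicted structures and model weights that are out of scope here.

## Known limitations

* Čech enumeration is $O(n^4)$ in cloud size; fine for local
  element-filtered clouds, not for whole proteins.  Use the neighborhood
  radius.
* The p-persistent Laplacian (pairs of filtration values) is not
  implemented; spectra are per-snapshot ($p = 0$), which is what the
  persistent Betti numbers here are defined from.
* mmCIF input, structure repair, protonation and mutant side-chain
  building are out of scope: both structures are inputs.
* The in-package Shrake–Rupley rASA (rolling probe 1.4 Å, Gly-X-Gly
  normalization) is adequate for fixtures; for production-quality surface
  areas supply a precomputed table.
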