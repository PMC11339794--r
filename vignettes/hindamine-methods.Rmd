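---
title: "Steric descriptors and best-subset screening for hindered amines: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric descriptors and best-subset screening for hindered amines: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindamine)
```

# The problem

Trisubstituted amines NR3 are pyramidal at nitrogen; extreme steric bulk
flattens the pyramid and remodels the amine's acidity and its affinity for
metals. This package quantifies that steric environment and relates it to
thermodynamic and kinetic response data (protonation and ligand-exchange
Gibbs energies, in kcal/mol) through three layers:

1. **Geometry descriptors** computed from 3D structures: the percent buried
   volume (%V\_Bur) of the amine around a virtual metal binding site, with
   quadrant decomposition and topographic steric maps; a nitrogen
   pyramidalization index; the longest C-N bond; and a van der Waals
   molecular surface area.
2. **Descriptor-table assembly** joining those geometric columns with
   externally computed quantum-chemical columns (E(LUMO), Mayer bond orders,
   NPA charges, chemical hardness, pKa) and the response energies. The
   quantum-chemical quantities are *inputs*: the package contains no
   electronic-structure code and never recomputes them.
3. **An exhaustive best-subset multilinear screen**: every 1-, 2- and
   3-variable OLS model from a candidate pool, ranked by R^2, with subgroup
   filters and robustness variants.

A synthetic-data layer (amine geometries of tunable bulk and pyramidality;
descriptor tables with planted linear models) closes the loop so that every
stage is testable without any external download.

# Buried volume

The probe sphere has radius 3.5 A and is centred on the axis of the nitrogen
lone pair at 2.0 A from N -- the typical amine-metal bond length, i.e. where
the metal would sit. The frame's xy plane is parallel to the least-squares
plane of the three N-bound substituent atoms. When the structure is a metal
complex, the z axis is the physical N->metal direction and the metal (plus
anything bonded through it) is excluded, so the descriptor always measures
the *amine ligand*. For free amines z points away from the substituent
centroid, i.e. toward the binding face.

The engine scans a cubic voxel grid of spacing `mesh` (default 0.1 A)
aligned to the frame axes. A voxel belongs to the sphere iff its centre lies
within the radius; it is buried iff that centre also lies within the scaled
van der Waals radius of any ligand atom. Then

\[ \%V_{Bur} = 100 \cdot \frac{\text{buried voxels}}{\text{sphere voxels}}. \]

Numerical choices and their rationale:

* **Voxel membership is a centre test** (no partial-volume weighting). The
  estimator converges as the mesh shrinks; on a single analytically solvable
  sphere the 0.1 A mesh is within ~0.03 percentage points of the closed form,
  and mesh halving moves full-amine totals by well under 0.3 points (both
  asserted in tests).
* **Grid registration** puts voxel centres at \((k + 0.5)\,\text{mesh} - R\),
  so no centre lies on a quadrant boundary at default parameters and each
  quadrant contains exactly one quarter of the sphere voxels; the quadrant
  mean therefore equals the total identically. Centres exactly on a boundary
  (possible for exotic meshes) are assigned to the positive side.
* **Radii**: Bondi van der Waals radii scaled by 1.17, with one substitution
  -- hydrogen uses the Rowland-Taylor value 1.09 A instead of Bondi's
  1.20 A (`vbur_radii_table()`). This is the convention of the standard
  buried-volume implementations, and the benchmark values bundled with the
  package (NH3 15.2, NMe3 29.7, pyridine 21.3) are reproduced only with it:
  with a literal Bondi hydrogen the NH3 value comes out 1.1 points high.
  `radii_table()` remains the pure Bondi set for anyone who wants it.
* **Hydrogens are included** by default. NH3 at 15.2% is impossible from the
  nitrogen sphere alone (~13.4%); `hydrogens = FALSE` reproduces the older
  heavy-atom convention.
* **Quadrant orientation**: the x axis is the in-plane projection of the
  lowest-index substituent (overridable with `x_ref_index`). The total is
  rotation-invariant about z; quadrant values are not, so low/high quadrant
  occupancies should be read with the convention in mind.
* **Near-planar free amines** (out-of-plane height < 0.05 A) make the "away
  from the substituents" sign ill-posed. Both faces are probed with a coarse
  pass and the less hindered one is kept, with a warning -- a metal binds
  the open face.

A Monte-Carlo engine (`mc_buried_volume()`, uniform sampling in the ball,
binomial standard error) shares nothing with the grid path beyond the frame
transform and serves as an independent oracle: on batches of generated
amines the two agree within three standard errors at 10^6 samples.

The topographic steric map reports, for every grid column over the
equatorial disc, the maximum z of buried voxel centres (sentinel -R for
unburied columns): the height profile of the ligand surface facing the
probe, the quantity usually drawn as isocontours.

# Pyramidalization

The default index is the perpendicular distance (A) of N from the plane of
its three substituents: exactly 0 for planar geometries, ~0.38 A for
ammonia, ~0.45 A for an idealized trialkylamine (N-C 1.47 A, C-N-C 111 deg).
That last number is why 0.450 is the conventional boundary between flattened
and sp3-like amines on this scale, and the subgroup filter
`"pyramidalization > 0.450"` (strict) reproduces that regime split. A second
strategy, `"angle-deficit"` (360 minus the sum of the three bond angles at
N, degrees), is installed behind the same contract: zero for planar, rigid-
motion invariant, monotone in the out-of-plane displacement. Published
pyramidality measures differ in normalization; the strategy switch isolates
that choice from the rest of the pipeline. A 2-coordinate (aromatic ring)
nitrogen defines no pyramid and scores exactly 0, matching the planar-
heterocycle convention. "Pd-bound pyramidalization" is the same operation
evaluated on the amine geometry inside a Pd complex (metal excluded from the
three substituents) -- a different column, not a different formula.

# Molecular area

`molecular_area()` is a Shrake-Rupley-style estimate of the scaled-vdW
surface: quasi-uniform golden-spiral point shells per atom, culled by
neighbour overlap, probe radius 0 by default. On a single atom it matches
\(4\pi r^2\) to better than 1%. Published "molecular area" columns rarely
state their convention, so the probe and radii are parameters.

# The screening engine

`screen_models()` enumerates **all** subsets of 1..3 candidates (`combn`),
applies listwise deletion per evaluated subset (each fit keeps the maximum
available n; the per-fit n is always reported so mismatches against an
external benchmark's "systems number" are visible rather than hidden), fits
OLS with intercept, and ranks by R^2 within each size, ties broken by fewer
variables then lexicographic names so output is reproducible.

* R^2 is `1 - SS_res/SS_tot`, identical to the squared Pearson correlation
  of fitted vs observed for OLS with intercept -- the equivalence is
  unit-tested rather than assumed. A constant response is guarded to R^2 = 0.
* RMSE uses denominator n; because conventions differ, the unbiased variant
  (n - p - 1) is carried alongside in every ledger.
* Rank-deficient designs error, naming the collinear columns.
* Robustness variants for barrier-like responses: clip negative responses to
  zero, or drop those rows entirely.
* No multiple-testing correction is applied -- best-subset R^2 is reported
  raw, as is customary in descriptor screening -- but every ledger records
  the number of subsets searched so a reader can judge the selection effect.

`screen_report()` drives a grid of screens (responses x filter x robustness)
and emits a benchmark-table-shaped CSV plus observed-vs-predicted data for
the best models.

# Synthetic data: what it emulates and what it does not

`build_amine()` constructs NR3 geometries: three substituent anchors with
3-fold symmetry, N displaced by `pyramid_height` along the axis, so the
default pyramidalization index of the product is the height *exactly* --
a sharp anchor for tests. Substituents are idealized sp3 templates
(tetrahedral angles, C-C 1.54 A, C-H 1.09 A; H, Me, Et, iPr, tBu and an
adamantyl-like branched blob). Each template carries a fixed canonical
rotamer chosen on physical grounds: methyls place one H anti to the lone
pair (the real NMe3 rotamer), ethyls sit tangentially as a same-sense
propeller, branched groups present their first branch toward the binding
face, which is how increasing bulk actually crowds a metal site. With these
rotamers the %V\_Bur of the homoleptic series at fixed height is strictly
increasing, Me < Et < iPr < tBu (29.5 < 33.9 < 46.4 < 49.3 at height
0.45 A), emulating the graded-bulk spread of real amine sets. Substituent
pairs closer than 0.8 A are rejected as clashes. What the generator does
*not* emulate: conformational ensembles, relaxed bond angles, electronic
effects, and the bulk-induced flattening coupling between substituent size
and pyramid height (heights are set, not energy-minimized). Passing tests
on generated amines therefore validate the descriptor machinery, not any
claim about real conformer populations.

`simulate_table()` draws descriptor columns uniformly on ranges emulating
the bundled reference data (%V\_Bur-like 15-70), plants a known linear
response with Gaussian noise, masks candidate cells at a missing rate
(mirroring the "not located" gaps of real tables), and can add decoy columns
correlated with an active one. The truth object carries the generating
parameters, so recovery is checked against ground truth: with n = 50, eight
candidates and noise sd 6 the true active pair tops the 2-variable ranking
in >= 95 of 100 seeded tables.

Idealized reference geometries (`ref_nh3()`, `ref_nme3()`, `ref_net3()`,
`ref_pyridine()`) are built from standard experimental structural parameters
and are stand-ins for optimized quantum-chemical structures. NH3 and
pyridine are geometrically rigid and land within 0.1 points of their
benchmark %V\_Bur; NMe3 lands within ~0.3 (its N-C bond length varies by
~0.01 A between experimental and DFT structures, worth ~0.2 points); NEt3
is conformationally floppy, and its single idealized rotamer (33.9) sits
well below the benchmark value (44.8) obtained for the metal-bound
conformation -- a deliberate illustration that one conformer does not
summarize a flexible amine.

# Problem sizes and determinism

The default test and acceptance runs use: voxel meshes 0.1-0.2 A (0.05 A
only for the single-atom convergence check), 10^5-10^6 Monte-Carlo samples,
batches of 5-10 generated amines for oracle equivalence, planted-model fits
at n = 200, and 50-100 seeded tables for recovery rates. These sizes give
sub-minute module tests while leaving every statistical margin (3 SE bands,
recovery >= 95%) comfortably resolved. All stochastic paths take explicit
seeds and restore the global RNG state, so runs are replayable bit for bit.

# Known limitations

* Monodentate N-donors only; one donor atom per structure call. Aromatic
  (2-coordinate) nitrogens are handled by `ring_n_frame()` for buried volume
  and score 0 pyramidalization by convention.
* Quadrant values depend on the documented x-axis convention.
* No conformer search: one geometry in, one descriptor out.
* The exact functional form behind some published pyramidality indices
  could not be verified against their original sources; the two installed
  strategies bracket the common conventions and agree on all anchors used
  here (zero for planar, threshold behaviour near 0.45 A).
* XYZ is the only input format; bond perception is covalent-radius-sum +
  0.4 A, adequate for optimized geometries but not for distorted or
  metal-cluster structures.
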