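---
title: "Models and methods behind mdscript"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mdscript}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscript)
```

# The evaluation model

`mdscript` evaluates a declarative script against a topology plus
trajectory.  The pipeline is: lex and parse (recursive descent, with
diagnostics carrying line/column spans rather than thrown errors), static
checking against the loaded topology (every node is annotated with a type
and a length before anything runs), then evaluation over the frames.

Three value families exist at runtime:

* **selections** — ordered lists of disjoint atom-index sets ("contexts"),
  derived from the topology only, hence frame-independent;
* **temporal values** — `float[K]` evaluated per frame; `K > 1` is a
  *population* (one member per context);
* **accumulated values** — 1D distributions and 3D volumes, summed over a
  frame range.

The `in` keyword is the language's centrepiece: `expr in ctx` evaluates
`expr` once per context of `ctx`, with atom indices local to each context,
and the static checker declares the result length to be the context count.
`and`/`or`/`not` operate on flattened atom sets and always yield a single
context.  This asymmetry (`in` preserves structure, `and` discards it) is
what the population machinery is built on.  Script-level indices are
1-based, as users of molecular viewers expect; the internal model is
0-based and conversion happens only at the language boundary.

Selections inside contextual evaluation are memoized by their printed form;
because selections are topology-only this is safe and keeps per-frame costs
flat.

# Geometry

Distances use the minimum-image convention `d - L * round(d / L)` per
periodic axis (round-half-to-even, so a displacement of exactly `L/2` is
left alone).  Only orthorhombic cells are supported; triclinic input is
rejected with an explicit error rather than silently mis-wrapped.

**Deperiodization** makes covalent structures whole: each connected
component of the bond graph is unwrapped by walking its bonds with
minimum-image steps from the lowest-index atom, then translated so its
(mass-weighted) center of mass lies inside the primary cell.  Computing the
center of mass *after* the graph unwrap (rather than a circular mean) is
deliberate: it makes the operation exactly idempotent and keeps the anchor
inside the structure.  **Recentering** deperiodizes, translates the target
set's center of mass to the cell center, and re-wraps — also idempotent,
and intra-structure pairwise minimum-image distances are preserved to
better than 1e-9.

**Superposition** is the standard mass-weighted Kabsch algorithm with the
determinant correction that excludes reflections.  **Shape anisotropy**
diagonalises the mass-weighted gyration tensor (eigenvalues
`l1 >= l2 >= l3`) into barycentric weights `c_lin = (l1 - l2)/T`,
`c_plan = 2(l2 - l3)/T`, `c_iso = 3 l3/T`; they are non-negative, sum to 1,
and map to the triangle with linear at (0,0), planar at (1,0) and isotropic
at (0.5, 1).  `planarity()` in the language returns `c_plan` directly;
whether a rescaling would match other tools is undocumented there, so the
definition here is pinned by tests.  Eigenvector order under degenerate
eigenvalues is unspecified, which is harmless because only eigenvalue
differences enter the weights.

**Bond inference** declares a bond when the minimum-image distance is at
most `1.3 * (r_cov(a) + r_cov(b))` (Cordero-style covalent radii), with
bonds involving hydrogen additionally capped at 1.2 Å.  Both constants are
exposed via `bond_config()` so tests can pin them.  File-provided bonds
(PDB CONECT) take precedence; inference fills the gap for formats without
bond records.

# Distributions and volumes

Distribution properties are accumulated as high-resolution histograms
(default 1024 bins, a power of two) and down-sampled for display by
adjacent-bin summation, which preserves total mass exactly and composes
(factor 2 twice equals factor 4).

`rdf(A, B, cutoff)` histograms minimum-image pair distances, excluding
self-pairs where the selections overlap, and normalises each frame's shell
counts by `N_A * rho_B * V_shell` with the *exact* spherical-shell volume
(not the `4 pi r^2 dr` approximation), so an ideal gas gives `g(r) = 1`
without small-bin bias.  Bonded pairs are *not* excluded by default; a flag
could add that, but the default keeps the estimator assumption-free.

`sdf(reference, target, extent)` uses the first reference context in the
first evaluated frame, centered on its center of mass, as the canonical
frame.  Every (frame, context) pair is Kabsch-superposed onto it and the
same rigid transform is applied to the target atoms, taken minimum-image
relative to the context's center of mass.  Deposits are nearest-voxel unit
counts, so the total deposited mass equals the number of in-range
(frame, context, target) triples exactly — the conservation law the tests
assert.  Trilinear deposits would look smoother but would turn an exact
invariant into an approximate one; raw counts are stored and any
normalisation is left to export time.

**Determinism across workers.**  Per-frame contributions are computed
independently and folded in ascending frame order regardless of how frames
are partitioned across workers, so a 1-worker and a 4-worker run produce
bitwise-identical results.  Series rows are exact by construction; SDF
deposits are integer counts (exact addition); RDF contributions are floats,
hence the explicit ordered fold.

# Temporal filtering

The temporal filter re-runs only distribution and volume accumulation over
the frames whose times fall in the selected range, storing filtered results
alongside (never replacing) the full-range ones; temporal series are never
truncated.  Filtered histograms reuse the full-range binning so the two
layers stay comparable bin by bin.

# Ramachandran analysis

Backbone dihedrals follow the standard definitions
`phi(i) = dihedral(C(i-1), N(i), CA(i), C(i))` and
`psi(i) = dihedral(N(i), CA(i), C(i), N(i+1))`; chain-terminal residues
lacking a neighbour are omitted, so a 15-residue chain yields 13 pairs.
Residues partition into four classes: GLY, PRO, pre-proline (a residue
immediately preceding a PRO in the same chain) and general.  A residue's
own GLY/PRO identity wins over the pre-proline rule — a GLY before a PRO
stays glycine — and pre-proline adjacency requires the same chain.

Densities are built on a periodic grid over `[-180, 180)^2` (default
180×180, i.e. 2° cells) and smoothed with a separable Gaussian kernel
(default sigma 6°) applied with periodic wrap on both axes as an exact
circular convolution; all points are weighted equally and the result is
normalised to total mass one.  Because the kernel matrix is circulant, the
separable implementation equals a direct 2D convolution to machine
precision — the tests check 1e-10 on a 32×32 grid.  No outlier-filtering
pre-pass is applied: the points come from simulation, not crystallography,
so every sample counts equally.

Contour levels are percentile-matched: for percentile `p` the finder
returns the largest density threshold whose super-level set holds at least
`p/100` of the mass.  Class defaults are 99.95%/98% (general) and
99.5%/98% (other classes).  On a grid the enclosed mass overshoots the
target by at most one cell's mass; a perfectly uniform density is a tie
degenerate case in which the super-level set at the common value is the
whole grid.  When layers (full trajectory, filtered interval, reference
distribution) are compared, all layers' thresholds are computed at the
reference's percentiles so iso-lines are A-to-B comparable, while each
layer keeps its own normalisation.  Reference densities are read from a
small csv grid format; no reference data ships with the package.

# Synthetic study systems

The generators define the package's study conditions and are first-class,
tested code:

* `make_alanine_chain(15, 500)` — a single 15-residue poly-alanine chain
  over 500 frames, built from idealised peptide internal coordinates at
  requested phi/psi (alpha-helical -57/-47 by default) with smooth
  per-residue sinusoidal dihedral modulation (default amplitude 8°, a
  magnitude typical of backbone fluctuation).  Internal residue geometry is
  rigid, which makes contextual values exactly predictable.
* `make_water_box(100, 30 Å)` — rigid 3-site waters at uniform random
  positions with a 1.8 Å oxygen exclusion, re-randomized each frame, so the
  oxygen-oxygen RDF is flat at 1 aside from sampling noise.  Sizes used in
  tests (80 waters, 60 frames, 24 Å box) keep the ideal-gas check inside a
  5-standard-error band at a few seconds' cost.
* `make_ligand_pocket()` — a rigid symmetric ligand (residue AIN) and rigid
  pocket residues whose center-of-mass distances are `d0 + k + drift*t` by
  construction, giving exact expected values for contextual distances.
* `make_split_molecule()` — a bonded chain stored wrapped across a box
  corner, the canonical deperiodization exercise.

These systems emulate file layouts, selection structure, periodic wrapping
and population semantics of real trajectories; they do not emulate force
fields, solvation structure, or realistic dynamics.  Passing tests
therefore certify the analysis machinery, not any physical claim about
real simulations.

# Numerical choices and limitations

* Coordinates are stored in Å; GRO input (nm) is converted on read; cube
  files are written in Bohr (the downstream-tool convention), with an
  Å mode behind the conventional negative-atom-count signal.
* Contexts are ordered by their lowest atom index; empty contexts are kept
  (e.g. `chain('A') in protein` when a protein has no chain-A atoms), so
  lengths always match the static type.
* Element inference strips leading digits, tries the two-letter then
  one-letter symbol, and resolves amino-acid ambiguities (CA/HG and
  friends) to their carbon/hydrogen reading.  It is total and idempotent,
  and it will misread genuinely ambiguous labels outside amino acids
  (an "HE" hetero-atom label reads as helium); `remap_elements()` is the
  escape hatch, applied per label or per atom.
* `protein` means residues with standard amino-acid names (plus common
  protonation variants), grouped into one context per chain; `water`
  matches HOH/SOL/WAT/TIP-style names, one context per molecule.
* Nested `in` contexts, triclinic cells, velocities, and binary trajectory
  formats (XTC/TRR/DCD) are out of scope; the reader interface is the
  extension point for compressed formats.
* Problem sizes in the test-suite (dozens of waters, tens of frames,
  32-point convolution oracles) were chosen as the smallest systems whose
  statistical checks are still sharp; the acceptance script uses 10,000
  density points on the full 180×180 grid, where one cell's mass bounds
  the contour-level discretisation error at well under 0.01%.
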