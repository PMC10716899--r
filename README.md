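# mdscript

A headless analysis core for molecular-dynamics trajectories, built around a
small declarative scripting language for atom selections and computed
properties.  It targets the analyst who wants scripted, reproducible
per-residue and per-structure measurements — distances, angles, dihedrals,
RMSD, radial and spatial distribution functions, Ramachandran densities —
without a GUI or a general-purpose programming language in the loop.

## The language and its contextual set semantics

Selections are sets of atoms produced by filters such as `element('H')`,
`resname("ALA")`, `chain('A')`, `protein`, `water`, or `atoms(1..10)`.
Two combinators look similar but differ in a load-bearing way:

* `and` / `or` intersect / unite selections and **flatten** the result into
  a single atom set;
* `expr in ctx` evaluates `expr` once per **context** of `ctx` (for
  `resname("ALA")`, one context per ALA residue) and **preserves** those
  contexts.  Atom indices on the left side of `in` are local to each
  context.

A numeric expression of length 1 evaluated in K contexts therefore has type
`float[K]` — a *population* — with one value per context per frame:

```
a1 = angle(1, 2, 3) in resname("ALA")   # N-H-CA angle inside every ALA
d1 = distance(com(resname("AIN")), com(resname("PCK")))
g  = rdf(element("O"), element("O"), 10.0)
v  = sdf(protein, resname("AIN"), 15.0)
```

Evaluated properties are temporal series (per frame), 1D distributions
(high-resolution histograms with conservative power-of-two down-sampling;
`rdf` normalised so an ideal gas gives g(r) = 1), or 3D volumes (`sdf`
accumulates target positions in the local frame of Kabsch-superposed
reference contexts).  Supporting machinery covers PDB/GRO/XYZ input,
csv/xvg/Gaussian-cube exchange, periodic-boundary deperiodization and
recentering, gyration-tensor shape anisotropy (`c_lin`, `c_plan`, `c_iso`),
selection growth, and Ramachandran densities smoothed with a periodic
separable Gaussian kernel and contoured at class-specific percentiles
(99.95/98 for the general class, 99.5/98 for glycine, proline and
pre-proline).

## A worked example

```r
library(mdscript)

traj <- make_alanine_chain(n_res = 15, n_frames = 500, seed = 1)
pt <- evaluate_script('a1 = angle(1, 2, 3) in resname("ALA")', traj)
pt
#> <md_property_table> 1 property
#>   a1           population_series (length 15)
round(pt$entries$a1$payload[1, 1:5], 2)
#> [1] 37.22 37.22 37.22 37.22 37.22
```

The property `a1` has length 15 — one angle per ALA residue context — and a
value per residue per frame; the printed numbers are the first frame's
angles (degrees) between local atoms 1, 2, 3 (N, H, CA) for residues 1-5.
They are identical across residues because the fixture holds every
residue's internal geometry rigid and varies only the backbone dihedrals —
a useful property when checking contextual evaluation.  The same analysis
runs from a shell:

```sh
Rscript inst/cli/mdscript.R run --top system.pdb --script analysis.txt --out results/
```

writing one csv/xvg/cube file per promoted property plus a JSON manifest
with checksums.

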